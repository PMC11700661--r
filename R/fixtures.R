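# Synthetic flat-file corpus and the brute-force enumeration oracle.
#
# The generator emulates the structural variety of UniProt entries
# (variants, conflicts, mutagens, maturation features, isoforms) on short
# random sequences; it makes no attempt at realistic biological sequence
# statistics.  The oracle expands every admissible feature subset by
# direct string editing and enumerates peptides by scanning, completely
# independently of the graph code path, so that graph construction, DP
# counting and mass queries can all be checked against it exactly.

#' Specification for a synthetic fixture corpus
#'
#' @param seed integer seed; the generator uses one private RNG stream and
#'   the same seed always yields byte-identical output.
#' @param n_entries number of entries.
#' @param length_range canonical sequence length range (residues).
#' @param max_features named integer vector: maximum number of features
#'   sampled per type (the actual count is uniform on 0..max).
#' @param replacement_len_range substitution replacement length range
#'   (0 = deletion).
#' @param isoform_range number of isoforms (each one VAR_SEQ edit).
#' @param alphabet residues to sample sequences from.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_entries = 10L,
                         length_range = c(8L, 30L),
                         max_features = c(VARIANT = 2L, CONFLICT = 1L,
                                          MUTAGEN = 1L, INIT_MET = 1L,
                                          SIGNAL = 1L, CHAIN = 1L,
                                          PEPTIDE = 1L, PROPEP = 0L),
                         replacement_len_range = c(0L, 3L),
                         isoform_range = c(0L, 2L),
                         alphabet = setdiff(AA_ALPHABET_EXT,
                                            c("B", "Z", "X", "U", "O"))) {
  stopifnot(length_range[1] >= 4L, n_entries >= 0L,
            replacement_len_range[1] >= 0L)
  structure(list(seed = as.integer(seed), n_entries = as.integer(n_entries),
                 length_range = as.integer(length_range),
                 max_features = max_features,
                 replacement_len_range = as.integer(replacement_len_range),
                 isoform_range = as.integer(isoform_range),
                 alphabet = alphabet),
            class = "fixture_spec")
}

with_private_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample a set of pairwise non-overlapping intervals of given widths
sample_disjoint <- function(L, widths, taken = matrix(0L, 0L, 2L)) {
  out <- matrix(0L, 0L, 2L)
  for (w in widths) {
    ok <- FALSE
    for (try in 1:50) {
      a <- sample.int(L - w + 1L, 1L)
      b <- a + w - 1L
      busy <- rbind(taken, out)
      if (!nrow(busy) || all(b < busy[, 1L] | a > busy[, 2L])) {
        out <- rbind(out, c(a, b)); ok <- TRUE; break
      }
    }
    if (!ok) break  # entry is crowded; fewer features is fine
  }
  out
}

generate_one_entry <- function(spec, idx) {
  L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
  seq <- paste(sample(spec$alphabet, L, replace = TRUE), collapse = "")
  acc <- sprintf("FX%04d", idx)
  feats <- list()
  counter <- 0L
  taken <- matrix(0L, 0L, 2L)
  add <- function(f) feats[[length(feats) + 1L]] <<- f

  nmax <- spec$max_features
  want <- vapply(names(nmax), function(t) {
    if (nmax[[t]] == 0L) 0L else sample(0:nmax[[t]], 1L)
  }, integer(1))

  if (isTRUE(want["INIT_MET"] > 0L) && L >= 4L) {
    substr(seq, 1L, 1L) <- "M"
    add(feature_record("INIT_MET", 1L, 1L))
    taken <- rbind(taken, c(1L, 1L))
  }
  if (isTRUE(want["SIGNAL"] > 0L) && L >= 8L && !nrow(taken)) {
    k <- sample(2:max(2L, L %/% 3L), 1L)
    add(feature_record("SIGNAL", 1L, k))
    taken <- rbind(taken, c(1L, k))
  }
  for (t in c("CHAIN", "PEPTIDE", "PROPEP")) {
    n <- want[t]
    if (is.na(n) || n == 0L) next
    for (i in seq_len(n)) {
      w <- sample(2:max(2L, L %/% 2L), 1L)
      iv <- sample_disjoint(L, w, taken)
      if (!nrow(iv)) next
      if (t == "PROPEP" && iv[1, 1] != 1L && iv[1, 2] != L) next
      taken <- rbind(taken, iv)
      add(feature_record(t, iv[1, 1], iv[1, 2]))
    }
  }
  for (t in c("VARIANT", "CONFLICT", "MUTAGEN")) {
    n <- want[t]
    if (is.na(n) || n == 0L) next
    widths <- sample(1:2, n, replace = TRUE)
    ivs <- sample_disjoint(L, widths, taken)
    for (i in seq_len(nrow(ivs))) {
      a <- ivs[i, 1L]; b <- ivs[i, 2L]
      taken <- rbind(taken, ivs[i, , drop = FALSE])
      rl <- sample(spec$replacement_len_range[1]:spec$replacement_len_range[2], 1L)
      if (rl == 0L && a == 1L && b == L) rl <- 1L  # whole-chain deletion is degenerate
      repl <- if (rl == 0L) "" else
        paste(sample(spec$alphabet, rl, replace = TRUE), collapse = "")
      if (identical(repl, substr(seq, a, b))) {
        repl <- paste0(repl, sample(spec$alphabet, 1L))
      }
      counter <- counter + 1L
      fid <- if (t == "VARIANT") sprintf("VAR_%04d%02d", idx, counter) else ""
      add(feature_record(t, a, b, substr(seq, a, b), repl, fid))
    }
  }
  n_iso <- sample(spec$isoform_range[1]:spec$isoform_range[2], 1L)
  for (i in seq_len(n_iso)) {
    iv <- sample_disjoint(L, sample(1:3, 1L), taken)
    if (!nrow(iv)) next
    taken <- rbind(taken, iv)
    rl <- sample(0:3, 1L)
    repl <- if (rl == 0L) "" else
      paste(sample(spec$alphabet, rl, replace = TRUE), collapse = "")
    if (iv[1, 1] == 1L && iv[1, 2] == L && rl == 0L) next
    counter <- counter + 1L
    add(feature_record("VAR_SEQ", iv[1, 1], iv[1, 2],
                       substr(seq, iv[1, 1], iv[1, 2]), repl,
                       sprintf("VSP_%04d%02d", idx, counter),
                       isoform_scope = as.character(i + 1L)))
  }
  derive_isoforms(protein_entry(acc, paste0(acc, "_TEST"), seq,
                                features = feats))
}

#' Generate a deterministic synthetic flat-file corpus
#'
#' @param spec a [fixture_spec()].
#' @return list with `text` (concatenated flat-file records), `entries`
#'   (the ground-truth [protein_entry()] list the text was written from)
#'   and `manifest` (a JSON-able summary of every feature).
#' @examples
#' fx <- generate_fixtures(fixture_spec(seed = 42, n_entries = 2))
#' length(parse_flatfile(fx$text))
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  entries <- with_private_rng(spec$seed, {
    lapply(seq_len(spec$n_entries), function(i) generate_one_entry(spec, i))
  })
  text <- paste(vapply(entries, format_flatfile, character(1)), collapse = "")
  manifest <- lapply(entries, function(e) {
    list(accession = e$accession, length = nchar(e$canonical),
         isoforms = as.list(e$isoforms),
         features = lapply(e$features, function(f) {
           list(ftype = f$ftype, start = f$start, end = f$end,
                original = f$original, replacement = f$replacement,
                fid = f$fid, isoform_scope = as.list(f$isoform_scope))
         }))
  })
  list(text = text, entries = entries, manifest = manifest)
}

#' Write a fixture corpus to disk
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths of the flat file and JSON manifest.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- generate_fixtures(spec)
  flat <- file.path(dir, "fixtures.txt")
  man <- file.path(dir, "manifest.json")
  writeLines(sub("\n$", "", fx$text), flat)
  jsonlite::write_json(fx$manifest, man, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(flatfile = flat, manifest = man))
}

# --- the oracle ------------------------------------------------------------

overlaps <- function(a1, b1, a2, b2) a1 <= b2 && a2 <= b1

# all subsets of substitution features that are pairwise non-overlapping
admissible_subsets <- function(subs) {
  n <- length(subs)
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1L))) > 0L)
    ok <- TRUE
    if (length(idx) > 1L) {
      for (i in seq_along(idx)[-1L]) {
        for (j in seq_len(i - 1L)) {
          a <- subs[[idx[i]]]; b <- subs[[idx[j]]]
          if (overlaps(a$start, a$end, b$start, b$end)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) out[[length(out) + 1L]] <- idx
  }
  out
}

# Entry and exit points on the original coordinates of one chain, derived
# purely from the annotations (never from any graph structure).  An entry
# point at position p means the peptide boundary can sit immediately
# before p, carrying the associated feature ids; maturation features
# contribute directly, and a deletion whose region begins at an entry
# point shifts that entry past its gap (accumulating its id) -- the
# closure mirrors how skipping from the boundary over a deleted region
# still uses the deletion.  Exit points are symmetric.
boundary_points <- function(feats, subs, L) {
  starts <- list(); ends <- list()
  addp <- function(lst, pos, fids) {
    k <- as.character(pos)
    lst[[k]] <- unique(c(lst[[k]], fids))
    lst
  }
  starts <- addp(starts, 1L, character())
  ends <- addp(ends, L, character())
  for (f in feats) {
    fid <- feature_id_of(f)
    if (f$ftype == "INIT_MET") {
      if (f$start == 1L && f$end == 1L && L >= 2L) starts <- addp(starts, 2L, fid)
    } else if (f$ftype %in% c("SIGNAL", "PROPEP")) {
      if (f$start == 1L && f$end < L) starts <- addp(starts, f$end + 1L, fid)
      else if (f$start > 1L && f$end == L) ends <- addp(ends, f$start - 1L, fid)
    } else if (f$ftype %in% c("PEPTIDE", "CHAIN")) {
      starts <- addp(starts, f$start, fid)
      ends <- addp(ends, f$end, fid)
    }
  }
  dels <- Filter(function(f) !nzchar(f$replacement), subs)
  dstart <- vapply(dels, `[[`, integer(1), "start")
  for (f in dels[order(dstart)]) {
    k <- as.character(f$start)
    if (!is.null(starts[[k]]) && f$end < L) {
      starts <- addp(starts, f$end + 1L,
                     c(feature_id_of(f), starts[[k]]))
    }
  }
  dend <- vapply(dels, `[[`, integer(1), "end")
  for (f in dels[order(dend, decreasing = TRUE)]) {
    k <- as.character(f$end)
    if (!is.null(ends[[k]]) && f$start > 1L) {
      ends <- addp(ends, f$start - 1L, c(feature_id_of(f), ends[[k]]))
    }
  }
  list(starts = starts, ends = ends)
}

oracle_one_chain <- function(chain_name, seq, subs, mats, rule,
                             scaled_masses, fixed_fp, water_fp) {
  L <- nchar(seq)
  chars0 <- strsplit(seq, "")[[1]]
  bp <- boundary_points(mats, subs, L)
  start_pos <- as.integer(names(bp$starts))
  end_pos <- as.integer(names(bp$ends))
  rows <- list()
  seen <- new.env(parent = emptyenv())

  for (S in admissible_subsets(subs)) {
    # build the edited string with per-character provenance tags
    ch <- character(); src <- integer(); tag <- character()
    vfid <- character()                      # per-char variant fid or NA
    junctions <- list()                      # deletion fid -> index before gap
    active <- subs[S]
    starts_of <- vapply(active, `[[`, integer(1), "start")
    p <- 1L
    while (p <= L) {
      hit <- which(starts_of == p)
      if (length(hit)) {
        f <- active[[hit[1]]]
        fid <- feature_id_of(f)
        if (nzchar(f$replacement)) {
          rc <- strsplit(f$replacement, "")[[1]]
          ch <- c(ch, rc)
          src <- c(src, rep(NA_integer_, length(rc)))
          tag <- c(tag, sprintf("%s#%d", fid, seq_along(rc)))
          vfid <- c(vfid, rep(fid, length(rc)))
        } else {
          junctions[[fid]] <- length(ch)
        }
        p <- f$end + 1L
      } else {
        ch <- c(ch, chars0[p])
        src <- c(src, p)
        tag <- c(tag, sprintf("p%d", p))
        vfid <- c(vfid, NA_character_)
        p <- p + 1L
      }
    }
    n <- length(ch)
    if (n == 0L) next

    # cleavage sites between adjacent characters of this edited string
    cleav <- if (rule$unspecific) {
      seq_len(n - 1L)
    } else {
      which(ch[-n] %in% rule$cut_after & !(ch[-1L] %in% rule$blocked_by_next))
    }

    # entry points: positions reachable straight from the boundary per
    # the annotation closure (with their feature ids), heads of
    # replacement chains whose region starts at such a position, and
    # positions following a cleavage site
    entries <- cleav + 1L
    entry_fids <- vector("list", n)
    for (j in seq_len(n)) {
      if (!is.na(src[j]) && src[j] %in% start_pos) {
        entries <- c(entries, j)
        entry_fids[[j]] <- bp$starts[[as.character(src[j])]]
      }
    }
    for (f in active) {
      if (!nzchar(f$replacement) || !(f$start %in% start_pos)) next
      j <- which(tag == sprintf("%s#1", feature_id_of(f)))
      entries <- c(entries, j)
      entry_fids[[j]] <- bp$starts[[as.character(f$start)]]
    }
    if (rule$unspecific) entries <- c(entries, seq_len(n))
    entries <- sort(unique(entries))

    exits <- cleav
    exit_fids <- vector("list", n)
    for (j in seq_len(n)) {
      if (!is.na(src[j]) && src[j] %in% end_pos) {
        exits <- c(exits, j)
        exit_fids[[j]] <- bp$ends[[as.character(src[j])]]
      }
    }
    for (f in active) {
      if (!nzchar(f$replacement) || !(f$end %in% end_pos)) next
      j <- which(tag == sprintf("%s#%d", feature_id_of(f),
                                nchar(f$replacement)))
      exits <- c(exits, j)
      exit_fids[[j]] <- bp$ends[[as.character(f$end)]]
    }
    if (rule$unspecific) exits <- c(exits, seq_len(n))
    exits <- sort(unique(exits))

    for (a in entries) {
      for (b in exits[exits >= a]) {
        key <- paste(chain_name, paste(tag[a:b], collapse = "."), sep = "|")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        misc <- sum(cleav >= a & cleav < b)
        fids <- character()
        vf <- vfid[a:b]
        fids <- c(fids, unique(vf[!is.na(vf)]))
        for (fid in names(junctions)) {
          j <- junctions[[fid]]
          if (j >= 1L && j < n && a <= j && b >= j + 1L) {
            fids <- c(fids, fid)
          }
        }
        if (!is.null(entry_fids[[a]])) fids <- c(fids, entry_fids[[a]])
        if (!is.null(exit_fids[[b]])) fids <- c(fids, exit_fids[[b]])
        pep <- ch[a:b]
        mass <- if (all(pep %in% names(scaled_masses))) {
          water_fp + sum(scaled_masses[pep]) +
            sum(fixed_fp[pep[pep %in% names(fixed_fp)]])
        } else NA_real_
        rows[[length(rows) + 1L]] <- list(
          chain = chain_name, key = key,
          sequence = paste(pep, collapse = ""),
          miscleavages = misc,
          fids = paste(sort(unique(fids)), collapse = ";"),
          mass = mass)
      }
    }
  }
  rows
}

#' Brute-force peptide enumeration (the oracle)
#'
#' Expands every pairwise non-overlapping subset of substitution features
#' by direct string editing, applies maturation entry/exit points, scans
#' each edited string for cleavage sites, and enumerates every
#' entry-to-exit window with any number of missed cleavages, computing
#' masses by direct summation.  Peptide identity is the traversed
#' character provenance, so windows untouched by a feature are not double
#' counted across subsets.  This is intentionally exponential and only
#' suitable for small entries; it shares no code with the graph pipeline
#' and is the reference all equivalence tests compare against.
#'
#' @param entry a [protein_entry()] (canonical length <= ~30 recommended).
#' @param rule an [enzyme_rule()].
#' @param feature_types feature types to apply.
#' @param ptm a [ptm_config()] (fixed deltas enter the masses; variable
#'   deltas are expanded by the caller where needed).
#' @param residue_masses named residue mass table in Dalton.
#' @return data.frame with columns `chain`, `key`, `sequence`,
#'   `miscleavages`, `fids` (sorted, ";"-joined), `mass` (fixed-point, NA
#'   for peptides with mass-less residues).
#' @export
oracle_enumerate <- function(entry, rule = enzyme_trypsin(),
                             feature_types = SUPPORTED_FTYPES,
                             ptm = ptm_config(),
                             residue_masses = default_residue_masses()) {
  scaled <- vapply(residue_masses, mass_scale, numeric(1))
  fixed_fp <- vapply(ptm$fixed, mass_scale, numeric(1))
  water_fp <- mass_scale(WATER_MONO)
  subs <- Filter(function(f) {
    f$ftype %in% intersect(SUBSTITUTION_FTYPES, feature_types) &&
      !(f$start == 1L && f$end == nchar(entry$canonical) &&
        !nzchar(f$replacement))
  }, entry$features)
  mats <- Filter(function(f) {
    f$ftype %in% intersect(MATURATION_FTYPES, feature_types)
  }, entry$features)
  rows <- oracle_one_chain("canonical", entry$canonical, subs, mats, rule,
                           scaled, fixed_fp, water_fp)
  for (iso in names(entry$isoforms)) {
    rows <- c(rows, oracle_one_chain(iso, entry$isoforms[[iso]], list(),
                                     list(), rule, scaled, fixed_fp,
                                     water_fp))
  }
  if (!length(rows)) {
    return(data.frame(chain = character(), key = character(),
                      sequence = character(), miscleavages = integer(),
                      fids = character(), mass = numeric()))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chain = r$chain, key = r$key, sequence = r$sequence,
               miscleavages = r$miscleavages, fids = r$fids, mass = r$mass,
               stringsAsFactors = FALSE)
  }))
}
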