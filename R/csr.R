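# Binary compressed-sparse-row serialization of compacted protein-graphs.
#
# Vertices are stored in deterministic topological order (Kahn's algorithm,
# min-vertex-id tie-break), so s is vertex 0 and e is the last vertex, and
# every edge points forward.  All integers are little-endian; masses and
# modification deltas are i64 on the 1e-9 Da fixed-point grid; counts and
# offsets are u64.  Write -> read -> write reproduces the file bit for bit.
#
# Layout (version 1):
#   magic "PGCSR\0" | u16 version | u64 nv | u64 ne
#   i64 mass[nv]
#   u64 label_offsets[nv+1] | label blob (amino-acid strings)
#   u64 edge_offsets[nv+1] | u64 targets[ne] | u8 edge_flags[ne] (bit0 cleaved)
#   feature table: u64 nf, then per feature u64 len + fid bytes,
#                  u64 len + ftype bytes
#   per-edge fid lists:   u64 offsets[ne+1] | u64 indices[]
#   per-vertex fid lists: u64 offsets[nv+1] | u64 indices[]
#   per-vertex variable mods: u64 offsets[nv+1] | u64 residue_offset[] |
#                             i64 delta[]
#   u8 vertex_flags[nv] (bit0: contains a mass-less residue, excluded from
#                        mass queries)
#   chain table: u64 nc, strings; u64 chain_index[nv]
#   i64 pos_start[nv] | i64 pos_end[nv]  (-1 encodes NA)
#   accession: u64 len + bytes
#   u64 max_variable_mods_per_peptide

CSR_MAGIC <- as.raw(c(0x50, 0x47, 0x43, 0x53, 0x52, 0x00))  # "PGCSR\0"
CSR_VERSION <- 1L

# -- little-endian integer codecs (values held exactly in doubles) ----------

enc_u64 <- function(x) {
  stopifnot(all(x >= 0), all(x < 2^53))
  out <- raw(8L * length(x))
  for (i in 0:7) {
    b <- x %% 256
    out[seq_along(x) * 8L - 7L + i] <- as.raw(b)
    x <- (x - b) / 256
  }
  out
}

dec_u64 <- function(r, n) {
  m <- matrix(as.numeric(r[seq_len(8L * n)]), nrow = 8L)
  as.numeric(colSums(m * 256^(0:7)))
}

enc_i64 <- function(x) {
  neg <- x < 0
  out <- enc_u64(ifelse(neg, -x - 1, x))
  if (any(neg)) {
    idx <- rep(which(neg) * 8L - 7L, each = 8L) + 0:7
    out[idx] <- as.raw(255L - as.integer(out[idx]))
  }
  out
}

dec_i64 <- function(r, n) {
  m <- matrix(as.integer(r[seq_len(8L * n)]), nrow = 8L)
  neg <- m[8L, ] >= 128L
  if (any(neg)) m[, neg] <- 255L - m[, neg]
  v <- as.numeric(colSums(m * 256^(0:7)))
  ifelse(neg, -v - 1, v)
}

enc_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
enc_str <- function(s) {
  b <- charToRaw(s)
  c(enc_u64(length(b)), b)
}

# -- conversion -------------------------------------------------------------

#' Convert a protein-graph to compressed-sparse-row form
#'
#' Reorders vertices into the deterministic topological order and packs
#' masses, labels, adjacency, feature annotations and positions into flat
#' arrays.  If the graph carries no mass labels yet, plain residue masses
#' are computed.  If `path` is given the binary file is written as well.
#'
#' @param g a (preferably compacted) `protein_graph`.
#' @param residue_masses named residue mass table in Dalton.
#' @param path optional output file for the binary form.
#' @return a `csr_graph`.
#' @examples
#' g <- build_protein_graph(protein_entry("X", "X_T", "MKAR"))
#' csr <- to_csr(g)
#' @export
to_csr <- function(g, residue_masses = default_residue_masses(), path = NULL) {
  stopifnot(is_protein_graph(g))
  if (is.null(g$vmass)) g <- annotate_ptms(g, ptm_config(), residue_masses)
  ord <- pg_topo_order(g)
  nv <- pg_n_vertices(g)
  pos_of <- integer(nv); pos_of[ord] <- seq_len(nv)

  eord <- order(pos_of[g$efrom], seq_len(pg_n_edges(g)))
  efrom <- pos_of[g$efrom[eord]]
  etarget <- pos_of[g$eto[eord]]

  eoff <- integer(nv + 1L)
  cnt <- tabulate(efrom, nv)
  eoff[1] <- 1L
  for (v in seq_len(nv)) eoff[v + 1L] <- eoff[v] + cnt[v]

  fids <- if (length(g$fid_type)) names(g$fid_type) else character()
  fid_idx <- function(fl) match(fl, fids)

  csr <- structure(list(
    accession = g$accession,
    n = nv, m = pg_n_edges(g),
    mass = g$vmass[ord],
    aa = g$aa[ord],
    # bit0: mass-less residue (excluded from queries); bit1: insertion-derived
    vflags = as.integer(g$vexcl[ord]) + 2L * as.integer(g$virtual[ord]),
    eoff = eoff,
    etarget = etarget,
    eflags = as.integer(g$ecleaved[eord]),
    fids = fids,
    fid_type = unname(g$fid_type),
    efid = lapply(g$efids[eord], fid_idx),
    vfid = lapply(g$vfids[ord], fid_idx),
    vmods = g$vmods[ord],
    chains = unique(g$chain[ord]),
    vchain = match(g$chain[ord], unique(g$chain[ord])),
    pos_start = g$pos_start[ord],
    pos_end = g$pos_end[ord],
    max_var_mods = if (!is.null(g$ptm)) g$ptm$max_variable_per_peptide else 3L
  ), class = "csr_graph")
  if (!is.null(path)) write_csr(csr, path)
  csr
}

#' @export
print.csr_graph <- function(x, ...) {
  cat(sprintf("<csr_graph %s: %d vertices, %d edges, %d feature id(s)>\n",
              x$accession, x$n, x$m, length(x$fids)))
  invisible(x)
}

offsets_of <- function(lst) {
  cumsum(c(0, vapply(lst, NROW, integer(1))))
}

#' Write a CSR graph to its binary format
#'
#' @param csr a `csr_graph` from [to_csr()] or [read_csr()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_csr <- function(csr, path) {
  nv <- csr$n; ne <- csr$m
  blob <- charToRaw(paste(csr$aa, collapse = ""))
  lab_off <- cumsum(c(0, nchar(csr$aa, type = "bytes")))

  efid0 <- lapply(csr$efid, function(x) if (length(x)) x - 1 else numeric(0))
  vfid0 <- lapply(csr$vfid, function(x) if (length(x)) x - 1 else numeric(0))
  mod_off <- offsets_of(csr$vmods)
  nonnull <- Filter(Negate(is.null), csr$vmods)
  mods <- if (length(nonnull)) {
    do.call(rbind, lapply(nonnull, `[`, c("offset", "delta")))
  } else {
    data.frame(offset = numeric(), delta = numeric())
  }

  parts <- list(
    CSR_MAGIC, enc_u16(CSR_VERSION), enc_u64(c(nv, ne)),
    enc_i64(csr$mass),
    enc_u64(lab_off), blob,
    enc_u64(csr$eoff - 1), enc_u64(csr$etarget - 1),
    as.raw(csr$eflags),
    enc_u64(length(csr$fids)),
    unlist(lapply(seq_along(csr$fids), function(i) {
      c(enc_str(csr$fids[i]), enc_str(csr$fid_type[i]))
    })),
    enc_u64(offsets_of(efid0)), enc_u64(unlist(efid0, use.names = FALSE)),
    enc_u64(offsets_of(vfid0)), enc_u64(unlist(vfid0, use.names = FALSE)),
    enc_u64(mod_off),
    enc_u64(mods$offset - 1), enc_i64(mods$delta),
    as.raw(csr$vflags),
    enc_u64(length(csr$chains)),
    unlist(lapply(csr$chains, enc_str)),
    enc_u64(csr$vchain - 1),
    enc_i64(ifelse(is.na(csr$pos_start), -1, csr$pos_start)),
    enc_i64(ifelse(is.na(csr$pos_end), -1, csr$pos_end)),
    enc_str(csr$accession),
    enc_u64(csr$max_var_mods)
  )
  parts <- parts[!vapply(parts, is.null, logical(1))]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(unlist(lapply(parts, as.raw)), con)
  invisible(path)
}

#' Read a binary CSR graph
#'
#' @param path file written by [write_csr()].
#' @return a `csr_graph`.
#' @export
read_csr <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  p <- 1L
  take <- function(n) {
    if (n == 0) return(raw(0))
    out <- r[p:(p + n - 1L)]
    p <<- p + as.integer(n)
    out
  }
  if (!identical(take(6L), CSR_MAGIC)) stop("not a CSR protein-graph file")
  version <- as.integer(take(1L)) + 256L * as.integer(take(1L))
  if (version != CSR_VERSION) stop("unsupported CSR format version ", version)
  u64s <- function(n) dec_u64(take(8L * n), n)
  i64s <- function(n) dec_i64(take(8L * n), n)
  str1 <- function() {
    len <- u64s(1L)
    if (len == 0) "" else rawToChar(take(len))
  }
  nv <- u64s(1L); ne <- u64s(1L)
  mass <- i64s(nv)
  lab_off <- u64s(nv + 1L)
  blob <- take(lab_off[nv + 1L])
  aa <- substring(rawToChar(blob), lab_off[-length(lab_off)] + 1L,
                  lab_off[-1L])
  eoff <- u64s(nv + 1L) + 1L
  etarget <- u64s(ne) + 1L
  eflags <- as.integer(take(ne))
  nf <- u64s(1L)
  fids <- character(nf); ftypes <- character(nf)
  for (i in seq_len(nf)) {
    fids[i] <- str1(); ftypes[i] <- str1()
  }
  read_lists <- function(count) {
    off <- u64s(count + 1L)
    idx <- u64s(off[count + 1L]) + 1L
    lapply(seq_len(count), function(i) {
      if (off[i + 1L] == off[i]) integer(0) else idx[(off[i] + 1L):off[i + 1L]]
    })
  }
  efid <- read_lists(ne)
  vfid <- read_lists(nv)
  mod_off <- u64s(nv + 1L)
  tot <- mod_off[nv + 1L]
  mod_res <- u64s(tot) + 1L
  mod_delta <- i64s(tot)
  vmods <- lapply(seq_len(nv), function(v) {
    if (mod_off[v + 1L] == mod_off[v]) return(NULL)
    i <- (mod_off[v] + 1L):mod_off[v + 1L]
    data.frame(offset = mod_res[i], delta = mod_delta[i])
  })
  vflags <- as.integer(take(nv))
  nc <- u64s(1L)
  chains <- vapply(seq_len(nc), function(i) str1(), character(1))
  vchain <- u64s(nv) + 1L
  pos_start <- i64s(nv); pos_start[pos_start < 0] <- NA
  pos_end <- i64s(nv); pos_end[pos_end < 0] <- NA
  accession <- str1()
  max_var_mods <- u64s(1L)
  structure(list(
    accession = accession, n = nv, m = ne, mass = mass, aa = aa,
    vflags = vflags, eoff = eoff, etarget = etarget, eflags = eflags,
    fids = fids, fid_type = ftypes, efid = efid, vfid = vfid,
    vmods = vmods, chains = chains, vchain = vchain,
    pos_start = as.integer(pos_start), pos_end = as.integer(pos_end),
    max_var_mods = max_var_mods
  ), class = "csr_graph")
}

#' Per-vertex residual mass bounds to the end vertex
#'
#' Reverse-topological dynamic program.  For the end vertex both bounds
#' are zero; for any other vertex the bound adds its own mass (variable
#' modification deltas contribute their negative part to the minimum and
#' their positive part to the maximum) to the extreme over its successors.
#' [query_csr()] prunes any partial path that cannot reach the query
#' interval under these bounds.
#'
#' @param csr a `csr_graph`.
#' @return a two-column matrix `cbind(min_remaining, max_remaining)` in
#'   fixed-point mass units.
#' @export
precompute_bounds <- function(csr) {
  nv <- csr$n
  minr <- numeric(nv); maxr <- numeric(nv)
  dneg <- dpos <- numeric(nv)
  for (v in seq_len(nv)) {
    if (!is.null(csr$vmods[[v]])) {
      d <- csr$vmods[[v]]$delta
      dneg[v] <- sum(d[d < 0])
      dpos[v] <- sum(d[d > 0])
    }
  }
  for (v in rev(seq_len(nv))) {
    lo <- eoff_edges(csr, v)
    if (!length(lo)) {
      minr[v] <- 0; maxr[v] <- 0  # end vertex
      next
    }
    succ <- csr$etarget[lo]
    minr[v] <- csr$mass[v] + dneg[v] + min(minr[succ])
    maxr[v] <- csr$mass[v] + dpos[v] + max(maxr[succ])
  }
  cbind(min_remaining = minr, max_remaining = maxr)
}

eoff_edges <- function(csr, v) {
  if (csr$eoff[v + 1L] == csr$eoff[v]) integer(0) else
    csr$eoff[v]:(csr$eoff[v + 1L] - 1L)
}
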