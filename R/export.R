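# FASTA export of peptides, global and precursor-specific.
#
# Header grammar (lossless, grep-able):
#   >pg|<accession>|<chain>|<start>-<end>|mssclvg:<n>|<fid1;fid2;...>
# with "canonical" in the last field when the peptide uses no features.
# Positions refer to the source chain, 1-based inclusive; residues derived
# from an insertion/replacement report the anchor interval of the replaced
# region with a '+' suffix on the start.

#' Export configuration
#'
#' @param min_length,max_length peptide length window in residues.
#' @param max_miscleavages missed-cleavage cap (`Inf` = unlimited).
#' @param max_mass mass cap in Dalton for the global export (the usual
#'   search-engine ceiling is 5000 Da).
#' @param exclude_ftypes feature types whose peptides are dropped (e.g.
#'   `"MUTAGEN"`).
#' @param dedup merge identical sequences into one record with
#'   concatenated headers (separated by Ctrl-A).
#' @param max_records refuse the export when the projected record count
#'   (from the exact DP counter) exceeds this cap.
#' @return an `export_config`.
#' @export
export_config <- function(min_length = 1L, max_length = Inf,
                          max_miscleavages = Inf, max_mass = 5000,
                          exclude_ftypes = character(), dedup = FALSE,
                          max_records = Inf) {
  stopifnot(min_length <= max_length, max_mass > 0)
  structure(list(min_length = min_length, max_length = max_length,
                 max_miscleavages = max_miscleavages, max_mass = max_mass,
                 exclude_ftypes = exclude_ftypes, dedup = isTRUE(dedup),
                 max_records = max_records),
            class = "export_config")
}

hit_header <- function(hit, accession) {
  span <- sprintf("%d%s-%d", hit$start,
                  if (isTRUE(hit$start_virtual)) "+" else "", hit$end)
  sprintf(">pg|%s|%s|%s|mssclvg:%d|%s", accession, hit$chain, span,
          hit$miscleavages,
          if (length(hit$feature_ids)) paste(hit$feature_ids, collapse = ";")
          else "canonical")
}

#' Parse a pepgraph FASTA header back into its fields
#'
#' Inverse of the header grammar written by the exporters.
#'
#' @param header header line with or without the leading `>`.
#' @return list with `accession`, `chain`, `start`, `end`, `miscleavages`,
#'   `feature_ids` (character vector, empty for canonical peptides).
#' @export
parse_fasta_header <- function(header) {
  header <- sub("^>", "", header)
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 6L, parts[1] == "pg")
  span <- strsplit(parts[4], "-", fixed = TRUE)[[1]]
  fids <- if (parts[6] == "canonical") character() else
    strsplit(parts[6], ";", fixed = TRUE)[[1]]
  list(accession = parts[2], chain = parts[3],
       start = as.integer(sub("\\+$", "", span[1])),
       end = as.integer(span[2]),
       miscleavages = as.integer(sub("^mssclvg:", "", parts[5])),
       feature_ids = fids)
}

hit_passes <- function(hit, cfg, fid_type) {
  len <- nchar(hit$sequence)
  if (len < cfg$min_length || len > cfg$max_length) return(FALSE)
  if (hit$miscleavages > cfg$max_miscleavages) return(FALSE)
  if (length(cfg$exclude_ftypes) && length(hit$feature_ids) &&
      any(fid_type[hit$feature_ids] %in% cfg$exclude_ftypes)) return(FALSE)
  TRUE
}

write_records <- function(headers, sequences, sink, dedup) {
  if (dedup && length(sequences)) {
    grp <- split(seq_along(sequences), sequences)
    # deterministic: order groups by first occurrence
    grp <- grp[order(vapply(grp, min, integer(1)))]
    headers <- vapply(grp, function(i) paste(headers[i], collapse = "\x01"),
                      character(1))
    sequences <- names(grp)
  }
  if (!length(sequences)) {
    # write an empty file
    con <- file(sink, "w"); close(con)
    return(0L)
  }
  writeLines(paste0(headers, "\n",
                    vapply(sequences, function(s) {
                      paste(substring(s, seq(1L, nchar(s), 60L),
                                      pmin(seq(60L, nchar(s) + 59L, 60L),
                                           nchar(s))),
                            collapse = "\n")
                    }, character(1), USE.NAMES = FALSE)),
             con = sink)
  length(sequences)
}

#' Export every peptide of a set of graphs to FASTA
#'
#' Enumerates all complete paths of each digested graph with mass up to
#' `cfg$max_mass` (via the bound-pruned traversal), filters by length,
#' missed cleavages and excluded feature types, and writes FASTA in a
#' deterministic order (graph order, then traversal order).  With
#' `cfg$dedup` identical sequences are merged into one record whose
#' headers are concatenated with Ctrl-A.  If the exact DP count of
#' peptides exceeds `cfg$max_records` the export refuses, citing the
#' count.
#'
#' @param graphs list of digested `protein_graph`s.
#' @param cfg an [export_config()].
#' @param sink output FASTA path.
#' @return number of records written.
#' @export
export_global <- function(graphs, cfg = export_config(), sink) {
  if (is_protein_graph(graphs)) graphs <- list(graphs)
  if (is.finite(cfg$max_records)) {
    projected <- big_sum(lapply(graphs, count_paths))
    if (big_cmp(projected, bigint(cfg$max_records)) > 0L) {
      stop("projected export of ", format(projected),
           " records exceeds the configured cap of ", cfg$max_records)
    }
  }
  headers <- character(); sequences <- character()
  for (g in graphs) {
    if (!g$digested) stop("graph ", g$accession, " is not digested")
    csr <- to_csr(g)
    res <- query_csr(csr, mass_interval(0, cfg$max_mass),
                     query_limits(max_miscleavages = cfg$max_miscleavages))
    for (hit in res$hits) {
      if (!hit_passes(hit, cfg, structure(csr$fid_type, names = csr$fids)))
        next
      headers <- c(headers, hit_header(hit, csr$accession))
      sequences <- c(sequences, hit$sequence)
    }
  }
  write_records(headers, sequences, sink, cfg$dedup)
}

#' Read a precursor query CSV
#'
#' @param path CSV with required header columns `mz`, `charge`, `tol_ppm`.
#' @return data.frame of valid rows; unreadable rows are dropped with a
#'   warning and counted in attribute `"skipped"`.
#' @export
read_precursor_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mz", "charge", "tol_ppm")
  if (!all(need %in% names(df))) {
    stop("precursor CSV must have columns: ", paste(need, collapse = ", "))
  }
  for (col in need) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  ok <- is.finite(df$mz) & df$mz > 0 &
    is.finite(df$charge) & df$charge >= 1 &
    is.finite(df$tol_ppm) & df$tol_ppm >= 0
  if (any(!ok)) {
    warning(sum(!ok), " unreadable precursor row(s) skipped", call. = FALSE)
  }
  out <- df[ok, need]
  attr(out, "skipped") <- sum(!ok)
  out
}

#' Export precursor-specific peptides to FASTA
#'
#' For each precursor the m/z, charge and tolerance define a neutral-mass
#' window; hits are gathered across all graphs, the union over precursors
#' is deduplicated by (sequence, feature-id set), and FASTA records carry
#' accession, position span, miscleavage count and feature ids in the
#' header.
#'
#' @param csrs list of `csr_graph`s.
#' @param precursors data.frame from [read_precursor_csv()] (or a path to
#'   the CSV).
#' @param cfg an [export_config()].
#' @param sink output FASTA path.
#' @param limits a [query_limits()] applied to every query.
#' @return number of records written.
#' @export
export_precursor_specific <- function(csrs, precursors,
                                      cfg = export_config(), sink,
                                      limits = query_limits()) {
  if (inherits(csrs, "csr_graph")) csrs <- list(csrs)
  if (is.character(precursors)) precursors <- read_precursor_csv(precursors)
  all_bounds <- lapply(csrs, precompute_bounds)
  headers <- character(); sequences <- character(); keys <- character()
  for (r in seq_len(nrow(precursors))) {
    iv <- precursor_to_interval(precursors$mz[r], precursors$charge[r],
                                precursors$tol_ppm[r])
    for (ci in seq_along(csrs)) {
      csr <- csrs[[ci]]
      res <- query_csr(csr, iv, limits, bounds = all_bounds[[ci]])
      for (hit in res$hits) {
        if (!hit_passes(hit, cfg, structure(csr$fid_type, names = csr$fids)))
          next
        key <- paste(hit$sequence,
                     paste(hit$feature_ids, collapse = ";"), sep = "\r")
        if (key %in% keys) next
        keys <- c(keys, key)
        headers <- c(headers, hit_header(hit, csr$accession))
        sequences <- c(sequences, hit$sequence)
      }
    }
  }
  write_records(headers, sequences, sink, dedup = FALSE)
}
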