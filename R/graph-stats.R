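# Exact characterization of the peptide search space.
#
# Path counts are computed by one dynamic-programming pass in topological
# order, accumulating arbitrary-precision counts per vertex (and per
# attribute bin).  Counts are over paths, not unique sequences: two paths
# spelling the same string are distinct peptides.

#' Count all complete s -> e paths exactly
#'
#' One topological pass accumulating the number of paths from `s` into
#' every vertex.  Counts are arbitrary-precision ([bigint()]): highly
#' annotated proteins exceed 10^200 peptides and must never overflow.
#'
#' @param g a `protein_graph` (digested, unless protein forms rather than
#'   peptides are wanted).
#' @return a [bigint()] path count.
#' @examples
#' e <- protein_entry("X", "X_T", "MKAR")
#' count_paths(build_protein_graph(e))  # MK, AR, MKAR
#' @export
count_paths <- function(g) {
  ord <- pg_topo_order(g)
  nv <- pg_n_vertices(g)
  succ_e <- split(seq_len(pg_n_edges(g)),
                  factor(g$efrom, levels = seq_len(nv)))
  paths <- rep(list(NULL), nv)
  paths[[g$s]] <- bigint(1)
  for (v in ord) {
    pv <- paths[[v]]
    if (is.null(pv)) next
    for (i in succ_e[[v]]) {
      w <- g$eto[i]
      paths[[w]] <- if (is.null(paths[[w]])) pv else big_add(paths[[w]], pv)
    }
  }
  if (is.null(paths[[g$e]])) bigint(0) else paths[[g$e]]
}

ATTRIBUTES <- c("none", "length", "miscleavages", "variant_count",
                "feature_count")

#' Count complete paths binned by an attribute
#'
#' Dynamic program carrying one bin-indexed count vector per vertex.
#' Supported attributes: `length` (residues spelled), `miscleavages`
#' (cleaved edges traversed), `variant_count` (distinct VARIANT feature
#' ids used), `feature_count` (distinct feature ids of any type used) and
#' `none` (total only).  A feature spanning several bridging edges counts
#' once per path.  With `cap`, DP states beyond the cap collapse into one
#' absorbing overflow bin, keeping capped runs cheap.
#'
#' @param g a `protein_graph`.
#' @param attribute one of `"none"`, `"length"`, `"miscleavages"`,
#'   `"variant_count"`, `"feature_count"`.
#' @param cap optional maximum bin; larger values aggregate into the
#'   `"overflow"` bin.
#' @return a `count_table`: list with `attribute`, `bins` (named list of
#'   [bigint()]s, names are bin values plus possibly `"overflow"`) and
#'   `total`.
#' @examples
#' e <- protein_entry("X", "X_T", "MKAR",
#'   features = list(feature_record("VARIANT", 3, 3, "A", "G", "VAR_1")))
#' count_by_attribute(build_protein_graph(e), "miscleavages")
#' @export
count_by_attribute <- function(g, attribute = "none", cap = NULL) {
  attribute <- match.arg(attribute, ATTRIBUTES)
  if (!is.null(cap)) stopifnot(cap >= 0)
  ord <- pg_topo_order(g)
  nv <- pg_n_vertices(g)
  succ_e <- split(seq_len(pg_n_edges(g)),
                  factor(g$efrom, levels = seq_len(nv)))
  newfids <- if (attribute %in% c("variant_count", "feature_count")) {
    pg_edge_newfids(g)
  }
  # per-edge attribute increment (length increments live on the target
  # vertex but are attached to its incoming edges, which is equivalent)
  inc <- switch(attribute,
    none = integer(pg_n_edges(g)),
    length = nchar(g$aa[g$eto]),
    miscleavages = as.integer(g$ecleaved),
    variant_count = vapply(newfids, function(f) {
      sum(g$fid_type[f] == "VARIANT")
    }, integer(1)),
    feature_count = lengths(newfids)
  )
  OVER <- "overflow"
  # A feature id can legitimately sit on both the entry edge (s -> a) and
  # the final edge (b -> e) of one path -- a maturation product traversed
  # end to end -- and must still count once.  For feature_count the DP
  # state therefore also carries the (small) set of entry-edge feature ids
  # that reappear on edges into e, and the final transition subtracts the
  # overlap.  Every other attribute needs no such correction.
  track_entry <- attribute == "feature_count"
  final_pool <- if (track_entry) {
    sort(unique(unlist(newfids[g$eto == g$e], use.names = FALSE)))
  } else character()
  states <- rep(list(NULL), nv)  # per vertex: key "bin|entryset" -> bigint
  states[[g$s]] <- stats::setNames(list(bigint(1)), "0|")
  bump <- function(tbl, key, val) {
    tbl[[key]] <- if (is.null(tbl[[key]])) val else big_add(tbl[[key]], val)
    tbl
  }
  for (v in ord) {
    sv <- states[[v]]
    if (is.null(sv)) next
    for (i in succ_e[[v]]) {
      w <- g$eto[i]
      tw <- states[[w]]
      if (is.null(tw)) tw <- list()
      ek_new <- if (track_entry && v == g$s) {
        paste(intersect(newfids[[i]], final_pool), collapse = ";")
      } else NULL
      for (key in names(sv)) {
        halves <- strsplit(key, "|", fixed = TRUE)[[1]]
        bin <- halves[1]
        ek <- if (length(halves) > 1L) halves[2] else ""
        if (!is.null(ek_new)) ek <- ek_new
        step <- inc[i]
        if (track_entry && w == g$e && nzchar(ek)) {
          step <- step - length(intersect(strsplit(ek, ";")[[1]], newfids[[i]]))
        }
        nb <- if (bin == OVER) OVER else {
          b <- as.integer(bin) + step
          if (!is.null(cap) && b > cap) OVER else as.character(b)
        }
        tw <- bump(tw, paste0(nb, "|", if (w == g$e) "" else ek), sv[[key]])
      }
      states[[w]] <- tw
    }
  }
  bins <- states[[g$e]]
  if (is.null(bins)) bins <- list()
  names(bins) <- sub("\\|$", "", names(bins))
  ord_keys <- names(bins)
  num <- suppressWarnings(as.integer(ord_keys))
  bins <- bins[order(is.na(num), num)]
  structure(list(attribute = attribute, bins = bins,
                 total = big_sum(bins), cap = cap),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table by %s: total %s>\n", x$attribute,
              big_signif(x$total)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.count_table <- function(x, ...) {
  data.frame(attribute = x$attribute,
             bin = names(x$bins),
             count = vapply(x$bins, format, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Search-space report over many entries and feature configurations
#'
#' Builds, digests and counts one graph per entry and feature
#' configuration.  Counts are serialized as decimal strings: they routinely
#' exceed the 64-bit range.  Per-entry failures are logged, skipped and
#' summarized.
#'
#' @param entries list of [protein_entry()]s.
#' @param feature_sets named list: configuration name -> character vector
#'   of feature types to apply (e.g. `list(none = character(),
#'   all = SUPPORTED_FTYPES)`).
#' @param enzyme an [enzyme_rule()].
#' @param max_miscleavages `NULL` for unlimited, or a cap applied by DP
#'   truncation.
#' @return data.frame with columns `accession`, `feature_set`,
#'   `max_miscleavages`, `total` (decimal string) and `total_sci`.
#' @export
count_report <- function(entries, feature_sets = list(
                           none = character(),
                           all = SUPPORTED_FTYPES),
                         enzyme = enzyme_trypsin(),
                         max_miscleavages = NULL) {
  rows <- list()
  failed <- character()
  for (entry in entries) {
    for (cfg in names(feature_sets)) {
      total <- tryCatch({
        g <- build_protein_graph(entry, enzyme = enzyme,
                                 feature_types = feature_sets[[cfg]])
        if (is.null(max_miscleavages)) {
          count_paths(g)
        } else {
          ct <- count_by_attribute(g, "miscleavages", cap = max_miscleavages)
          big_sum(ct$bins[names(ct$bins) != "overflow"])
        }
      }, error = function(e) {
        failed <<- c(failed, sprintf("%s/%s: %s", entry$accession, cfg,
                                     conditionMessage(e)))
        NULL
      })
      if (is.null(total)) next
      rows[[length(rows) + 1L]] <- data.frame(
        accession = entry$accession, feature_set = cfg,
        max_miscleavages = if (is.null(max_miscleavages)) NA_integer_ else
          as.integer(max_miscleavages),
        total = format(total), total_sci = big_signif(total),
        stringsAsFactors = FALSE)
    }
  }
  if (length(failed)) {
    warning("skipped ", length(failed), " entry/configuration pair(s):\n  ",
            paste(failed, collapse = "\n  "), call. = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write count tables or reports as CSV or JSON
#'
#' @param df a data.frame from [count_report()] or
#'   [as.data.frame.count_table()].
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_count_report <- function(df, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}
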