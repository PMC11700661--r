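# Shared comparison helpers: canonical signatures for peptides so that
# graph-derived hits and oracle rows can be compared as multisets.

# internal accessors used across the suite
pg_n_vertices <- pepgraph:::pg_n_vertices
pg_n_edges <- pepgraph:::pg_n_edges
feature_id_of <- pepgraph:::feature_id_of
ALL_FTYPES_TEST <- pepgraph:::SUPPORTED_FTYPES
MATURATION_TYPES_TEST <- pepgraph:::MATURATION_FTYPES

hit_signature <- function(hits) {
  sort(vapply(hits, function(h) {
    paste(h$sequence, h$miscleavages,
          paste(sort(h$feature_ids), collapse = ";"),
          sprintf("%.0f", h$mass), sep = "|")
  }, character(1)))
}

oracle_signature <- function(orc, interval = NULL) {
  if (!is.null(interval)) {
    keep <- !is.na(orc$mass) & orc$mass >= interval$lo & orc$mass <= interval$hi
    orc <- orc[keep, , drop = FALSE]
  }
  sort(paste(orc$sequence, orc$miscleavages,
             vapply(strsplit(orc$fids, ";"),
                    function(x) paste(sort(x), collapse = ";"), character(1)),
             sprintf("%.0f", orc$mass), sep = "|"))
}

hit_sequences <- function(res) sort(vapply(res$hits, `[[`, character(1), "sequence"))

bins_as_numeric <- function(ct) {
  stats::setNames(vapply(ct$bins, big_as_numeric, numeric(1)), names(ct$bins))
}

expect_bins_match <- function(ct, values) {
  ref <- table(values)
  got <- bins_as_numeric(ct)
  expect_identical(as.numeric(got[names(ref)]), as.numeric(ref))
  expect_equal(sum(got), length(values))
  expect_equal(big_as_numeric(ct$total), length(values))
}

# independent path spelling via igraph (never via package traversal code)
igraph_spellings <- function(g) {
  ig <- igraph::graph_from_edgelist(cbind(g$efrom, g$eto))
  paths <- igraph::all_simple_paths(ig, from = g$s, to = g$e, mode = "out")
  sort(vapply(paths, function(p) paste(g$aa[as.integer(p)], collapse = ""),
              character(1)))
}

entry_mkar_variant <- function() {
  protein_entry("X0001", "X0001_TEST", "MKAR", features = list(
    feature_record("VARIANT", 3, 3, "A", "G", "VAR_000001")))
}
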