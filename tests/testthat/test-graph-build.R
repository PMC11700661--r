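test_that("initial graph has one vertex per residue plus s and e", {
  g <- build_initial_graph(protein_entry("X", "X_T", "MK"))
  expect_identical(pg_n_vertices(g), 4L)
  expect_identical(pg_n_edges(g), 3L)

  e2 <- derive_isoforms(protein_entry("X", "X_T", "MK", features = list(
    feature_record("VAR_SEQ", 2, 2, "K", "R", "VSP_1", isoform_scope = "2"))))
  g2 <- build_initial_graph(e2)
  expect_identical(pg_n_vertices(g2), 6L)
  expect_identical(pg_n_edges(g2), 6L)

  g3 <- build_initial_graph(protein_entry("X", "X_T", "M"))
  expect_identical(igraph_spellings(g3), "M")
})

test_that("substitution features add bypassed alternative routes", {
  g <- build_initial_graph(protein_entry("X", "X_T", "MKAR"))
  gv <- apply_substitution_feature(g, feature_record("VARIANT", 3, 3, "A", "G", "V1"))
  expect_identical(pg_n_vertices(gv) - pg_n_vertices(g), 1L)
  expect_identical(pg_n_edges(gv) - pg_n_edges(g), 2L)
  expect_identical(igraph_spellings(gv), sort(c("MKAR", "MKGR")))

  gd <- apply_substitution_feature(g, feature_record("VARIANT", 3, 3, "A", "", "V1"))
  expect_identical(pg_n_vertices(gd), pg_n_vertices(g))
  expect_identical(pg_n_edges(gd) - pg_n_edges(g), 1L)
  expect_identical(igraph_spellings(gd), sort(c("MKAR", "MKR")))

  g2 <- apply_substitution_feature(gv, feature_record("VARIANT", 4, 4, "R", "W", "V2"))
  expect_identical(igraph_spellings(g2), sort(c("MKAR", "MKGR", "MKAW", "MKGW")))

  expect_error(apply_substitution_feature(g, feature_record("VARIANT", 5, 5, "A", "G")),
               "outside chain")
  expect_error(apply_substitution_feature(g, feature_record("VARIANT", 3, 3, "W", "G")),
               "claims original")
})

test_that("maturation features open matured start and end points", {
  g <- build_initial_graph(protein_entry("X", "X_T", "MKAR"))
  expect_identical(igraph_spellings(
    apply_maturation_feature(g, feature_record("INIT_MET", 1, 1))),
    sort(c("MKAR", "KAR")))
  expect_identical(igraph_spellings(
    apply_maturation_feature(g, feature_record("SIGNAL", 1, 2))),
    sort(c("MKAR", "AR")))
  chain <- igraph_spellings(
    apply_maturation_feature(g, feature_record("CHAIN", 2, 3)))
  expect_true("KA" %in% chain)
  expect_error(apply_maturation_feature(g, feature_record("CHAIN", 2, 9)),
               "outside chain")
})

test_that("tryptic digestion marks cleaved edges and opens peptide bounds", {
  e <- protein_entry("X", "X_T", "MKAR")
  g <- apply_digestion(build_initial_graph(e))
  expect_identical(igraph_spellings(g), sort(c("MK", "AR", "MKAR")))
  orc <- oracle_enumerate(e)
  expect_identical(sort(orc$sequence), sort(c("MK", "AR", "MKAR")))
  expect_identical(orc$miscleavages[orc$sequence == "MKAR"], 1L)

  gv <- build_protein_graph(entry_mkar_variant(), compact_graph = FALSE)
  expect_identical(igraph_spellings(gv), sort(c("MK", "AR", "GR", "MKAR", "MKGR")))

  g3 <- apply_digestion(build_initial_graph(protein_entry("X", "X_T", "AAA")))
  expect_identical(igraph_spellings(g3), "AAA")

  expect_error(apply_digestion(g), "already digested")
})

test_that("proline blocks tryptic cleavage and unspecific cleaves everywhere", {
  gp <- apply_digestion(build_initial_graph(protein_entry("X", "X_T", "MKPR")))
  expect_identical(igraph_spellings(gp), "MKPR")

  gu <- apply_digestion(build_initial_graph(protein_entry("X", "X_T", "MAR")),
                        enzyme_unspecific())
  expect_identical(igraph_spellings(gu),
                   sort(c("M", "A", "R", "MA", "AR", "MAR")))
})

test_that("compaction merges chains and preserves the path language", {
  e <- protein_entry("X", "X_T", "MKAR")
  g <- compact(build_initial_graph(e))
  expect_identical(pg_n_vertices(g), 3L)
  expect_identical(pg_n_edges(g), 2L)

  gd <- compact(apply_digestion(build_initial_graph(e)))
  # the cleaved K -> A edge must survive compaction
  expect_true(any(gd$ecleaved))
  expect_identical(igraph_spellings(gd), sort(c("MK", "AR", "MKAR")))

  fx <- generate_fixtures(fixture_spec(seed = 8, n_entries = 12))
  for (entry in fx$entries) {
    gu <- build_protein_graph(entry, compact_graph = FALSE)
    gc <- compact(gu)
    expect_identical(igraph_spellings(gc), igraph_spellings(gu))
    expect_identical(big_cmp(count_paths(gc), count_paths(gu)), 0L)
  }
})

test_that("every operation preserves acyclicity and determinism", {
  fx <- generate_fixtures(fixture_spec(seed = 15, n_entries = 10))
  for (entry in fx$entries) {
    g <- build_protein_graph(entry)
    ig <- igraph::graph_from_edgelist(cbind(g$efrom, g$eto))
    expect_true(igraph::is_dag(ig))
    g2 <- build_protein_graph(entry)
    expect_identical(g2, g)
  }
})

test_that("k independent substitutions yield 2^k undigested protein forms", {
  for (k in c(2L, 4L)) {
    L <- 2L * k + 2L
    seqv <- paste(rep(c("A", "G"), length.out = L), collapse = "")
    feats <- lapply(seq_len(k), function(i) {
      feature_record("VARIANT", 2L * i, 2L * i, substr(seqv, 2L * i, 2L * i),
                     "W", sprintf("VAR_%d", i))
    })
    g <- build_protein_graph(protein_entry("B", "B_T", seqv, features = feats),
                             enzyme = NULL)
    expect_identical(big_as_numeric(count_paths(g)), 2^k)
  }
})

test_that("graph dumps are syntactically sound and igraph-readable", {
  g <- build_protein_graph(entry_mkar_variant())
  dot <- withr::local_tempfile(fileext = ".dot")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_dot(g, dot)
  expect_match(readLines(dot)[1], "digraph")
  write_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_identical(as.integer(igraph::gorder(ig)), pg_n_vertices(g))
  expect_identical(as.integer(igraph::gsize(ig)), pg_n_edges(g))
})
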