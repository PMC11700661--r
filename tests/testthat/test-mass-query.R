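test_that("CSR vertices are topologically ordered with s first and e last", {
  g <- build_protein_graph(entry_mkar_variant())
  csr <- to_csr(g)
  expect_identical(csr$aa[1], "")
  expect_identical(csr$aa[csr$n], "")
  src <- rep(seq_len(csr$n), times = diff(csr$eoff))
  expect_true(all(csr$etarget > src))
  expect_identical(csr$mass[c(1, csr$n)], c(0, 0))
})

test_that("CSR write -> read -> write is byte-identical across fixtures", {
  fx <- generate_fixtures(fixture_spec(seed = 41, n_entries = 8))
  for (entry in fx$entries) {
    g <- build_protein_graph(entry,
                             ptm = ptm_config(variable = list(M = 15.994915)))
    f1 <- withr::local_tempfile(fileext = ".pgcsr")
    f2 <- withr::local_tempfile(fileext = ".pgcsr")
    csr <- to_csr(g, path = f1)
    back <- read_csr(f1)
    write_csr(back, f2)
    expect_identical(readBin(f2, "raw", file.size(f2)),
                     readBin(f1, "raw", file.size(f1)))
    expect_identical(back$aa, csr$aa)
    expect_identical(back$mass, csr$mass)
    expect_identical(as.integer(back$etarget), as.integer(csr$etarget))
  }
})

test_that("vertex masses sum residue masses on the fixed-point grid", {
  g <- compact(build_initial_graph(protein_entry("X", "X_T", "AR")))
  csr <- to_csr(g)
  m <- default_residue_masses()
  expect_identical(csr$mass[2], mass_scale(m[["A"]]) + mass_scale(m[["R"]]))
})

test_that("residual-mass bounds follow the reverse-topological recurrence", {
  g <- compact(build_initial_graph(protein_entry("X", "X_T", "AR")))
  csr <- to_csr(g)
  b <- precompute_bounds(csr)
  expect_identical(unname(b[csr$n, ]), c(0, 0))
  expect_identical(unname(b[2, ]), rep(csr$mass[2], 2))
  # a branch point sees min and max over both arms
  gv <- build_protein_graph(entry_mkar_variant())
  cv <- to_csr(gv)
  bv <- precompute_bounds(cv)
  s_succ <- cv$etarget[1:(cv$eoff[2] - 1)]
  expect_identical(unname(bv[1, 1]), min(bv[s_succ, 1]))
  expect_identical(unname(bv[1, 2]), max(bv[s_succ, 2]))
  expect_true(all(bv[, 2] >= bv[, 1]))
})

test_that("mass-window queries return exactly the enumerated peptides", {
  g <- build_protein_graph(entry_mkar_variant())
  csr <- to_csr(g)
  res <- query_csr(csr, mass_interval(245, 246))
  expect_identical(hit_sequences(res), "AR")
  expect_equal(res$hits[[1]]$mass_da, 245.14879, tolerance = 1e-6)

  all_res <- query_csr(csr, mass_interval(0, Inf))
  expect_length(all_res$hits, 5L)
  expect_true(all_res$completed)

  expect_length(query_csr(csr, mass_interval(0, 50))$hits, 0L)
})

test_that("precursor windows convert m/z, charge and ppm correctly", {
  iv <- precursor_to_interval(500.0, 2L, 10)
  expect_equal(iv$lo / 1e9, 997.975467, tolerance = 1e-6)
  expect_equal(iv$hi / 1e9, 997.995427, tolerance = 1e-6)

  iv0 <- precursor_to_interval(500.0, 2L, 0)
  expect_lte(iv0$hi - iv0$lo, 1)

  m <- 245.148790
  iv1 <- precursor_to_interval(m + 1.007276466, 1L, 0)
  expect_equal(iv1$lo / 1e9, m, tolerance = 1e-6)

  expect_error(precursor_to_interval(-1, 1, 10))
})

test_that("query hits equal the oracle on random windows across fixtures", {
  fx <- generate_fixtures(fixture_spec(seed = 42, n_entries = 10))
  set.seed(42)
  for (entry in fx$entries) {
    orc <- oracle_enumerate(entry)
    csr <- to_csr(build_protein_graph(entry))
    bounds <- precompute_bounds(csr)
    for (i in 1:15) {
      lo <- runif(1, 50, 1800)
      iv <- mass_interval(lo, lo + runif(1, 1, 500))
      res <- query_csr(csr, iv, bounds = bounds)
      expect_identical(hit_signature(res$hits), oracle_signature(orc, iv))
    }
  }
})

test_that("disabling pruning never changes the hit set", {
  fx <- generate_fixtures(fixture_spec(seed = 43, n_entries = 8))
  set.seed(43)
  for (entry in fx$entries) {
    csr <- to_csr(build_protein_graph(entry))
    bounds <- precompute_bounds(csr)
    for (i in 1:5) {
      lo <- runif(1, 50, 1500)
      iv <- mass_interval(lo, lo + runif(1, 10, 300))
      pruned <- query_csr(csr, iv, bounds = bounds, prune = TRUE)
      free <- query_csr(csr, iv, bounds = bounds, prune = FALSE)
      expect_identical(hit_signature(pruned$hits), hit_signature(free$hits))
    }
  }
})

test_that("widening the window only ever adds hits", {
  csr <- to_csr(build_protein_graph(entry_mkar_variant()))
  prev <- character()
  for (hi in c(250, 400, 520, 1000)) {
    cur <- hit_signature(query_csr(csr, mass_interval(200, hi))$hits)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("limits prune variants, features and miscleavages correctly", {
  entry <- entry_mkar_variant()
  csr <- to_csr(build_protein_graph(entry))
  novar <- query_csr(csr, mass_interval(0, Inf),
                     query_limits(max_variants = 0))
  bare <- to_csr(build_protein_graph(entry, feature_types = character()))
  expect_identical(hit_sequences(novar),
                   hit_sequences(query_csr(bare, mass_interval(0, Inf))))

  mc0 <- query_csr(csr, mass_interval(0, Inf),
                   query_limits(max_miscleavages = 0))
  expect_identical(hit_sequences(mc0), sort(c("MK", "AR", "GR")))

  capped <- query_csr(csr, mass_interval(0, Inf), query_limits(max_hits = 2))
  expect_length(capped$hits, 2L)
  expect_false(capped$completed)
})

test_that("variable modifications branch per occurrence up to the cap", {
  ox <- 15.994915
  g <- build_protein_graph(protein_entry("M1", "M1_T", "MKMAR"),
                           ptm = ptm_config(variable = list(M = ox)))
  res <- query_csr(to_csr(g), mass_interval(0, Inf))
  # MK and MAR carry one M each; MKMAR carries two: 2 + 2 + 4 branches
  expect_length(res$hits, 8L)
  mkmar <- Filter(function(h) h$sequence == "MKMAR", res$hits)
  masses <- sort(vapply(mkmar, `[[`, numeric(1), "mass"))
  base <- min(masses)
  expect_identical(masses - base,
                   c(0, mass_scale(ox), mass_scale(ox), 2 * mass_scale(ox)))

  one <- build_protein_graph(protein_entry("M1", "M1_T", "MKMAR"),
                             ptm = ptm_config(variable = list(M = ox),
                                              max_variable_per_peptide = 1L))
  res1 <- query_csr(to_csr(one), mass_interval(0, Inf))
  expect_length(res1$hits, 7L)  # the doubly modified MKMAR branch is gone
})

test_that("peptides with mass-less residues are excluded from queries", {
  g <- build_protein_graph(protein_entry("BX", "BX_T", "MKBAR"))
  res <- query_csr(to_csr(g), mass_interval(0, Inf))
  expect_identical(hit_sequences(res), "MK")
})

test_that("the feature-limit estimate brackets the budget", {
  csr <- to_csr(build_protein_graph(entry_mkar_variant()))
  iv <- mass_interval(0, Inf)
  # counts by feature bin are {0: 3, 1: 2}
  expect_identical(estimate_feature_limit(csr, iv, 4), 0L)
  expect_identical(estimate_feature_limit(csr, iv, 2), 0L)
  expect_identical(estimate_feature_limit(csr, iv, 5), Inf)
  k <- estimate_feature_limit(csr, iv, 4)
  res <- query_csr(csr, iv, query_limits(max_features = k))
  expect_lte(length(res$hits), 4L)
})
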