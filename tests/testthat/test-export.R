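test_that("global export honours miscleavage, length and dedup settings", {
  g <- build_protein_graph(entry_mkar_variant())
  path <- withr::local_tempfile(fileext = ".fasta")

  expect_identical(export_global(g, export_config(), path), 5L)
  expect_identical(export_global(g, export_config(max_miscleavages = 0), path), 3L)
  expect_identical(export_global(g, export_config(min_length = 3), path), 2L)
  lines <- readLines(path)
  expect_identical(lines[c(2, 4)], c("MKAR", "MKGR"))
})

test_that("dedup merges identical sequences with Ctrl-A joined headers", {
  # two graphs of the same entry produce every sequence twice
  g <- build_protein_graph(entry_mkar_variant())
  path <- withr::local_tempfile(fileext = ".fasta")
  n <- export_global(list(g, g), export_config(dedup = TRUE), path)
  expect_identical(n, 5L)
  headers <- grep("^>", readLines(path), value = TRUE)
  expect_true(all(grepl("\x01", headers)))
})

test_that("the export refuses when the projected count exceeds the cap", {
  g <- build_protein_graph(entry_mkar_variant())
  path <- withr::local_tempfile(fileext = ".fasta")
  expect_error(export_global(g, export_config(max_records = 4), path),
               "5 records exceeds")
})

test_that("FASTA headers are parseable and invert to their fields", {
  g <- build_protein_graph(entry_mkar_variant())
  path <- withr::local_tempfile(fileext = ".fasta")
  export_global(g, export_config(), path)
  lines <- readLines(path)
  headers <- grep("^>", lines, value = TRUE)
  parsed <- lapply(headers, parse_fasta_header)
  expect_true(all(vapply(parsed, `[[`, "", "accession") == "X0001"))
  gr <- parse_fasta_header(lines[match("GR", lines) - 1L])
  expect_identical(gr$feature_ids, "VAR_000001")
  expect_identical(c(gr$start, gr$end), c(3L, 4L))
  expect_identical(gr$miscleavages, 0L)
})

test_that("export record count equals the DP count under identical limits", {
  fx <- generate_fixtures(fixture_spec(seed = 51, n_entries = 6))
  path <- withr::local_tempfile(fileext = ".fasta")
  for (entry in fx$entries) {
    g <- build_protein_graph(entry)
    n <- export_global(g, export_config(), path)
    expect_identical(n, as.integer(big_as_numeric(count_paths(g))))
    n0 <- export_global(g, export_config(max_miscleavages = 0), path)
    ct <- count_by_attribute(g, "miscleavages", cap = 0)
    expect_identical(n0, as.integer(big_as_numeric(ct$bins[["0"]])))
  }
})

test_that("precursor-specific export gathers, filters and deduplicates", {
  g <- build_protein_graph(entry_mkar_variant())
  csr <- to_csr(g)
  path <- withr::local_tempfile(fileext = ".fasta")
  ar_mz <- 245.148790 + 1.007276466

  prec <- data.frame(mz = ar_mz, charge = 1, tol_ppm = 20)
  expect_identical(export_precursor_specific(csr, prec, export_config(), path), 1L)
  expect_identical(readLines(path)[2], "AR")

  none <- data.frame(mz = numeric(), charge = numeric(), tol_ppm = numeric())
  expect_identical(export_precursor_specific(csr, none, export_config(), path), 0L)

  twice <- data.frame(mz = c(ar_mz, ar_mz), charge = 1, tol_ppm = c(20, 50))
  expect_identical(export_precursor_specific(csr, twice, export_config(), path), 1L)
})

test_that("unreadable precursor rows are skipped with a warning and counted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,charge,tol_ppm", "500,2,10", "oops,1,10", "-4,1,10"), path)
  expect_warning(prec <- read_precursor_csv(path), "unreadable")
  expect_identical(nrow(prec), 1L)
  expect_identical(attr(prec, "skipped"), 2L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b", bad)
  expect_error(read_precursor_csv(bad), "must have columns")
})

test_that("the CLI wires fixtures, build, stats and query together", {
  dir <- withr::local_tempdir()
  expect_identical(suppressMessages(
    cli(c("fixtures", "--out-dir", dir, "--seed", "5", "--n-entries", "2"))), 0L)
  flat <- file.path(dir, "fixtures.txt")
  expect_true(file.exists(flat))

  csr_dir <- file.path(dir, "csr")
  expect_identical(suppressMessages(
    cli(c("build", "--input", flat, "--out-dir", csr_dir))), 0L)
  files <- list.files(csr_dir, pattern = "\\.pgcsr$", full.names = TRUE)
  expect_length(files, 2L)

  # CLI query against a mass computed from the library route
  csr <- read_csr(files[1])
  hit <- query_csr(csr, mass_interval(0, Inf))$hits[[1]]
  prec_csv <- file.path(dir, "prec.csv")
  writeLines(c("mz,charge,tol_ppm",
               sprintf("%.6f,1,10", hit$mass_da + 1.007276466)), prec_csv)
  out <- file.path(dir, "out.fasta")
  expect_identical(suppressMessages(
    cli(c("query", "--csr-dir", csr_dir, "--precursors", prec_csv,
          "--out", out))), 0L)
  expect_true(hit$sequence %in% readLines(out))

  stats_csv <- file.path(dir, "stats.csv")
  expect_identical(suppressMessages(
    cli(c("stats", "--input", flat, "--attribute", "variant_count",
          "--out", stats_csv))), 0L)
  expect_true("variant_count" %in% utils::read.csv(stats_csv)$attribute)

  expect_identical(suppressMessages(cli(c("stats", "--input", "nope.txt"))), 1L)
  expect_identical(suppressMessages(cli(c("frobnicate"))), 1L)
})
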