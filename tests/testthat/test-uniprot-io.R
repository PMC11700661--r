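flat_mkar <- c(
  "ID   X1_TEST                  Reviewed;              4 AA.",
  "AC   X0001;",
  "FT   VARIANT         3",
  "FT                   /note=\"A -> G\"",
  "FT                   /id=\"VAR_000001\"",
  "SQ   SEQUENCE    4 AA;",
  "     MKAR",
  "//")

test_that("a two-entry file parses to two entries in file order", {
  second <- sub("X1_TEST", "X2_TEST", sub("X0001", "X0002", flat_mkar))
  entries <- parse_flatfile(c(flat_mkar, second))
  expect_length(entries, 2L)
  expect_identical(vapply(entries, `[[`, "", "accession"), c("X0001", "X0002"))
  expect_identical(entries[[1]]$canonical, "MKAR")
})

test_that("substitution FT notes parse into validated feature records", {
  e <- parse_flatfile(flat_mkar)[[1]]
  f <- e$features[[1]]
  expect_identical(f$ftype, "VARIANT")
  expect_identical(c(f$start, f$end), c(3L, 3L))
  expect_identical(f$original, "A")
  expect_identical(f$replacement, "G")
  expect_identical(f$fid, "VAR_000001")
})

test_that("'Missing' notes become deletions and unknown keys are skipped", {
  txt <- append(flat_mkar, c(
    "FT   VARIANT         3..4",
    "FT                   /note=\"Missing\"",
    "FT   HELIX           1..2"), after = 5L)
  e <- suppressMessages(parse_flatfile(txt))[[1]]
  expect_length(e$features, 2L)
  expect_identical(e$features[[2]]$replacement, "")
  expect_identical(e$features[[2]]$original, "AR")
})

test_that("features whose original disagrees with the sequence are rejected", {
  fx <- generate_fixtures(fixture_spec(seed = 21, n_entries = 8))
  entries <- parse_flatfile(fx$text)
  for (e in entries) {
    # deletions serialize as "Missing" (no original text), so corrupt only
    # features whose "X -> Y" note actually carries the original
    eligible <- vapply(e$features,
                       function(f) nzchar(f$original) && nzchar(f$replacement),
                       logical(1))
    if (!any(eligible)) next
    bad <- e
    i <- which(eligible)[1]
    f <- bad$features[[i]]
    seqchr <- substr(bad$canonical, f$start, f$start)
    wrong <- setdiff(c("A", "G", "W"), seqchr)[1]
    bad$features[[i]]$original <- paste0(wrong, substring(f$original, 2))
    expect_warning(
      reparsed <- parse_flatfile(format_flatfile(bad)),
      "claims original")
    expect_length(reparsed[[1]]$features, length(e$features) - 1L)
  }
})

test_that("parse -> serialize -> parse is idempotent on the fixture corpus", {
  fx <- generate_fixtures(fixture_spec(seed = 4, n_entries = 10))
  entries <- parse_flatfile(fx$text)
  text2 <- paste(vapply(entries, format_flatfile, character(1)), collapse = "")
  expect_identical(text2, fx$text)
  entries2 <- parse_flatfile(text2)
  expect_identical(lapply(entries2, unclass), lapply(entries, unclass))
})

test_that("a truncated trailing entry warns with its accession and is skipped", {
  expect_warning(
    got <- parse_flatfile(c(flat_mkar, "ID   Y1_TEST", "AC   Y0001;",
                            "SQ   SEQUENCE 2 AA;", "     MK")),
    class = "pepgraph_truncated_entry")
  expect_length(suppressWarnings(
    parse_flatfile(c(flat_mkar, "AC   Y0001;", "SQ  x", "  MK"))), 1L)
})

test_that("isoforms materialize from VAR_SEQ edits in descending order", {
  del <- protein_entry("Z", "Z_T", "MKAR", features = list(
    feature_record("VAR_SEQ", 2, 2, "K", "", "VSP_1", isoform_scope = "2")))
  expect_identical(derive_isoforms(del)$isoforms[["2"]], "MAR")

  rep2 <- protein_entry("Z", "Z_T", "MKAR", features = list(
    feature_record("VAR_SEQ", 1, 2, "MK", "MGG", "VSP_1", isoform_scope = "2")))
  expect_identical(derive_isoforms(rep2)$isoforms[["2"]], "MGGAR")

  expect_length(derive_isoforms(protein_entry("Z", "Z_T", "MKAR"))$isoforms, 0L)

  multi <- protein_entry("Z", "Z_T", "MKARWC", features = list(
    feature_record("VAR_SEQ", 2, 2, "K", "QQ", "VSP_1", isoform_scope = "2"),
    feature_record("VAR_SEQ", 5, 6, "WC", "", "VSP_2", isoform_scope = "2")))
  expect_identical(derive_isoforms(multi)$isoforms[["2"]], "MQQAR")

  overlap <- protein_entry("Z", "Z_T", "MKAR", features = list(
    feature_record("VAR_SEQ", 1, 2, "MK", "Q", "VSP_1", isoform_scope = "2"),
    feature_record("VAR_SEQ", 2, 3, "KA", "W", "VSP_2", isoform_scope = "2")))
  expect_error(derive_isoforms(overlap), "isoform '2'")
})

test_that("isoform scope text parses singles and conjunctions", {
  txt <- c(
    "ID   I1_TEST                  Reviewed;              4 AA.",
    "AC   I0001;",
    "FT   VAR_SEQ         2",
    "FT                   /note=\"K -> Q (in isoform 2 and isoform Short)\"",
    "FT                   /id=\"VSP_000001\"",
    "SQ   SEQUENCE    4 AA;",
    "     MKAR",
    "//")
  e <- parse_flatfile(txt)[[1]]
  expect_identical(sort(names(e$isoforms)), c("2", "Short"))
  expect_identical(unname(e$isoforms[["2"]]), "MQAR")
})

test_that("FASTA output wraps, round-trips, and rejects empty sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seq61 <- strrep("A", 61)
  write_fasta(c("pg|X|a", "pg|Y|b"), c(seq61, "MK"), path)
  lines <- readLines(path)
  expect_identical(lines[1], ">pg|X|a")
  expect_identical(nchar(lines[2:3]), c(60L, 1L))
  back <- Biostrings::readAAStringSet(path)
  expect_identical(as.character(back[[1]]), seq61)
  expect_identical(names(back)[2], "pg|Y|b")

  write_fasta(character(), character(), path)
  expect_identical(file.size(path), 0)
  expect_error(write_fasta("h", "", path), "empty sequence")
})
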