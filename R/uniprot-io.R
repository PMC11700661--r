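# UniProt flat-file ("*.txt") parsing into a neutral in-memory model.
#
# Coordinates follow the UniProt convention throughout this file: 1-based,
# inclusive on both ends.  Conversion to internal representations happens
# once, at graph build.

AA_ALPHABET_EXT <- c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                     "Q","R","S","T","V","W","Y","B","Z","X","U","O")

SUPPORTED_FTYPES <- c("VARIANT", "CONFLICT", "MUTAGEN", "VAR_SEQ",
                      "SIGNAL", "INIT_MET", "PROPEP", "PEPTIDE", "CHAIN")
SUBSTITUTION_FTYPES <- c("VARIANT", "CONFLICT", "MUTAGEN")
MATURATION_FTYPES <- c("INIT_MET", "SIGNAL", "PROPEP", "PEPTIDE", "CHAIN")

#' Annotated sequence feature
#'
#' One UniProt feature on a protein sequence: a substitution-type feature
#' (VARIANT, CONFLICT, MUTAGEN), an isoform edit (VAR_SEQ) or a maturation
#' feature (INIT_MET, SIGNAL, PROPEP, PEPTIDE, CHAIN).
#'
#' @param ftype feature type, one of the supported keys.
#' @param start,end 1-based inclusive residue interval on the scoped
#'   sequence.
#' @param original residue string replaced by the feature (may be empty for
#'   pure insertions; always empty for maturation features).
#' @param replacement replacement residue string; empty means deletion
#'   ("Missing").
#' @param fid stable feature identifier such as `"VAR_002793"`, or `""`.
#' @param isoform_scope character vector of isoform names a VAR_SEQ applies
#'   to; empty for canonical-scoped features.
#' @return a `feature_record`.
#' @export
feature_record <- function(ftype, start, end, original = "",
                           replacement = "", fid = "",
                           isoform_scope = character()) {
  ftype <- match.arg(ftype, SUPPORTED_FTYPES)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 1L, end >= start)
  structure(list(ftype = ftype, start = start, end = end,
                 original = original, replacement = replacement,
                 fid = fid, isoform_scope = isoform_scope),
            class = "feature_record")
}

#' Parsed protein entry
#'
#' @param accession primary accession.
#' @param entry_name UniProt entry name (ID line).
#' @param canonical canonical amino-acid sequence (20-letter alphabet plus
#'   B, Z, X, U, O).
#' @param isoforms named character vector of fully materialized isoform
#'   sequences (may be empty before [derive_isoforms()]).
#' @param features list of [feature_record()]s in annotation order.
#' @return a `protein_entry`.
#' @export
protein_entry <- function(accession, entry_name, canonical,
                          isoforms = character(), features = list()) {
  stopifnot(nzchar(canonical))
  bad <- setdiff(strsplit(canonical, "")[[1]], AA_ALPHABET_EXT)
  if (length(bad)) {
    stop("invalid residues in canonical sequence of ", accession, ": ",
         paste(unique(bad), collapse = ""))
  }
  structure(list(accession = accession, entry_name = entry_name,
                 canonical = canonical, isoforms = isoforms,
                 features = features),
            class = "protein_entry")
}

#' @export
print.protein_entry <- function(x, ...) {
  cat(sprintf("<protein_entry %s (%s): %d aa, %d isoform(s), %d feature(s)>\n",
              x$accession, x$entry_name, nchar(x$canonical),
              length(x$isoforms), length(x$features)))
  invisible(x)
}

# --- parsing ---------------------------------------------------------------

parse_ft_location <- function(loc) {
  if (grepl("^[0-9]+$", loc)) {
    p <- as.integer(loc); return(c(p, p))
  }
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) == 3L) return(as.integer(m[2:3]))
  NULL  # uncertain positions like "?..22" or "<1" are unsupported
}

parse_isoform_scope <- function(comment) {
  m <- gregexpr("isoform ([^,()]+?)(?=,| and |\\)|$)", comment, perl = TRUE)
  hits <- regmatches(comment, m)[[1]]
  trimws(sub("^isoform ", "", hits))
}

# Turn one accumulated FT block into a feature_record (or NULL + warning).
build_feature <- function(key, loc, text, canonical, accession) {
  pos <- parse_ft_location(loc)
  if (is.null(pos)) {
    warning(sprintf("%s: unsupported %s location '%s'; feature skipped",
                    accession, key, loc), call. = FALSE)
    return(NULL)
  }
  note <- regmatches(text, regexec("/note=\"([^\"]*)\"", text))[[1]]
  note <- if (length(note) == 2L) note[2] else ""
  fid <- regmatches(text, regexec("/id=\"([^\"]*)\"", text))[[1]]
  fid <- if (length(fid) == 2L) fid[2] else ""

  original <- ""; replacement <- ""; scope <- character()
  if (key %in% c(SUBSTITUTION_FTYPES, "VAR_SEQ")) {
    comment <- sub("^[^(]*", "", note)
    if (key == "VAR_SEQ") scope <- parse_isoform_scope(comment)
    body <- trimws(sub("\\(.*$", "", note))
    if (identical(body, "Missing")) {
      original <- substr(canonical, pos[1], pos[2])
      replacement <- ""
    } else if (grepl("->", body)) {
      halves <- strsplit(body, "->")[[1]]
      original <- gsub("[^A-Z]", "", halves[1])
      replacement <- gsub("[^A-Z]", "", halves[2])
    } else {
      warning(sprintf("%s: cannot parse %s note '%s'; feature skipped",
                      accession, key, note), call. = FALSE)
      return(NULL)
    }
  }

  if (pos[2] > nchar(canonical)) {
    warning(sprintf("%s: %s interval %d..%d outside sequence; feature skipped",
                    accession, key, pos[1], pos[2]), call. = FALSE)
    return(NULL)
  }
  if (nzchar(original) &&
      !identical(original, substr(canonical, pos[1], pos[2]))) {
    warning(sprintf(
      "%s: %s %d..%d claims original '%s' but sequence reads '%s'; feature skipped",
      accession, key, pos[1], pos[2], original,
      substr(canonical, pos[1], pos[2])), call. = FALSE)
    return(NULL)
  }
  feature_record(key, pos[1], pos[2], original, replacement, fid, scope)
}

parse_one_entry <- function(lines) {
  tag <- substr(lines, 1L, 2L)
  entry_name <- accession <- ""
  id_line <- lines[tag == "ID"]
  if (length(id_line)) entry_name <- strsplit(trimws(substring(id_line[1], 6)), "\\s+")[[1]][1]
  ac_line <- lines[tag == "AC"]
  if (length(ac_line)) accession <- sub(";.*$", "", trimws(substring(ac_line[1], 6)))

  sq_at <- which(tag == "SQ")
  if (!length(sq_at)) {
    warning(sprintf("%s: entry has no SQ block; skipped", accession), call. = FALSE)
    return(NULL)
  }
  seq_lines <- lines[seq(sq_at[1] + 1L, length(lines))]
  canonical <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  canonical <- toupper(canonical)
  if (!nzchar(canonical) ||
      length(setdiff(strsplit(canonical, "")[[1]], AA_ALPHABET_EXT))) {
    warning(sprintf("%s: unparseable sequence; entry skipped", accession),
            call. = FALSE)
    return(NULL)
  }

  # FT blocks: a new feature starts when columns 6-20 carry a key.
  ft_lines <- lines[tag == "FT"]
  features <- list()
  unknown <- character()
  key <- NULL; loc <- NULL; text <- character()
  flush <- function() {
    if (is.null(key)) return()
    if (key %in% SUPPORTED_FTYPES) {
      f <- build_feature(key, loc, paste(text, collapse = " "),
                         canonical, accession)
      if (!is.null(f)) features[[length(features) + 1L]] <<- f
    } else {
      unknown <<- c(unknown, key)
    }
  }
  for (ln in ft_lines) {
    head_field <- trimws(substr(ln, 6L, 20L))
    if (nzchar(head_field)) {
      flush()
      key <- head_field
      loc <- trimws(substring(ln, 21L))
      text <- character()
    } else {
      text <- c(text, trimws(substring(ln, 21L)))
    }
  }
  flush()
  if (length(unknown)) {
    message(sprintf("%s: ignoring unsupported feature key(s): %s", accession,
                    paste(sort(unique(unknown)), collapse = ", ")))
  }
  protein_entry(accession, entry_name, canonical, features = features)
}

#' Parse UniProt flat-file entries
#'
#' Reads zero or more concatenated UniProt flat-file (`*.txt`) records, each
#' terminated by a `//` line, into [protein_entry()] objects.  Isoforms are
#' materialized from VAR_SEQ features via [derive_isoforms()].  Features
#' whose `X -> Y` original text disagrees with the canonical sequence, or
#' whose location is uncertain, are skipped with a warning; unknown feature
#' keys are ignored with a message; entries with unparseable sequences are
#' skipped with a warning.  A trailing record without its `//` terminator
#' raises a warning (class `pepgraph_truncated_entry`) naming the accession
#' and is skipped.
#'
#' @param con a file path or text; anything [readLines()] accepts, or a
#'   character vector of lines.
#' @param derive if `TRUE` (default), materialize isoform sequences.
#' @return list of `protein_entry` in file order.
#' @examples
#' txt <- format_flatfile(protein_entry("X1", "X1_TEST", "MKAR"))
#' parse_flatfile(strsplit(txt, "\n")[[1]])
#' @export
parse_flatfile <- function(con, derive = TRUE) {
  lines <- if (is.character(con) && (length(con) > 1L || grepl("\n", con))) {
    unlist(strsplit(con, "\n"), use.names = FALSE)
  } else {
    readLines(con)
  }
  term <- which(lines == "//")
  begin <- c(1L, head(term, -1L) + 1L)
  entries <- list()
  for (i in seq_along(term)) {
    chunk <- lines[begin[i]:(term[i] - 1L)]
    chunk <- chunk[nzchar(chunk)]
    if (!length(chunk)) next
    e <- parse_one_entry(chunk)
    if (!is.null(e)) {
      if (derive) e <- derive_isoforms(e)
      entries[[length(entries) + 1L]] <- e
    }
  }
  leftover_from <- if (length(term)) term[length(term)] + 1L else 1L
  if (leftover_from <= length(lines)) {
    leftover <- lines[leftover_from:length(lines)]
    if (any(nzchar(leftover))) {
      acc <- grep("^AC ", leftover, value = TRUE)
      acc <- if (length(acc)) sub(";.*$", "", trimws(substring(acc[1], 6))) else "<unknown>"
      warning(structure(
        class = c("pepgraph_truncated_entry", "warning", "condition"),
        list(message = sprintf(
               "truncated entry '%s' (missing '//' terminator); skipped", acc),
             call = NULL)))
    }
  }
  entries
}

#' Materialize isoform sequences from VAR_SEQ features
#'
#' Applies each isoform's VAR_SEQ edits to the canonical sequence in
#' descending coordinate order, so earlier edits never shift later
#' coordinates.  Overlapping VAR_SEQ intervals for the same isoform are an
#' error naming the isoform.
#'
#' @param entry a [protein_entry()] whose VAR_SEQ features carry
#'   `isoform_scope`.
#' @return the entry with its `isoforms` map filled in.
#' @export
derive_isoforms <- function(entry) {
  vs <- Filter(function(f) f$ftype == "VAR_SEQ", entry$features)
  iso_ids <- unique(unlist(lapply(vs, `[[`, "isoform_scope"), use.names = FALSE))
  isoforms <- character()
  for (iso in iso_ids) {
    edits <- Filter(function(f) iso %in% f$isoform_scope, vs)
    starts <- vapply(edits, `[[`, integer(1), "start")
    ends <- vapply(edits, `[[`, integer(1), "end")
    o <- order(starts)
    if (any(starts[o][-1] <= ends[o][-length(o)])) {
      stop("overlapping VAR_SEQ intervals for isoform '", iso, "' in ",
           entry$accession)
    }
    seq <- entry$canonical
    for (f in edits[order(starts, decreasing = TRUE)]) {
      seq <- paste0(substr(seq, 1L, f$start - 1L), f$replacement,
                    substring(seq, f$end + 1L))
    }
    if (!nzchar(seq)) {
      warning(sprintf("%s: isoform '%s' is empty after edits; skipped",
                      entry$accession, iso), call. = FALSE)
      next
    }
    isoforms[[iso]] <- seq
  }
  entry$isoforms <- isoforms
  entry
}

# --- serialization ---------------------------------------------------------

#' Serialize a protein entry back to flat-file text
#'
#' Writes the subset of the flat-file grammar this package parses (ID, AC,
#' FT with `/note` and `/id` qualifiers, SQ, `//`), so that
#' `parse_flatfile(format_flatfile(e))` round-trips.
#'
#' @param entry a [protein_entry()].
#' @return a single string of flat-file text ending in `//`.
#' @export
format_flatfile <- function(entry) {
  out <- c(
    sprintf("ID   %-24s Reviewed; %15d AA.",
            ifelse(nzchar(entry$entry_name), entry$entry_name, entry$accession),
            nchar(entry$canonical)),
    sprintf("AC   %s;", entry$accession)
  )
  for (f in entry$features) {
    loc <- if (f$start == f$end) sprintf("%d", f$start) else
      sprintf("%d..%d", f$start, f$end)
    out <- c(out, sprintf("FT   %-15s %s", f$ftype, loc))
    note <- NULL
    if (f$ftype %in% c(SUBSTITUTION_FTYPES, "VAR_SEQ")) {
      body <- if (nzchar(f$replacement)) {
        sprintf("%s -> %s", f$original, f$replacement)
      } else "Missing"
      note <- if (length(f$isoform_scope)) {
        sprintf("%s (in %s)", body,
                paste(sprintf("isoform %s", f$isoform_scope), collapse = " and "))
      } else body
    } else if (f$ftype == "INIT_MET") {
      note <- "Removed"
    }
    if (!is.null(note)) {
      out <- c(out, sprintf("FT                   /note=\"%s\"", note))
    }
    if (nzchar(f$fid)) {
      out <- c(out, sprintf("FT                   /id=\"%s\"", f$fid))
    }
  }
  out <- c(out, sprintf("SQ   SEQUENCE %4d AA;", nchar(entry$canonical)))
  seq <- entry$canonical
  starts <- seq(1L, nchar(seq), by = 60L)
  for (s in starts) {
    block <- substr(seq, s, min(s + 59L, nchar(seq)))
    tens <- substring(block, seq(1L, nchar(block), 10L),
                      pmin(seq(10L, nchar(block) + 9L, 10L), nchar(block)))
    out <- c(out, paste0("     ", paste(tens, collapse = " ")))
  }
  paste(c(out, "//", ""), collapse = "\n")
}

#' Write sequences as FASTA
#'
#' @param headers character vector of record headers (without `>`).
#' @param sequences character vector of non-empty sequences.
#' @param path output file path or connection.
#' @param wrap line width for sequence wrapping (default 60).
#' @return invisibly, the number of records written.
#' @export
write_fasta <- function(headers, sequences, path, wrap = 60L) {
  stopifnot(length(headers) == length(sequences), wrap >= 1L)
  if (any(!nzchar(sequences))) stop("empty sequence in FASTA output")
  set <- Biostrings::AAStringSet(sequences)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(wrap))
  invisible(length(sequences))
}
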