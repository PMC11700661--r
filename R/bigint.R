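# Arbitrary-precision non-negative integers for path counting.
#
# Peptide counts on well-annotated proteins exceed 10^200, far past both
# 32-bit integers and the exact range of doubles.  The dynamic programs in
# this package only ever need addition and comparison, so counts are stored
# as little-endian limb vectors in base 1e9.  Each limb is a double holding
# an exact integer in [0, 1e9); limb sums stay far below 2^53, so all carry
# arithmetic is exact.

BIG_BASE <- 1e9

#' Arbitrary-precision non-negative integer
#'
#' Constructs a `bigint` from a single non-negative numeric or a decimal
#' string.  `bigint`s support `+`, comparison via [big_cmp()], exact decimal
#' printing via [format()], and scientific rounding via [big_signif()].
#' They exist so that exact peptide-path counts (which reach beyond 10^200)
#' never overflow.
#'
#' @param x a non-negative integer-valued numeric `< 2^53`, or a string of
#'   decimal digits.
#' @return an object of class `bigint`.
#' @examples
#' bigint(12) + bigint("999999999999999999999")
#' @export
bigint <- function(x = 0) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L, grepl("^[0-9]+$", x))
    x <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(x)
    starts <- rev(seq(n, 1L, by = -9L))
    limbs <- rev(vapply(starts, function(s) {
      as.numeric(substr(x, max(1L, s - 8L), s))
    }, numeric(1)))
    return(structure(list(limbs = big_trim(limbs)), class = "bigint"))
  }
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
    if (x == 0) break
  }
  structure(list(limbs = limbs), class = "bigint")
}

big_trim <- function(limbs) {
  while (length(limbs) > 1L && limbs[length(limbs)] == 0) {
    limbs <- limbs[-length(limbs)]
  }
  limbs
}

big_add <- function(a, b) {
  la <- a$limbs; lb <- b$limbs
  n <- max(length(la), length(lb))
  la <- c(la, numeric(n - length(la)))
  lb <- c(lb, numeric(n - length(lb)))
  s <- la + lb
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= BIG_BASE) 1 else 0
    if (carry) s[i] <- s[i] - BIG_BASE
  }
  if (carry) s <- c(s, 1)
  structure(list(limbs = s), class = "bigint")
}

#' @export
`+.bigint` <- function(e1, e2) big_add(bigint(e1), bigint(e2))

#' Compare two bigints
#'
#' @param a,b `bigint`s (or values coercible via [bigint()]).
#' @return -1, 0 or 1 as `a` is less than, equal to or greater than `b`.
#' @export
big_cmp <- function(a, b) {
  a <- bigint(a); b <- bigint(b)
  if (length(a$limbs) != length(b$limbs)) {
    return(if (length(a$limbs) < length(b$limbs)) -1L else 1L)
  }
  for (i in rev(seq_along(a$limbs))) {
    if (a$limbs[i] != b$limbs[i]) {
      return(if (a$limbs[i] < b$limbs[i]) -1L else 1L)
    }
  }
  0L
}

#' @export
`==.bigint` <- function(e1, e2) big_cmp(e1, e2) == 0L

#' @export
format.bigint <- function(x, ...) {
  limbs <- rev(x$limbs)
  out <- sprintf("%.0f", limbs[1])
  if (length(limbs) > 1L) {
    out <- paste0(out, paste(sprintf("%09.0f", limbs[-1]), collapse = ""))
  }
  out
}

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' Approximate a bigint as a double
#'
#' Exact while the value fits in 2^53; the leading ~15 significant digits
#' otherwise.  Used for reporting, never for counting.
#' @param x a `bigint`.
#' @return a double.
#' @export
big_as_numeric <- function(x) {
  sum(x$limbs * BIG_BASE^(seq_along(x$limbs) - 1L))
}

#' Scientific rendering of a bigint
#'
#' Formats counts the way search-space magnitudes are usually quoted,
#' e.g. `"1.7287E224"`.
#' @param x a `bigint`.
#' @param digits significant digits after the leading one.
#' @return a string like `"1.7287E224"`, or the plain integer when it has
#'   fewer than `digits + 1` digits.
#' @export
big_signif <- function(x, digits = 4L) {
  s <- format(x)
  if (nchar(s) <= digits) return(s)
  mant <- paste0(substr(s, 1L, 1L), ".", substr(s, 2L, digits + 1L))
  # round the mantissa using the next digit
  nxt <- as.integer(substr(s, digits + 2L, digits + 2L))
  if (!is.na(nxt) && nxt >= 5L) {
    m <- as.numeric(mant) + 10^(-digits)
    mant <- sprintf(paste0("%.", digits, "f"), m)
    if (as.numeric(mant) >= 10) {
      return(sprintf("%sE%d", sprintf(paste0("%.", digits, "f"),
                                      as.numeric(mant) / 10),
                     nchar(s)))
    }
  }
  sprintf("%sE%d", mant, nchar(s) - 1L)
}

big_sum <- function(xs) {
  acc <- bigint(0)
  for (x in xs) acc <- big_add(acc, bigint(x))
  acc
}
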