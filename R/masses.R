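# Monoisotopic mass bookkeeping.
#
# All internal mass arithmetic is fixed-point: Dalton values scaled by 1e9
# and stored in doubles.  A 5000 Da peptide is 5e12 on this grid, far below
# 2^53, so additions and comparisons are exact and platform-independent.
# Floating-point Daltons appear only at I/O boundaries.

MASS_SCALE <- 1e9

#' Scale a mass in Dalton to the fixed-point integer grid
#' @param da mass in Dalton.
#' @return integer-valued double on the 1e-9 Da grid.
#' @export
mass_scale <- function(da) round(da * MASS_SCALE)

#' Convert a fixed-point mass back to Dalton
#' @param x integer-valued double on the 1e-9 Da grid.
#' @return mass in Dalton.
#' @export
mass_unscale <- function(x) x / MASS_SCALE

#' Default monoisotopic residue masses
#'
#' Standard monoisotopic residue (amino-acid minus water) masses in Dalton,
#' including selenocysteine (U) and pyrrolysine (O).  The ambiguity codes
#' B, Z and X carry no mass: vertices containing them are flagged and any
#' peptide traversing them is excluded from mass queries.
#'
#' @return named numeric vector of masses in Dalton.
#' @export
default_residue_masses <- function() {
  c(G = 57.02146373, A = 71.03711379, S = 87.03202841, P = 97.05276385,
    V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
    I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
    K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
    F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295,
    U = 150.95364, O = 237.14773)
}

#' Physical constants used in precursor mass arithmetic
#'
#' Water is added once per peptide (the termini); the proton mass converts
#' an observed m/z and charge into a neutral mass.  Both are overridable in
#' the functions that consume them.
#' @name mass-constants
#' @export
WATER_MONO <- 18.010565

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.007276466

#' Enzyme cleavage rule
#'
#' @param name rule name, e.g. `"trypsin"`.
#' @param cut_after residues after which the backbone is cleaved.
#' @param blocked_by_next residues that suppress cleavage when they follow
#'   the cut site (proline for trypsin).
#' @param unspecific if `TRUE`, every peptide bond is a cleavage site and
#'   `cut_after`/`blocked_by_next` are ignored.
#' @return an `enzyme_rule` object.
#' @examples
#' enzyme_trypsin()
#' @export
enzyme_rule <- function(name, cut_after = character(),
                        blocked_by_next = character(), unspecific = FALSE) {
  structure(list(name = name,
                 cut_after = cut_after,
                 blocked_by_next = blocked_by_next,
                 unspecific = isTRUE(unspecific)),
            class = "enzyme_rule")
}

#' @rdname enzyme_rule
#' @export
enzyme_trypsin <- function() {
  enzyme_rule("trypsin", cut_after = c("K", "R"), blocked_by_next = "P")
}

#' @rdname enzyme_rule
#' @export
enzyme_unspecific <- function() {
  enzyme_rule("unspecific", unspecific = TRUE)
}

#' Post-translational modification configuration
#'
#' Fixed modifications shift the residue mass wherever the residue occurs;
#' variable modifications branch during mass queries: each occurrence is
#' emitted both with and without the delta, subject to
#' `max_variable_per_peptide`.
#'
#' @param fixed named numeric vector, residue -> mass delta (Da).
#' @param variable named list, residue -> numeric vector of optional mass
#'   deltas (Da).
#' @param max_variable_per_peptide cap on applied variable deltas per
#'   peptide.
#' @return a `ptm_config` object.
#' @examples
#' ptm_config(fixed = c(C = 57.02146), variable = list(M = 15.994915))
#' @export
ptm_config <- function(fixed = numeric(), variable = list(),
                       max_variable_per_peptide = 3L) {
  if (length(variable) && !is.list(variable)) {
    variable <- as.list(variable)
  }
  stopifnot(all(is.finite(unlist(c(fixed, variable), use.names = FALSE))),
            max_variable_per_peptide >= 0)
  structure(list(fixed = fixed, variable = variable,
                 max_variable_per_peptide = as.integer(max_variable_per_peptide)),
            class = "ptm_config")
}
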