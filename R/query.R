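# Bound-pruned enumeration of peptides by monoisotopic mass window.
#
# The traversal is a depth-first walk over the CSR graph from s, expanding
# edges in stored order.  A partial path with accumulated fixed-point mass
# m is pruned as soon as m + min_remaining > hi or m + max_remaining < lo;
# this is the interval extension of a target-value search.  The worst case
# is exponential in the number of vertices (O(2^(n-1)) complete paths on a
# fully branched graph), which is why pruning, per-peptide limits, and a
# cooperative timeout all exist.

#' Mass interval in Dalton
#'
#' Builds the fixed-point query window; bounds are rounded outward to the
#' 1e-9 Da grid so no floating-point boundary case can drop a peptide.
#'
#' @param lo,hi interval bounds in Dalton, `0 <= lo <= hi` (`hi` may be
#'   `Inf`).
#' @return a `mass_interval` with scaled integer fields `lo`, `hi`.
#' @export
mass_interval <- function(lo, hi) {
  stopifnot(lo >= 0, lo <= hi)
  structure(list(lo = floor(lo * MASS_SCALE), hi = ceiling(hi * MASS_SCALE)),
            class = "mass_interval")
}

#' Convert a precursor observation to a neutral-mass query window
#'
#' The neutral mass is `M = mz * z - z * proton`; the window is
#' `[M * (1 - tol_ppm * 1e-6), M * (1 + tol_ppm * 1e-6)]`, rounded outward
#' to the fixed-point grid.
#'
#' @param mz observed precursor m/z in Dalton per charge.
#' @param z charge state (positive integer).
#' @param tol_ppm symmetric tolerance in parts per million.
#' @param proton proton mass in Dalton.
#' @return a [mass_interval()].
#' @examples
#' precursor_to_interval(500.0, 2L, 10)
#' @export
precursor_to_interval <- function(mz, z, tol_ppm, proton = PROTON_MASS) {
  stopifnot(mz > 0, z >= 1, tol_ppm >= 0)
  m <- mz * z - z * proton
  if (m <= 0) stop("non-positive neutral mass from mz=", mz, ", z=", z)
  mass_interval(m * (1 - tol_ppm * 1e-6), m * (1 + tol_ppm * 1e-6))
}

#' Per-query traversal limits
#'
#' @param max_variants maximum distinct VARIANT feature ids per peptide.
#' @param max_features maximum distinct feature ids of any type per
#'   peptide.
#' @param max_miscleavages maximum cleaved edges per peptide.
#' @param timeout cooperative wall-clock limit in seconds (`Inf` = none);
#'   on expiry the hits found so far are returned with `completed = FALSE`.
#' @param max_hits stop after this many hits (`Inf` = none), also flagged
#'   as incomplete.
#' @param check_every expansions between timeout checks.
#' @return a `query_limits` object.
#' @export
query_limits <- function(max_variants = Inf, max_features = Inf,
                         max_miscleavages = Inf, timeout = Inf,
                         max_hits = Inf, check_every = 4096L) {
  stopifnot(max_variants >= 0, max_features >= 0, max_miscleavages >= 0,
            timeout > 0, max_hits >= 0, check_every >= 1)
  structure(list(max_variants = max_variants, max_features = max_features,
                 max_miscleavages = max_miscleavages, timeout = timeout,
                 max_hits = max_hits, check_every = as.integer(check_every)),
            class = "query_limits")
}

# Enumerate variable-modification choices for one vertex: subsets of mod
# rows with pairwise-distinct residue offsets, at most `budget` applied.
# Deterministic order: the empty choice first, then by lexicographic row
# index.  Returns list of list(rows=, dsum=).
mod_choices <- function(mods, budget) {
  base <- list(list(rows = integer(), dsum = 0))
  if (is.null(mods) || budget < 1 || nrow(mods) == 0L) return(base)
  k <- nrow(mods)
  acc <- base
  grow <- function(rows, dsum, from) {
    for (i in from:k) {
      if (mods$offset[i] %in% mods$offset[rows]) next
      r2 <- c(rows, i)
      acc[[length(acc) + 1L]] <<- list(rows = r2,
                                       dsum = dsum + mods$delta[i])
      if (length(r2) < budget && i < k) grow(r2, dsum + mods$delta[i], i + 1L)
    }
  }
  grow(integer(), 0, 1L)
  acc
}

#' Enumerate all peptides in a mass window
#'
#' Depth-first traversal of a CSR protein-graph emitting every complete
#' s -> e path whose final monoisotopic mass (vertex masses + water +
#' applied variable-modification deltas) lies in the query interval.
#' Result order is deterministic.  Paths violating the limits, or entering
#' a vertex with a mass-less residue, are pruned.  The completion flag is
#' `FALSE` iff a timeout or `max_hits` truncated the search.
#'
#' @param csr a `csr_graph`.
#' @param interval a [mass_interval()].
#' @param limits a [query_limits()].
#' @param bounds matrix from [precompute_bounds()]; computed on the fly if
#'   missing.
#' @param prune set `FALSE` to disable bound pruning (the hit set must not
#'   change; used for soundness checks).
#' @param water terminal water mass in Dalton, pre-added at `s`.
#' @return list with `hits` (list of `peptide_hit`) and `completed`
#'   (logical).  Each hit has `path` (CSR vertex ids), `sequence`, `mass`
#'   (fixed-point), `mass_da`, `miscleavages`, `feature_ids`,
#'   `variable_mods` (data.frame of peptide position and delta in Da),
#'   `chain`, `start`, `end`.
#' @examples
#' g <- build_protein_graph(protein_entry("X", "X_T", "MKAR"))
#' query_csr(to_csr(g), mass_interval(245, 246))
#' @export
query_csr <- function(csr, interval, limits = query_limits(), bounds = NULL,
                      prune = TRUE, water = WATER_MONO) {
  stopifnot(inherits(csr, "csr_graph"), inherits(interval, "mass_interval"))
  if (is.null(bounds)) bounds <- precompute_bounds(csr)
  lo <- interval$lo; hi <- interval$hi
  minr <- bounds[, 1L]; maxr <- bounds[, 2L]
  s <- 1L; e <- csr$n
  water_fp <- mass_scale(water)

  # feature ids newly introduced per edge (distinct-per-path semantics)
  is_variant <- csr$fid_type == "VARIANT"
  newf <- lapply(seq_len(csr$m), function(i) integer(0))
  for (v in seq_len(csr$n)) {
    for (i in eoff_edges(csr, v)) {
      w <- csr$etarget[i]
      newf[[i]] <- setdiff(union(csr$efid[[i]], csr$vfid[[w]]), csr$vfid[[v]])
    }
  }

  hits <- list()
  completed <- TRUE
  expansions <- 0L
  t0 <- Sys.time()

  # explicit DFS stack; each frame: vertex, remaining out-edge indices,
  # accumulated mass, miscleavages, variant/feature fid sets, mods so far
  stack <- list(list(v = s, edges = eoff_edges(csr, s), mass = water_fp,
                     misc = 0L, fids = integer(), mods = NULL, off = 0L,
                     path = s))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    if (!length(top$edges)) {
      stack[[length(stack)]] <- NULL
      next
    }
    i <- top$edges[1L]
    stack[[length(stack)]]$edges <- top$edges[-1L]

    expansions <- expansions + 1L
    if (expansions %% limits$check_every == 0L &&
        is.finite(limits$timeout) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > limits$timeout) {
      completed <- FALSE
      break
    }

    w <- csr$etarget[i]
    misc <- top$misc + (csr$eflags[i] != 0L)
    if (misc > limits$max_miscleavages) next
    fids <- if (length(newf[[i]])) union(top$fids, newf[[i]]) else top$fids
    if (length(fids) > limits$max_features) next
    if (sum(is_variant[fids]) > limits$max_variants) next

    if (w == e) {
      if (top$mass >= lo && top$mass <= hi) {
        first <- top$path[2L]
        last <- top$path[length(top$path)]
        mods_df <- top$mods
        hits[[length(hits) + 1L]] <- structure(list(
          path = top$path, sequence = paste(csr$aa[top$path], collapse = ""),
          mass = top$mass, mass_da = mass_unscale(top$mass),
          miscleavages = misc, feature_ids = csr$fids[sort(fids)],
          variable_mods = mods_df,
          chain = csr$chains[csr$vchain[first]],
          start = csr$pos_start[first], end = csr$pos_end[last],
          start_virtual = bitwAnd(csr$vflags[first], 2L) > 0L
        ), class = "peptide_hit")
        if (length(hits) >= limits$max_hits) {
          completed <- FALSE
          break
        }
      }
      next
    }
    if (bitwAnd(csr$vflags[w], 1L) != 0L) next  # mass-less: not queryable
    if (prune &&
        (top$mass + minr[w] > hi || top$mass + maxr[w] < lo)) next

    n_applied <- if (is.null(top$mods)) 0L else nrow(top$mods)
    budget <- csr$max_var_mods - n_applied
    for (choice in mod_choices(csr$vmods[[w]], budget)) {
      mods <- top$mods
      if (length(choice$rows)) {
        add <- csr$vmods[[w]][choice$rows, , drop = FALSE]
        add$position <- top$off + add$offset
        mods <- rbind(mods, add[, c("position", "delta")])
      }
      stack[[length(stack) + 1L]] <- list(
        v = w, edges = eoff_edges(csr, w),
        mass = top$mass + csr$mass[w] + choice$dsum,
        misc = misc, fids = fids, mods = mods,
        off = top$off + nchar(csr$aa[w]),
        path = c(top$path, w))
    }
  }
  for (k in seq_along(hits)) {
    if (!is.null(hits[[k]]$variable_mods)) {
      hits[[k]]$variable_mods$delta <- mass_unscale(hits[[k]]$variable_mods$delta)
    }
  }
  list(hits = hits, completed = completed)
}

#' @export
print.peptide_hit <- function(x, ...) {
  cat(sprintf("<peptide %s  %.5f Da  mssclvg:%d  %s>\n", x$sequence,
              x$mass_da, x$miscleavages,
              if (length(x$feature_ids)) paste(x$feature_ids, collapse = ";")
              else "canonical"))
  invisible(x)
}

#' Estimate the exportable feature limit for a mass window
#'
#' Counts paths per (feature count, coarse mass bin) with a dynamic
#' program, then returns the largest `k` such that the number of peptides
#' using at most `k` distinct features in the bins intersecting the query
#' interval stays within `budget`.  Returns `Inf` when even the unlimited
#' count fits, and 0 when feature-free peptides alone exceed the budget
#' (the query then runs with that cap and flags truncation).  Mass binning
#' is coarse (bin lower edges accumulate), so the estimate is approximate
#' by design; counts saturate at the budget rather than growing without
#' bound.
#'
#' @param csr a `csr_graph`.
#' @param interval a [mass_interval()].
#' @param budget maximum acceptable peptide count (>= 1).
#' @param bin_width mass bin width in Dalton.
#' @param water terminal water mass in Dalton.
#' @return largest admissible feature count `k` (0, a positive integer, or
#'   `Inf`).
#' @export
estimate_feature_limit <- function(csr, interval, budget, bin_width = 25,
                                   water = WATER_MONO) {
  stopifnot(budget >= 1)
  w_fp <- mass_scale(bin_width)
  hi_bin <- if (is.finite(interval$hi)) {
    as.integer(interval$hi %/% w_fp) + 1L
  } else NA_integer_
  nbin <- if (is.na(hi_bin)) 1L else hi_bin + 1L  # last bin absorbs > hi

  esrc <- rep(seq_len(csr$n), times = diff(csr$eoff))
  newf <- lapply(seq_len(csr$m), function(i) {
    setdiff(union(csr$efid[[i]], csr$vfid[[csr$etarget[i]]]),
            csr$vfid[[esrc[i]]])
  })
  kmax <- length(csr$fids)
  cap <- budget * 2  # saturation: only comparisons to budget matter

  # state[v]: (kmax+1) x nbin matrix of saturating counts
  states <- rep(list(NULL), csr$n)
  m0 <- matrix(0, kmax + 1L, nbin)
  binof <- function(mass) {
    if (is.na(hi_bin)) return(1L)
    min(as.integer(mass %/% w_fp) + 1L, nbin)
  }
  start <- m0; start[1L, binof(mass_scale(water))] <- 1
  states[[1L]] <- start
  for (v in seq_len(csr$n)) {
    sv <- states[[v]]
    if (is.null(sv)) next
    for (i in eoff_edges(csr, v)) {
      w <- csr$etarget[i]
      if (w != csr$n && bitwAnd(csr$vflags[w], 1L) != 0L) next
      dk <- length(newf[[i]])
      dm <- if (w == csr$n) 0 else csr$mass[w]
      tw <- states[[w]]
      if (is.null(tw)) tw <- m0
      for (k in seq_len(kmax + 1L)) {
        row <- sv[k, ]
        if (!any(row > 0)) next
        k2 <- min(k + dk, kmax + 1L)
        for (b in which(row > 0)) {
          b2 <- if (is.na(hi_bin)) 1L else
            min(as.integer(((b - 1L) * w_fp + dm) %/% w_fp) + 1L, nbin)
          tw[k2, b2] <- min(tw[k2, b2] + row[b], cap)
        }
      }
      states[[w]] <- tw
    }
  }
  final <- states[[csr$n]]
  if (is.null(final)) return(Inf)
  sel <- if (is.na(hi_bin)) rep(TRUE, nbin) else {
    edges_lo <- ((seq_len(nbin) - 1L)) * w_fp
    edges_hi <- edges_lo + w_fp
    edges_hi >= interval$lo & edges_lo <= interval$hi
  }
  per_k <- rowSums(final[, sel, drop = FALSE])
  cum <- cumsum(per_k)
  if (cum[length(cum)] <= budget) return(Inf)
  k <- max(which(cum <= budget) - 1L, -1L)
  max(k, 0L)
}
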