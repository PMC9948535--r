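#' Discrete torsion of a chain
#'
#' Computes, at every interior vertex where the five-point stencil fits,
#' the discrete analogue of the Frenet torsion
#' `tau = ((r' x r'') . r''') / |r' x r''|^2`
#' with central finite differences
#' `r'_i = (r_{i+1} - r_{i-1}) / 2`,
#' `r''_i = r_{i+1} - 2 r_i + r_{i-1}`,
#' `r'''_i = (r_{i+2} - 2 r_{i+1} + 2 r_{i-1} - r_{i-2}) / 2`.
#' The ratio is invariant under a uniform rescaling of the index step, so
#' torsion comes out in units of inverse bond length for a rigid-bond chain.
#' Vertices where the local curve is straight (`|r' x r''|` below
#' tolerance) are skipped, not imputed; `n_valid` counts the rest.
#'
#' Torsion is positive for right-handed local twist and changes sign under
#' mirror reflection.
#'
#' @param conf A [conformation()] or any vertex matrix with at least 5 rows.
#' @param tol Degeneracy tolerance on `|r' x r''|^2` (locally straight
#'   vertices are excluded below it).
#' @return A list with `tau_i` (per-vertex values, `NA` where undefined),
#'   `tau_mean` (mean over defined vertices), and `n_valid`.
#' @examples
#' h <- make_curve(helix_spec(a = 1, c = 0.2, turns = 5, n_vertices = 400))
#' discrete_torsion(h)$tau_mean  # close to c / (a^2 + c^2)
#' @export
discrete_torsion <- function(conf, tol = 1e-12) {
  v <- unclass(as.matrix(conf))
  n <- nrow(v)
  if (n < 5L) stop("discrete torsion needs at least 5 vertices (N >= 4)")
  i <- 3:(n - 2L)
  r1 <- (v[i + 1L, , drop = FALSE] - v[i - 1L, , drop = FALSE]) / 2
  r2 <- v[i + 1L, , drop = FALSE] - 2 * v[i, , drop = FALSE] +
    v[i - 1L, , drop = FALSE]
  r3 <- (v[i + 2L, , drop = FALSE] - 2 * v[i + 1L, , drop = FALSE] +
           2 * v[i - 1L, , drop = FALSE] - v[i - 2L, , drop = FALSE]) / 2
  cxx <- r1[, 2L] * r2[, 3L] - r1[, 3L] * r2[, 2L]
  cyy <- r1[, 3L] * r2[, 1L] - r1[, 1L] * r2[, 3L]
  czz <- r1[, 1L] * r2[, 2L] - r1[, 2L] * r2[, 1L]
  denom <- cxx^2 + cyy^2 + czz^2
  num <- cxx * r3[, 1L] + cyy * r3[, 2L] + czz * r3[, 3L]
  tau <- ifelse(denom > tol, num / denom, NA_real_)
  list(tau_i = tau,
       tau_mean = if (any(!is.na(tau))) mean(tau, na.rm = TRUE) else NA_real_,
       n_valid = sum(!is.na(tau)))
}

#' Ensemble-averaged torsion of a trajectory
#'
#' Averages the chain-mean torsion over frames (each chain weighted
#' equally) and reports the standard error of the mean.
#'
#' @param trajectory A `"trajectory"` from [reptation_run()], or a plain
#'   list of conformations.
#' @return A list with `tau` (ensemble mean), `se` (standard error), and
#'   `n` (number of frames contributing).
#' @export
ensemble_torsion <- function(trajectory) {
  frames <- if (inherits(trajectory, "trajectory")) trajectory$frames else
    trajectory
  if (length(frames) < 2L) stop("need at least 2 frames")
  tm <- vapply(frames, function(f) discrete_torsion(f)$tau_mean, numeric(1))
  tm <- tm[!is.na(tm)]
  n <- length(tm)
  list(tau = mean(tm), se = stats::sd(tm) / sqrt(n), n = n)
}

#' Variance of the chiral energy (heat-capacity-like fluctuation measure)
#'
#' Computes the population variance of the per-frame chiral energy,
#' normalized by `|u|` and by the segment count `N` so that chains of
#' different length are comparable:
#' `C_c = (<E_c^2> - <E_c>^2) / (|u| N)`.
#' The standard error follows the fluctuation-average formula for a
#' variance, `se(var) = sqrt((m4 - var^2) / n)` with `m4` the fourth
#' central moment, propagated through the normalization.
#'
#' @param trajectory A `"trajectory"` (its stored `E_chiral` column is
#'   used), or a numeric vector of chiral energies.
#' @param params A [model_params()]; required when `trajectory` is a plain
#'   vector, otherwise defaults to the trajectory's own parameters.
#' @return A list with `mean_Ec`, `var_Ec`, `C_c`, `se_Cc`, and `n`.
#'   At `u = 0` the normalized quantities are `NA` with a `reason` field.
#' @export
chiral_variance <- function(trajectory, params = NULL) {
  if (inherits(trajectory, "trajectory")) {
    ec <- trajectory$energies$E_chiral
    if (is.null(params)) params <- trajectory$params
  } else {
    ec <- as.numeric(trajectory)
  }
  stopifnot(inherits(params, "model_params"))
  if (length(ec) < 2L) stop("need at least 2 frames")
  n <- length(ec)
  m <- mean(ec)
  v <- mean((ec - m)^2) # population variance
  if (params$u == 0) {
    return(list(mean_Ec = m, var_Ec = v, C_c = NA_real_, se_Cc = NA_real_,
                n = n, reason = "C_c undefined at u = 0"))
  }
  norm <- abs(params$u) * params$N
  m4 <- mean((ec - m)^4)
  se_var <- sqrt(max(0, m4 - v^2) / n)
  list(mean_Ec = m, var_Ec = v, C_c = v / norm, se_Cc = se_var / norm, n = n)
}
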