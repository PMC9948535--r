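#' Energies of the chiral worm-like chain Hamiltonian
#'
#' The Hamiltonian (in units of kT) is the sum of three terms:
#' a bending energy `-eps_b * sum_i t_i . t_{i+1}` over consecutive segment
#' tangents, a chiral coupling
#' `u * sum_{0 < j - i <= d} (t_i x t_j) . rhat_ij`
#' over segment pairs up to `d` apart along the contour (`rhat_ij` is the
#' unit vector between segment centers, oriented from `i` to `j`; the sign
#' of the kernel is fixed so that a right-handed helix is favoured for
#' `u > 0`), and a
#' hard-core term that is `+Inf` whenever two segment centers separated by
#' at least `floor(4R/b)` segments along the contour come closer than `2R`.
#'
#' With `u > 0` the chiral term favours right-handed helical twist, with
#' `u < 0` left-handed twist. Pairs with coincident centers contribute zero
#' to the chiral sum.
#'
#' @param conf A [conformation()].
#' @param params A [model_params()]; its `N` must match `conf`.
#' @return `bending_energy()` and `chiral_energy()` return a scalar energy
#'   in kT; `hardcore_overlap()` returns `TRUE`/`FALSE`; `total_energy()`
#'   returns a list with fields `E_bend`, `E_chiral`, `hardcore_violated`,
#'   and `total` (`+Inf` when the hard core is violated).
#' @examples
#' p <- model_params(eps_b = 4, u = 0.5, d = 10, N = 10)
#' total_energy(straight_rod(10), p)
#' @export
bending_energy <- function(conf, params) {
  check_conf_params(conf, params)
  t <- segment_vectors(conf)
  n <- nrow(t)
  -params$eps_b * sum(t[-n, , drop = FALSE] * t[-1L, , drop = FALSE])
}

#' @rdname bending_energy
#' @export
chiral_energy <- function(conf, params) {
  check_conf_params(conf, params)
  if (params$u == 0 || params$d == 0L) return(0)
  t <- segment_vectors(conf)
  ctr <- segment_centers(conf)
  n <- nrow(t)
  acc <- 0
  for (k in seq_len(min(params$d, n - 1L))) {
    i <- seq_len(n - k)
    j <- i + k
    ti <- t[i, , drop = FALSE]
    tj <- t[j, , drop = FALSE]
    cx <- ti[, 2L] * tj[, 3L] - ti[, 3L] * tj[, 2L]
    cy <- ti[, 3L] * tj[, 1L] - ti[, 1L] * tj[, 3L]
    cz <- ti[, 1L] * tj[, 2L] - ti[, 2L] * tj[, 1L]
    rij <- ctr[j, , drop = FALSE] - ctr[i, , drop = FALSE]
    nrm <- sqrt(rowSums(rij^2))
    dot <- cx * rij[, 1L] + cy * rij[, 2L] + cz * rij[, 3L]
    ok <- nrm > 0
    acc <- acc + sum(dot[ok] / nrm[ok])
  }
  params$u * acc
}

#' @rdname bending_energy
#' @export
hardcore_overlap <- function(conf, params) {
  check_conf_params(conf, params)
  if (params$R == 0) return(FALSE)
  ctr <- segment_centers(conf)
  n <- nrow(ctr)
  w <- max(exclusion_window(params), 1L)
  lim2 <- (2 * params$R)^2
  if (w > n - 1L) return(FALSE)
  for (k in w:(n - 1L)) {
    i <- seq_len(n - k)
    d2 <- rowSums((ctr[i + k, , drop = FALSE] - ctr[i, , drop = FALSE])^2)
    if (any(d2 <= lim2)) return(TRUE)
  }
  FALSE
}

#' @rdname bending_energy
#' @export
total_energy <- function(conf, params) {
  eb <- bending_energy(conf, params)
  ec <- chiral_energy(conf, params)
  hc <- hardcore_overlap(conf, params)
  list(E_bend = eb, E_chiral = ec, hardcore_violated = hc,
       total = if (hc) Inf else eb + ec)
}

check_conf_params <- function(conf, params) {
  stopifnot(inherits(params, "model_params"))
  if (n_segments(conf) != params$N) {
    stop(sprintf("conformation has %d segments but params$N = %d",
                 n_segments(conf), params$N))
  }
  invisible(TRUE)
}
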