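#' Monte Carlo run configuration
#'
#' @param n_samples Number of conformations to store.
#' @param equilibration_moves Moves discarded before the first stored sample
#'   (default `50 * N`, resolved at run time when `NULL`).
#' @param moves_per_sample Moves between stored samples (default `5 * N`).
#' @param seed Integer seed; recorded in every output artifact.
#' @param head_tail_prob Probability of growing at the head end (default 0.5).
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(n_samples = 1000, equilibration_moves = NULL,
                      moves_per_sample = NULL, seed = 1,
                      head_tail_prob = 0.5) {
  stopifnot(
    n_samples >= 0,
    is.null(equilibration_moves) || equilibration_moves >= 0,
    is.null(moves_per_sample) || moves_per_sample >= 0,
    head_tail_prob >= 0, head_tail_prob <= 1,
    is.numeric(seed), length(seed) == 1L
  )
  structure(
    list(n_samples = as.integer(n_samples),
         equilibration_moves = equilibration_moves,
         moves_per_sample = moves_per_sample,
         seed = as.integer(seed),
         head_tail_prob = as.numeric(head_tail_prob)),
    class = "mc_config"
  )
}

#' Propose a single reptation move
#'
#' Deletes the terminal segment at one chain end (head with probability
#' `head_tail_prob`, else tail) and appends a new segment at the opposite
#' end whose direction is drawn uniformly on the unit sphere. Uses R's
#' global random number stream; seed with [set.seed()] for reproducibility.
#'
#' @param conf A [conformation()].
#' @param params A [model_params()].
#' @param head_tail_prob Probability of growing at the head (vertex `N`) end.
#' @return The proposed [conformation()] (same segment count, rigid bonds).
#' @export
propose_reptation <- function(conf, params, head_tail_prob = 0.5) {
  check_conf_params(conf, params)
  b <- params$b
  v <- unclass(conf)
  n <- nrow(v)
  omega <- random_unit_vector()
  if (stats::runif(1) < head_tail_prob) {
    w <- v[n, ] + b * omega
    out <- rbind(v[-1L, , drop = FALSE], w)
  } else {
    w <- v[1L, ] - b * omega
    out <- rbind(w, v[-n, , drop = FALSE])
  }
  dimnames(out) <- NULL
  conformation(out, b = b, validate = FALSE)
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(max(0, 1 - z^2))
  c(s * cos(phi), s * sin(phi), z)
}

#' Metropolis acceptance for an energy difference
#'
#' Accepts with probability `min(1, exp(-delta_H))`; an infinite energy
#' difference (hard-core violation) is always rejected. Uses R's global
#' random number stream.
#'
#' @param delta_H Energy difference in kT; may be `+Inf`.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
metropolis_accept <- function(delta_H) {
  if (is.infinite(delta_H) && delta_H > 0) return(FALSE)
  if (delta_H <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_H)
}

#' Sample the chiral WLC ensemble by reptation Monte Carlo
#'
#' Runs a Metropolis reptation chain: each move deletes the terminal
#' segment at one end and regrows a segment with uniform-on-sphere
#' direction at the other end, accepted with probability
#' `min(1, exp(-delta_H))` under the full Hamiltonian. The initial
#' conformation is a straight rod, which is overlap-free for every
#' hard-core radius; the equilibration phase is discarded.
#'
#' @param params A [model_params()].
#' @param mc An [mc_config()]. `NULL` entries for the move counts resolve to
#'   `50 * N` equilibration moves and `5 * N` moves per sample.
#' @return An object of class `"trajectory"`: a list with `frames` (list of
#'   [conformation()]s), `energies` (data frame with the incrementally
#'   tracked `E_bend`, `E_chiral` per frame), `params`, `mc`,
#'   `acceptance_rate`, and `seed`.
#' @examples
#' tr <- reptation_run(model_params(eps_b = 2, N = 20),
#'                     mc_config(n_samples = 10, seed = 42))
#' tr$acceptance_rate
#' @export
reptation_run <- function(params, mc = mc_config()) {
  stopifnot(inherits(params, "model_params"), inherits(mc, "mc_config"))
  equil <- if (is.null(mc$equilibration_moves)) 50 * params$N else
    mc$equilibration_moves
  per_sample <- if (is.null(mc$moves_per_sample)) 5 * params$N else
    mc$moves_per_sample
  init <- straight_rod(params$N, b = params$b)
  set.seed(mc$seed)
  res <- cpp_run_reptation(unclass(init), params$eps_b, params$u, params$d,
                           params$R, params$b, mc$n_samples, equil,
                           per_sample, mc$head_tail_prob)
  frames <- lapply(res$frames, conformation, b = params$b, validate = FALSE)
  structure(
    list(frames = frames,
         energies = data.frame(E_bend = res$E_bend, E_chiral = res$E_chiral),
         params = params,
         mc = mc,
         acceptance_rate = res$acceptance_rate,
         seed = mc$seed),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Reptation MC trajectory: %d frames, N = %d, u = %g, R = %g\n",
    length(x$frames), x$params$N, x$params$u, x$params$R))
  cat(sprintf("  seed = %d, acceptance rate = %.3f\n", x$seed,
              x$acceptance_rate))
  invisible(x)
}
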