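#' Model parameters for the chiral worm-like chain
#'
#' Bundles the Hamiltonian and geometry parameters of the chiral WLC model:
#' a bending stiffness acting on consecutive segments, a short-range chiral
#' coupling acting on segment pairs up to `d` apart along the contour, and a
#' spherical hard core of radius `R` around each segment center. All energies
#' are expressed in units of the thermal energy kT and all lengths in units
#' of the bond length `b`.
#'
#' @param eps_b Bending stiffness (kT). Larger values stiffen the chain.
#' @param u Chiral coupling strength (kT). `u > 0` promotes right-handed
#'   helices, `u < 0` left-handed ones, `u = 0` an achiral chain.
#' @param d Chiral coupling range: segment pairs with contour separation
#'   `1..d` interact (non-negative integer).
#' @param R Hard-core radius around each segment center, in units of `b`.
#'   Pairs separated by fewer than `floor(4 R / b)` segments along the
#'   contour are exempt from the hard core.
#' @param b Bond length (the length unit; default 1).
#' @param N Number of segments; the chain has `N + 1` vertices.
#'
#' @return An object of class `"model_params"`: a named list with fields
#'   `eps_b`, `u`, `d`, `R`, `b`, `N`.
#' @examples
#' p <- model_params(eps_b = 4, u = 0.5, d = 10, R = 0.5, N = 200)
#' exclusion_window(p)
#' @export
model_params <- function(eps_b = 4, u = 0, d = 10, R = 0, b = 1, N = 200) {
  stopifnot(
    is.numeric(eps_b), length(eps_b) == 1L, is.finite(eps_b),
    is.numeric(u), length(u) == 1L, is.finite(u),
    is.numeric(d), length(d) == 1L, d >= 0, d == as.integer(d),
    is.numeric(R), length(R) == 1L, is.finite(R), R >= 0,
    is.numeric(b), length(b) == 1L, is.finite(b), b > 0,
    is.numeric(N), length(N) == 1L, N >= 2, N == as.integer(N)
  )
  structure(
    list(eps_b = as.numeric(eps_b), u = as.numeric(u), d = as.integer(d),
         R = as.numeric(R), b = as.numeric(b), N = as.integer(N)),
    class = "model_params"
  )
}

#' Contour exclusion window of the hard core
#'
#' Pairs of segments separated by fewer than `floor(4 R / b)` segments along
#' the contour carry no excluded-volume interaction. The window is always
#' recomputed from `R` and `b`, never stored.
#'
#' @param params A [model_params()] object.
#' @return A non-negative integer.
#' @export
exclusion_window <- function(params) {
  as.integer(floor(4 * params$R / params$b))
}

#' @export
print.model_params <- function(x, ...) {
  cat("Chiral WLC model parameters\n")
  cat(sprintf("  eps_b = %g kT   u = %g kT   d = %d segments\n",
              x$eps_b, x$u, x$d))
  cat(sprintf("  R = %g b   b = %g   N = %d segments (%d vertices)\n",
              x$R, x$b, x$N, x$N + 1L))
  cat(sprintf("  hard-core exclusion window = %d segments\n",
              exclusion_window(x)))
  invisible(x)
}

#' Read and write model parameters as a flat YAML config
#'
#' The file holds the flat keys `eps_b`, `u`, `d`, `R`, `b`, `N`. Unknown
#' keys are rejected so that typos do not silently fall back to defaults.
#'
#' @param path Path of the YAML file.
#' @param params A [model_params()] object (for writing).
#' @return `read_params()` returns a [model_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("eps_b", "u", "d", "R", "b", "N")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  }
  do.call(model_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
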