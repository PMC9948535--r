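#' Polymer conformation with rigid bonds
#'
#' A conformation is an ordered list of `N + 1` vertex positions whose
#' consecutive distances all equal the bond length `b`. The contour
#' direction used to number segments is fixed once per chain by the vertex
#' order.
#'
#' @param vertices Numeric matrix with `N + 1` rows and 3 columns.
#' @param b Bond length; every bond must match it to within `tol * b`.
#' @param validate Set to `FALSE` to skip the bond-length check (used
#'   internally on freshly generated chains).
#' @param tol Relative bond-length tolerance (default `1e-9`; file readers
#'   pass a looser value matching the serialization precision).
#' @return An object of class `"conformation"`: the vertex matrix with the
#'   bond length attached as attribute `b`.
#' @examples
#' rod <- straight_rod(10)
#' n_segments(rod)
#' @export
conformation <- function(vertices, b = 1, validate = TRUE, tol = 1e-9) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(vertices) < 3L) stop("a chain needs at least 2 segments")
  if (validate) {
    len <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                           vertices[-nrow(vertices), , drop = FALSE])^2))
    bad <- which(abs(len - b) > tol * b)
    if (length(bad) > 0L) {
      stop(sprintf("bond %d has length %.12g, expected %g", bad[1L],
                   len[bad[1L]], b))
    }
  }
  structure(vertices, b = as.numeric(b), class = c("conformation", "matrix"))
}

#' @rdname conformation
#' @param conf A conformation.
#' @export
n_segments <- function(conf) nrow(conf) - 1L

#' @rdname conformation
#' @export
bond_length <- function(conf) {
  b <- attr(conf, "b")
  if (is.null(b)) 1 else b
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("WLC conformation: %d segments (%d vertices), b = %g\n",
              n_segments(x), nrow(x), bond_length(x)))
  invisible(x)
}

#' Segment geometry of a conformation
#'
#' `segment_vectors()` returns the `N` unit tangent vectors
#' `(r_i - r_{i-1}) / b`; `segment_centers()` the `N` segment midpoints
#' `(r_{i-1} + r_i) / 2`.
#'
#' @param conf A [conformation()] (or a plain vertex matrix).
#' @return A numeric matrix with `N` rows and 3 columns.
#' @export
segment_vectors <- function(conf) {
  v <- unclass(conf)
  (v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]) / bond_length(conf)
}

#' @rdname segment_vectors
#' @export
segment_centers <- function(conf) {
  v <- unclass(conf)
  (v[-1L, , drop = FALSE] + v[-nrow(v), , drop = FALSE]) / 2
}

#' Straight-rod conformation
#'
#' `N` collinear segments along the z axis. The rod is overlap-free for any
#' hard-core radius: pairs inside the contour exclusion window do not
#' interact, and beyond it the center distance `s * b` with
#' `s >= floor(4R/b)` always exceeds the hard-core diameter `2R`.
#'
#' @param N Number of segments.
#' @param b Bond length.
#' @return A [conformation()].
#' @export
straight_rod <- function(N, b = 1) {
  conformation(cbind(0, 0, (0:N) * b), b = b, validate = FALSE)
}

#' Mirror image of a conformation or closed polygon
#'
#' Reflects all coordinates through the xy-plane (`z -> -z`). The operation
#' is an involution. Bending energy and the hard-core state are invariant
#' under it, while the chiral energy, the torsion, and knot handedness all
#' change sign.
#'
#' @param x A [conformation()], a closed polygon, or a plain vertex matrix.
#' @return An object of the same kind.
#' @export
mirror_conformation <- function(x) {
  x[, 3L] <- -x[, 3L]
  x
}
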