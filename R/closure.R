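#' Deterministic closure of an open chain
#'
#' Knot type is only defined for closed curves, so an open conformation is
#' closed far away from its body: each end is extended along the ray from
#' the chain's center of mass through that end, out to a radius
#' `R_far = far_factor * max(vertex distance from COM)`, and the two far
#' points are joined by a great-circle arc on the sphere of radius `R_far`
#' (sampled with at least `arc_points` points). The closure arc therefore
#' never approaches the chain body.
#'
#' @param conf A [conformation()] or vertex matrix with at least 3 rows.
#' @param far_factor Multiple of the maximal COM distance used as closure
#'   radius (default 3).
#' @param arc_points Minimum number of points sampling the far arc.
#' @return An object of class `"knot_polygon"`: a cyclic vertex matrix
#'   (first row follows the last) containing the original vertices
#'   verbatim, with attributes `n_chain` (original vertex count) and
#'   `closure_points`.
#' @export
close_chain <- function(conf, far_factor = 3, arc_points = 8) {
  v <- unclass(as.matrix(conf))
  n <- nrow(v)
  if (n < 3L) stop("need at least 3 vertices to close a chain")
  com <- colMeans(v)
  rel <- sweep(v, 2L, com)
  rad <- sqrt(rowSums(rel^2))
  r_far <- far_factor * max(rad)
  e1 <- rel[1L, ]
  e2 <- rel[n, ]
  tol <- 1e-9 * max(r_far, 1)
  if (sqrt(sum(e1^2)) < tol) e1 <- e1 + c(tol, 0, 0)
  if (sqrt(sum(e2^2)) < tol) e2 <- e2 + c(-tol, 0, 0)
  u1 <- e1 / sqrt(sum(e1^2))
  u2 <- e2 / sqrt(sum(e2^2))
  p_end <- r_far * u2   # far point reached from the last vertex
  p_start <- r_far * u1 # far point connecting back to the first vertex
  arc <- great_circle_arc(u2, u1, r_far, arc_points)
  closure <- sweep(rbind(p_end, arc, p_start), 2L, com, "+")
  poly <- rbind(v, closure)
  dimnames(poly) <- NULL
  structure(poly, class = c("knot_polygon", "matrix"),
            n_chain = n, closure_points = nrow(closure))
}

# points strictly between unit vectors a and b on the sphere of radius r
great_circle_arc <- function(a, b, r, min_points) {
  d <- sum(a * b)
  d <- max(-1, min(1, d))
  ang <- acos(d)
  if (ang < 1e-9) return(matrix(numeric(0), 0L, 3L))
  # orthonormal partner of a in the plane of a, b
  w <- b - d * a
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {
    # antipodal ends: pick any perpendicular to travel through
    w <- c(a[2L], -a[1L], 0)
    if (sqrt(sum(w^2)) < 1e-12) w <- c(1, 0, 0)
    nw <- sqrt(sum(w^2))
  }
  w <- w / nw
  k <- max(min_points, ceiling(ang / (pi / 8)))
  t <- seq_len(k) / (k + 1) * ang
  r * (outer(cos(t), a) + outer(sin(t), w))
}

#' @export
print.knot_polygon <- function(x, ...) {
  cat(sprintf("Closed polygon: %d vertices", nrow(x)))
  nc <- attr(x, "n_chain")
  if (!is.null(nc)) cat(sprintf(" (%d chain + %d closure)", nc, nrow(x) - nc))
  cat("\n")
  invisible(x)
}

#' Coerce a cyclic vertex matrix to a closed polygon
#'
#' @param vertices Vertex matrix (rows are cycle vertices; the last row
#'   connects back to the first). Consecutive duplicate vertices are
#'   dropped.
#' @return A `"knot_polygon"`.
#' @export
knot_polygon <- function(vertices) {
  v <- unclass(as.matrix(vertices))
  if (ncol(v) != 3L) stop("vertices must have 3 columns")
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  dup <- sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2)) < 1e-12
  if (any(dup)) v <- v[!dup, , drop = FALSE]
  if (nrow(v) < 3L) stop("closed polygon needs at least 3 distinct vertices")
  rownames(v) <- NULL
  structure(v, class = c("knot_polygon", "matrix"))
}

#' KMT reduction of a closed polygon
#'
#' Iteratively deletes any vertex whose spanned triangle is intersected by
#' no other edge of the polygon. Each deletion is an isotopy, so the knot
#' type is unchanged while the vertex count shrinks; unknotted cycles
#' typically collapse to a triangle. The operation is idempotent.
#'
#' @param poly A `"knot_polygon"` (or cyclic vertex matrix).
#' @param tol Geometric tolerance in units of the bond length.
#' @return A reduced `"knot_polygon"`.
#' @export
kmt_reduce <- function(poly, tol = 1e-9) {
  v <- unclass(as.matrix(poly))
  out <- cpp_kmt_reduce(v, tol)
  structure(out, class = c("knot_polygon", "matrix"),
            n_chain = attr(poly, "n_chain"))
}
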