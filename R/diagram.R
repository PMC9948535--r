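#' Handedness sign of a single crossing
#'
#' For a crossing in a planar projection viewed along `e_z`, with `o` the
#' direction of the overpassing bond and `u` the direction of the
#' underpassing bond, the handedness is
#' `h = sign(e_z . (o x u) / |o x u|)`. It flips when `o` and `u` are
#' exchanged and under reflection through any plane containing `e_z`.
#'
#' @param e_z Unit vector of the viewing/projection direction.
#' @param o Direction vector of the overpassing bond.
#' @param u Direction vector of the underpassing bond.
#' @return `+1` or `-1`.
#' @export
crossing_handedness <- function(e_z, o, u) {
  cr <- c(o[2L] * u[3L] - o[3L] * u[2L],
          o[3L] * u[1L] - o[1L] * u[3L],
          o[1L] * u[2L] - o[2L] * u[1L])
  nc <- sqrt(sum(cr^2))
  if (nc <= 1e-12 * sqrt(sum(o^2) * sum(u^2))) {
    stop("degenerate crossing: over- and under-strand are parallel")
  }
  val <- sum(e_z * cr) / nc
  if (val > 0) 1L else -1L
}

# Deterministic sequence of candidate projection directions: +z first, then
# golden-angle perturbations of slowly growing polar angle. Seedless.
projection_directions <- function(n_max = 64L) {
  golden <- pi * (3 - sqrt(5))
  dirs <- matrix(0, n_max, 3L)
  dirs[1L, ] <- c(0, 0, 1)
  for (k in 2:n_max) {
    theta <- 0.2 + 0.9 * (k - 2L) / n_max * pi
    phi <- (k - 2L) * golden
    dirs[k, ] <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }
  dirs
}

#' Planar knot diagram of a closed polygon
#'
#' Projects the polygon along a viewing direction, enumerates all
#' transversal crossings between non-adjacent edges, assigns over/under
#' from the depth along the direction, and signs every crossing with
#' [crossing_handedness()]. Projections that are not regular (an edge
#' nearly parallel to the direction, a crossing too close to a vertex
#' image, a triple point, or two strands at equal depth) are rejected and
#' the next direction in a deterministic golden-angle sequence is tried.
#'
#' @param poly A `"knot_polygon"`.
#' @param direction Optional viewing direction; by default the
#'   deterministic sequence starting at `+z` is used.
#' @param tol Geometric tolerance (units of the edge lengths).
#' @return An object of class `"knot_diagram"`: a list with `crossings`
#'   (data frame: `over_seg`, `under_seg`, `sign`, `x`, `y`), `passages`
#'   (one component: integer crossing ids in traversal order), `over`
#'   (logical per passage), `direction`, and `n_crossings`.
#' @export
project_diagram <- function(poly, direction = NULL, tol = 1e-9) {
  v <- unclass(as.matrix(poly))
  dirs <- if (is.null(direction)) projection_directions() else
    matrix(direction / sqrt(sum(direction^2)), 1L)
  for (k in seq_len(nrow(dirs))) {
    dg <- try_projection(v, dirs[k, ], tol)
    if (!is.null(dg)) return(dg)
  }
  stop("no regular projection direction found (degenerate geometry)")
}

try_projection <- function(v, dir, tol) {
  n <- nrow(v)
  basis <- orthonormal_basis(dir)
  p <- v %*% basis$plane     # n x 2 projected coordinates
  z <- drop(v %*% dir)       # depth toward the viewer
  nxt <- c(2:n, 1L)
  edge <- p[nxt, , drop = FALSE] - p
  elen <- sqrt(rowSums(edge^2))
  len3 <- sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2))
  scale <- stats::median(len3)
  if (any(elen < 1e-6 * len3)) return(NULL) # edge parallel to direction
  cr_list <- vector("list", 64L)
  ncr <- 0L
  guard <- max(tol, 1e-9) * scale
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next # cyclically adjacent
      s <- seg2_params(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ])
      if (is.null(s)) next
      eps_i <- 1e-7
      if (s$t <= -eps_i || s$t >= 1 + eps_i) next
      if (s$s <= -eps_i || s$s >= 1 + eps_i) next
      if (s$t < eps_i || s$t > 1 - eps_i || s$s < eps_i || s$s > 1 - eps_i) {
        return(NULL) # crossing at (or too near) a vertex image
      }
      zi <- z[i] + s$t * (z[nxt[i]] - z[i])
      zj <- z[j] + s$s * (z[nxt[j]] - z[j])
      if (abs(zi - zj) <= guard) return(NULL) # strands at equal depth
      over_first <- zi > zj
      o_seg <- if (over_first) i else j
      u_seg <- if (over_first) j else i
      o_vec <- v[nxt[o_seg], ] - v[o_seg, ]
      u_vec <- v[nxt[u_seg], ] - v[u_seg, ]
      h <- crossing_handedness(dir, o_vec, u_vec)
      ncr <- ncr + 1L
      if (ncr > length(cr_list)) cr_list <- c(cr_list, vector("list", ncr))
      pt <- p[i, ] + s$t * (p[nxt[i], ] - p[i, ])
      cr_list[[ncr]] <- list(i = i, j = j, ti = s$t, tj = s$s,
                             over_seg = o_seg, under_seg = u_seg,
                             sign = h, x = pt[1L], y = pt[2L])
    }
  }
  cr <- cr_list[seq_len(ncr)]
  # triple-point check: crossing points pairwise distinct
  if (ncr > 1L) {
    xs <- vapply(cr, `[[`, numeric(1), "x")
    ys <- vapply(cr, `[[`, numeric(1), "y")
    dx <- outer(xs, xs, "-")
    dy <- outer(ys, ys, "-")
    dd <- sqrt(dx^2 + dy^2)
    diag(dd) <- Inf
    if (min(dd) <= 1e-7 * scale) return(NULL)
  }
  # passage order: sort crossings along the traversal of the cycle
  seg_of <- c(vapply(cr, `[[`, numeric(1), "i"),
              vapply(cr, `[[`, numeric(1), "j"))
  t_of <- c(vapply(cr, `[[`, numeric(1), "ti"),
            vapply(cr, `[[`, numeric(1), "tj"))
  id_of <- rep(seq_len(ncr), 2L)
  ord <- order(seg_of, t_of)
  pass_cr <- id_of[ord]
  over_seg <- vapply(cr, `[[`, numeric(1), "over_seg")
  pass_over <- (seg_of == over_seg[id_of])[ord]
  crossings <- data.frame(
    over_seg = as.integer(over_seg),
    under_seg = as.integer(vapply(cr, `[[`, numeric(1), "under_seg")),
    sign = as.integer(vapply(cr, `[[`, numeric(1), "sign")),
    x = vapply(cr, `[[`, numeric(1), "x"),
    y = vapply(cr, `[[`, numeric(1), "y"))
  structure(
    list(crossings = crossings,
         passages = as.integer(pass_cr),
         over = pass_over,
         sign = as.integer(crossings$sign),
         direction = dir,
         n_crossings = ncr),
    class = "knot_diagram"
  )
}

orthonormal_basis <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  ref <- if (abs(dir[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2L] * e1[3L] - dir[3L] * e1[2L],
          dir[3L] * e1[1L] - dir[1L] * e1[3L],
          dir[1L] * e1[2L] - dir[2L] * e1[1L])
  list(plane = cbind(e1, e2), dir = dir)
}

# intersection parameters of 2D segments a0-a1 and b0-b1, NULL if parallel
seg2_params <- function(a0, a1, b0, b1) {
  r <- a1 - a0
  s <- b1 - b0
  denom <- r[1L] * s[2L] - r[2L] * s[1L]
  if (abs(denom) <= 1e-14 * sqrt(sum(r^2) * sum(s^2))) return(NULL)
  q <- b0 - a0
  list(t = (q[1L] * s[2L] - q[2L] * s[1L]) / denom,
       s = (q[1L] * r[2L] - q[2L] * r[1L]) / denom)
}

#' @export
print.knot_diagram <- function(x, ...) {
  cat(sprintf("Knot diagram: %d crossings, writhe %+d\n", x$n_crossings,
              sum(x$sign)))
  invisible(x)
}

#' Writhe (sum of crossing signs) of a diagram
#'
#' For the minimal diagrams of the knots treated here, the sign of the
#' writhe determines the knot's handedness: positive for right-handed,
#' negative for left-handed.
#'
#' @param diagram A `"knot_diagram"`.
#' @return Integer sum of the crossing signs.
#' @export
diagram_writhe <- function(diagram) sum(diagram$sign)
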