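# Reference-curve generators: parametric helices, torus knots, the
# figure-eight knot, twist/pretzel embeddings, and combinatorial braid
# diagrams. These are first-class, deterministic constructions used both
# as test fixtures and to build the knot classification table.

#' Parametric curve specifications
#'
#' Builders for the specs accepted by [make_curve()].
#'
#' * `helix_spec(a, c, turns)` — circular helix `(a cos t, a sin t, c t)`;
#'   right-handed for `c > 0`, torsion `c / (a^2 + c^2)`. Returns an open
#'   chain.
#' * `torus_knot_spec(p, q)` — curve on a torus winding `p` times around
#'   the axis and `q` times around the tube; `(2,3)` is a trefoil, `(2,5)`
#'   the 5_1 knot. `p`, `q` must be coprime. Returns a closed polygon.
#' * `figure_eight_spec()` — the standard parametric embedding of the
#'   achiral 4_1 knot. Closed polygon.
#' * `twist52_spec()` — the 5_2 twist knot as the (3,1,1) pretzel, built
#'   from three vertical twist regions joined by planar arcs; its
#'   z-projection is a minimal 5-crossing diagram. Closed polygon.
#'
#' @param a,c Helix radius and pitch parameter (torsion `c/(a^2+c^2)`).
#' @param turns Number of helical turns.
#' @param p,q Torus-knot winding numbers (coprime).
#' @param n_vertices Number of polygon vertices; defaults are large enough
#'   that the polygonal curve is isotopic to the smooth one (at least 60
#'   for `torus_knot(2,3)`; the defaults are several times that).
#' @param handedness `"right"` or `"left"`; left-handed variants are the
#'   mirror image (`z -> -z`).
#' @return A spec object for [make_curve()].
#' @export
helix_spec <- function(a = 1, c = 0.2, turns = 6, n_vertices = 400,
                       handedness = c("right", "left"),
                       unit_bonds = TRUE) {
  handedness <- match.arg(handedness)
  structure(list(kind = "helix", a = a, c = c, turns = turns,
                 n_vertices = as.integer(n_vertices),
                 handedness = handedness, unit_bonds = unit_bonds),
            class = "curve_spec")
}

#' @rdname helix_spec
#' @export
torus_knot_spec <- function(p = 2, q = 3, n_vertices = 211,
                            handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  if (gcd_int(p, q) != 1L) stop("p and q must be coprime for a torus knot")
  structure(list(kind = "torus_knot", p = as.integer(p), q = as.integer(q),
                 n_vertices = as.integer(n_vertices),
                 handedness = handedness), class = "curve_spec")
}

#' @rdname helix_spec
#' @export
figure_eight_spec <- function(n_vertices = 241) {
  structure(list(kind = "figure_eight", n_vertices = as.integer(n_vertices)),
            class = "curve_spec")
}

#' @rdname helix_spec
#' @export
twist52_spec <- function(handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  structure(list(kind = "twist_5_2", handedness = handedness),
            class = "curve_spec")
}

gcd_int <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b != 0L) {
    t <- b; b <- a %% b; a <- t
  }
  a
}

#' Build a reference curve from a specification
#'
#' @param spec A spec from [helix_spec()], [torus_knot_spec()],
#'   [figure_eight_spec()], or [twist52_spec()].
#' @return A [conformation()] for open curves (helix), a `"knot_polygon"`
#'   for closed ones.
#' @examples
#' tref <- make_curve(torus_knot_spec(2, 3))
#' classify_polygon(tref)
#' @export
make_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  out <- switch(spec$kind,
    helix = curve_helix(spec),
    torus_knot = curve_torus(spec),
    figure_eight = curve_fig8(spec),
    twist_5_2 = curve_52(spec),
    stop("unknown curve kind: ", spec$kind)
  )
  if (!is.null(spec$handedness) && spec$handedness == "left") {
    out <- mirror_conformation(out)
  }
  out
}

curve_helix <- function(spec) {
  t <- seq(0, 2 * pi * spec$turns, length.out = spec$n_vertices)
  v <- cbind(spec$a * cos(t), spec$a * sin(t), spec$c * t)
  if (!spec$unit_bonds) {
    # raw coordinates: torsion stays c / (a^2 + c^2), bonds are not unit
    return(v)
  }
  # uniform parameter steps give exactly equal chords on a helix; rescale
  # so the chain has unit bonds (torsion rescales by the chord length)
  chord <- sqrt(sum((v[2L, ] - v[1L, ])^2))
  conformation(v / chord, b = 1, validate = FALSE)
}

curve_torus <- function(spec) {
  n <- spec$n_vertices
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- spec$p; q <- spec$q
  v <- cbind((2 + cos(q * t)) * cos(p * t),
             (2 + cos(q * t)) * sin(p * t),
             -sin(q * t))
  knot_polygon(v)
}

curve_fig8 <- function(spec) {
  n <- spec$n_vertices
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  v <- cbind((2 + cos(2 * t)) * cos(3 * t),
             (2 + cos(2 * t)) * sin(3 * t),
             sin(4 * t))
  knot_polygon(v)
}

# the raw (3,1,1) pretzel as built has all-negative twists (writhe -5);
# mirror it so the spec's "right" default matches positive crossing sum
curve_52 <- function(spec) mirror_conformation(pretzel_polygon(c(3, 1, 1)))

# ---- pretzel embeddings ------------------------------------------------

#' Polygonal embedding of a three-tassel pretzel knot
#'
#' Builds a 3D polyline whose z-projection is the standard pretzel diagram
#' with vertical twist regions of `p[1]`, `p[2]`, `p[3]` crossings joined
#' by planar arcs. With all `p` odd the result is a knot; `(1,1,1)` is a
#' trefoil and `(3,1,1)` the 5_2 knot. All twists share the same sense, so
#' the projected diagram has `sum(p)` crossings.
#'
#' @param p Integer vector of three positive odd twist counts.
#' @return A `"knot_polygon"`.
#' @export
pretzel_polygon <- function(p = c(3, 1, 1)) {
  stopifnot(length(p) == 3L, all(p >= 1L), all(p %% 2 == 1))
  h <- max(p)
  pieces <- list()
  ends <- list()
  for (i in 1:3) {
    xc <- 2 * i
    tw <- twist_strands(xc, 0, p[i], h)
    pieces <- c(pieces, tw$pieces)
  }
  # connector arcs in the z = 0 plane; "top" is y = h + offsets
  top_y <- h
  arc_top_small <- function(x1, x2, lift) {
    rbind(c(x1, top_y, 0), c(x1, top_y + lift, 0), c(x2, top_y + lift, 0),
          c(x2, top_y, 0))
  }
  arc_bot_small <- function(x1, x2, drop) {
    rbind(c(x1, 0, 0), c(x1, -drop, 0), c(x2, -drop, 0), c(x2, 0, 0))
  }
  pieces <- c(pieces, list(
    arc_top_small(2.5, 3.5, 0.5),   # region1 right top -- region2 left top
    arc_top_small(4.5, 5.5, 0.5),   # region2 right top -- region3 left top
    arc_top_small(1.5, 6.5, 1.2),   # region1 left top -- region3 right top
    arc_bot_small(2.5, 3.5, 0.5),
    arc_bot_small(4.5, 5.5, 0.5),
    arc_bot_small(1.5, 6.5, 1.2)
  ))
  knot_polygon(assemble_cycle(pieces))
}

# two strands of a vertical twist region with p crossings centered at xc,
# from y = y0 to y = y0 + h (crossings in the first p unit cells, straight
# continuation above); left-to-right strand passes over (z bump +0.4)
twist_strands <- function(xc, y0, p, h) {
  left <- xc - 0.5
  right <- xc + 0.5
  sA <- matrix(c(left, y0, 0), 1L)   # starts at bottom-left
  sB <- matrix(c(right, y0, 0), 1L)  # starts at bottom-right
  at_left_A <- TRUE
  for (k in seq_len(p)) {
    ymid <- y0 + k - 0.5
    ytop <- y0 + k
    # the small y-offsets keep the projected crossing away from vertex
    # images so the +z projection is regular
    if (at_left_A) {
      # A moves left->right (over), B right->left (under)
      sA <- rbind(sA, c(xc, ymid + 0.06, 0.4), c(right, ytop, 0))
      sB <- rbind(sB, c(xc, ymid - 0.06, -0.4), c(left, ytop, 0))
    } else {
      sA <- rbind(sA, c(xc, ymid + 0.06, -0.4), c(left, ytop, 0))
      sB <- rbind(sB, c(xc, ymid - 0.06, 0.4), c(right, ytop, 0))
    }
    at_left_A <- !at_left_A
  }
  if (h > p) {
    xa <- sA[nrow(sA), 1L]
    xb <- sB[nrow(sB), 1L]
    sA <- rbind(sA, c(xa, y0 + h, 0))
    sB <- rbind(sB, c(xb, y0 + h, 0))
  }
  list(pieces = list(sA, sB))
}

# join polyline pieces into one closed cycle by matching endpoints
assemble_cycle <- function(pieces, tol = 1e-6) {
  used <- rep(FALSE, length(pieces))
  cur <- pieces[[1L]]
  used[1L] <- TRUE
  path <- cur
  repeat {
    tail_pt <- path[nrow(path), ]
    found <- FALSE
    for (i in seq_along(pieces)) {
      if (used[i]) next
      pc <- pieces[[i]]
      if (sqrt(sum((pc[1L, ] - tail_pt)^2)) < tol) {
        path <- rbind(path, pc[-1L, , drop = FALSE])
        used[i] <- TRUE
        found <- TRUE
        break
      }
      np <- nrow(pc)
      if (sqrt(sum((pc[np, ] - tail_pt)^2)) < tol) {
        path <- rbind(path, pc[(np - 1L):1L, , drop = FALSE])
        used[i] <- TRUE
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  if (!all(used)) stop("curve pieces do not assemble into one component")
  head_pt <- path[1L, ]
  tail_pt <- path[nrow(path), ]
  if (sqrt(sum((head_pt - tail_pt)^2)) > tol) {
    stop("assembled curve is not closed")
  }
  path[-nrow(path), , drop = FALSE]
}

# ---- braid words -------------------------------------------------------

#' Combinatorial diagram of a braid closure
#'
#' Builds the knot/link diagram obtained by closing a braid word. Letters
#' are signed integers: `+k` is the positive generator crossing strands at
#' positions `k`, `k+1` (the strand arriving from position `k+1` passes
#' over; crossing sign `+1`), `-k` its inverse. The closure of `c(1,1,1)`
#' is the right-handed trefoil (writhe `+3`), of `c(1,-2,1,-2)` the
#' figure-eight knot, and of `c(1,1,1,1,1)` the right-handed 5_1.
#'
#' @param word Integer vector of signed generators.
#' @param n_strands Number of strands (default inferred from the word).
#' @return A `"knot_diagram"` with `components`, `sign`, `n_crossings`.
#' @export
braid_diagram <- function(word, n_strands = max(abs(word)) + 1L) {
  stopifnot(length(word) > 0L, all(word != 0L),
            max(abs(word)) < n_strands)
  occupant <- seq_len(n_strands)
  pass_cr <- vector("list", n_strands)
  pass_over <- vector("list", n_strands)
  sgn <- integer(length(word))
  for (t in seq_along(word)) {
    k <- abs(word[t])
    eps <- sign(word[t])
    sgn[t] <- eps
    a <- occupant[k]        # strand at left position
    b <- occupant[k + 1L]   # strand at right position
    pass_cr[[a]] <- c(pass_cr[[a]], t)
    pass_over[[a]] <- c(pass_over[[a]], eps < 0)
    pass_cr[[b]] <- c(pass_cr[[b]], t)
    pass_over[[b]] <- c(pass_over[[b]], eps > 0)
    occupant[c(k, k + 1L)] <- c(b, a)
  }
  end_pos <- match(seq_len(n_strands), occupant) # strand s ends at this pos
  comps <- list()
  visited <- rep(FALSE, n_strands)
  for (s0 in seq_len(n_strands)) {
    if (visited[s0]) next
    cr <- integer(0)
    ov <- logical(0)
    s <- s0
    repeat {
      visited[s] <- TRUE
      cr <- c(cr, pass_cr[[s]])
      ov <- c(ov, pass_over[[s]])
      s <- end_pos[s]
      if (s == s0) break
    }
    comps[[length(comps) + 1L]] <- list(cr = cr, over = ov)
  }
  structure(
    list(components = comps, sign = sgn, n_crossings = length(word),
         n_components = length(comps)),
    class = "knot_diagram"
  )
}

#' Polygonal embedding of a braid closure
#'
#' Realizes [braid_diagram()] geometrically: strands run downward in the
#' `z = 0` plane with over/under bumps at `z = +-0.4`, and nested planar
#' return arcs close each strand on the left. The z-projection of the
#' result reproduces the combinatorial braid diagram crossing for
#' crossing.
#'
#' @inheritParams braid_diagram
#' @return A `"knot_polygon"` (the closure must be a knot, i.e. a single
#'   component).
#' @export
braid_embedding <- function(word, n_strands = max(abs(word)) + 1L) {
  dg <- braid_diagram(word, n_strands)
  if (dg$n_components != 1L) {
    stop("braid closure has ", dg$n_components,
         " components; need a knot")
  }
  L <- length(word)
  occupant <- seq_len(n_strands)
  paths <- lapply(seq_len(n_strands), function(s) {
    matrix(c(s, 0, 0), 1L)
  })
  for (t in seq_along(word)) {
    k <- abs(word[t])
    eps <- sign(word[t])
    a <- occupant[k]
    b <- occupant[k + 1L]
    ymid <- -(t - 0.5)
    ybot <- -t
    za <- if (eps < 0) 0.4 else -0.4 # left strand over for negative letter
    # y-offsets keep the projected crossing mid-segment (regular projection)
    paths[[a]] <- rbind(paths[[a]], c(k + 0.5, ymid + 0.08, za),
                        c(k + 1, ybot, 0))
    paths[[b]] <- rbind(paths[[b]], c(k + 0.5, ymid - 0.08, -za),
                        c(k, ybot, 0))
    occupant[c(k, k + 1L)] <- c(b, a)
    for (pos in seq_len(n_strands)) {
      if (pos == k || pos == k + 1L) next
      s <- occupant[pos]
      paths[[s]] <- rbind(paths[[s]], c(pos, ybot, 0))
    }
  }
  pieces <- paths
  # closure arcs: bottom position p reconnects to top position p, routed
  # through nested lanes on the left at z = 0
  for (p in seq_len(n_strands)) {
    lane_x <- -0.7 - 0.5 * p
    lane_y_top <- 0.7 + 0.3 * p
    lane_y_bot <- -L - 0.7 - 0.3 * p
    pieces[[length(pieces) + 1L]] <- rbind(
      c(p, -L, 0), c(p, lane_y_bot, 0), c(lane_x, lane_y_bot, 0),
      c(lane_x, lane_y_top, 0), c(p, lane_y_top, 0), c(p, 0, 0))
  }
  knot_polygon(assemble_cycle(pieces))
}
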