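# Naive, term-by-term oracle implementations of the Hamiltonian pieces,
# plus small generators used across the test files.

oracle_bending <- function(conf, params) {
  t <- segment_vectors(conf)
  acc <- 0
  for (i in seq_len(nrow(t) - 1L)) acc <- acc + sum(t[i, ] * t[i + 1L, ])
  -params$eps_b * acc
}

oracle_chiral <- function(conf, params) {
  t <- segment_vectors(conf)
  ctr <- segment_centers(conf)
  n <- nrow(t)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || j - i > params$d) next
      r <- ctr[j, ] - ctr[i, ]
      nr <- sqrt(sum(r^2))
      if (nr == 0) next
      cr <- c(t[i, 2] * t[j, 3] - t[i, 3] * t[j, 2],
              t[i, 3] * t[j, 1] - t[i, 1] * t[j, 3],
              t[i, 1] * t[j, 2] - t[i, 2] * t[j, 1])
      acc <- acc + sum(cr * r) / nr
    }
  }
  params$u * acc
}

oracle_overlap <- function(conf, params) {
  if (params$R == 0) return(FALSE)
  ctr <- segment_centers(conf)
  n <- nrow(ctr)
  w <- floor(4 * params$R / params$b)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || j - i < max(w, 1)) next
      if (sqrt(sum((ctr[j, ] - ctr[i, ])^2)) <= 2 * params$R) return(TRUE)
    }
  }
  FALSE
}

# random chain with rigid unit bonds
random_conformation <- function(N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- runif(N, -1, 1)
  phi <- runif(N, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  steps <- cbind(s * cos(phi), s * sin(phi), z)
  conformation(rbind(0, apply(steps, 2L, cumsum)), b = 1)
}

# reverse the contour numbering direction of a chain
reverse_conformation <- function(conf) {
  v <- unclass(conf)[nrow(conf):1, , drop = FALSE]
  conformation(v, b = bond_length(conf))
}

rigid_motion <- function(x, angles = c(0.3, 1.1, -0.7), shift = c(1, -2, 3)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  out <- unclass(as.matrix(x)) %*% t(Rz %*% Ry %*% Rx)
  out <- sweep(out, 2L, shift, "+")
  attributes(out) <- c(attributes(out)[c("dim")],
                       attributes(x)[setdiff(names(attributes(x)), "dim")])
  out
}

# split every edge of a closed polygon in two (vertex densification)
densify_polygon <- function(poly) {
  v <- unclass(as.matrix(poly))
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  mid <- (v + v[nxt, , drop = FALSE]) / 2
  out <- matrix(0, 2L * n, 3L)
  out[seq(1L, 2L * n, by = 2L), ] <- v
  out[seq(2L, 2L * n, by = 2L), ] <- mid
  knot_polygon(out)
}
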