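test_that("crossing handedness is the sign of the triple product", {
  ez <- c(0, 0, 1)
  expect_identical(crossing_handedness(ez, c(1, 0, 0), c(0, 1, 0)), 1L)
  expect_identical(crossing_handedness(ez, c(0, 1, 0), c(1, 0, 0)), -1L)
  set.seed(31)
  for (k in 1:50) {
    o <- rnorm(3); u <- rnorm(3)
    det <- sum(ez * c(o[2] * u[3] - o[3] * u[2],
                      o[3] * u[1] - o[1] * u[3],
                      o[1] * u[2] - o[2] * u[1]))
    expect_identical(crossing_handedness(ez, o, u),
                     if (det > 0) 1L else -1L)
  }
  expect_error(crossing_handedness(ez, c(1, 0, 0), c(2, 0, 0)),
               "degenerate")
})

test_that("closure keeps the chain verbatim and unknots a rod", {
  conf <- random_conformation(25, seed = 4)
  poly <- close_chain(conf)
  expect_equal(poly[1:26, ], conf[1:26, ], tolerance = 0)
  expect_gt(nrow(poly), 26)
  expect_identical(classify_conformation(straight_rod(20))$type, "unknot")
})

test_that("closure agrees with direct joining when the ends are close", {
  # open trefoil whose ends nearly meet: drop the last vertex of the cycle
  t23 <- make_curve(torus_knot_spec(2, 3, n_vertices = 120))
  open_chain <- unclass(t23)
  lab_closed <- classify_polygon(t23)
  lab_via_closure <- classify_polygon(close_chain(open_chain))
  expect_identical(lab_via_closure$type, lab_closed$type)
  expect_identical(lab_via_closure$handedness, lab_closed$handedness)
  # doubling the closure radius must not change the label
  lab_far <- classify_polygon(close_chain(open_chain, far_factor = 6))
  expect_identical(lab_far$type, lab_closed$type)
  expect_identical(lab_far$handedness, lab_closed$handedness)
})

test_that("KMT reduction collapses unknots and preserves knot type", {
  t <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- knot_polygon(cbind(cos(t), sin(t), 0))
  expect_lte(nrow(kmt_reduce(circ)), 3)

  t23 <- make_curve(torus_knot_spec(2, 3, n_vertices = 200))
  red <- kmt_reduce(t23)
  expect_lt(nrow(red), nrow(t23))
  expect_true(homfly_equal(homfly(project_diagram(t23)),
                              homfly(project_diagram(red))))
  # idempotence
  expect_identical(nrow(kmt_reduce(red)), nrow(red))
})

test_that("projection is regular and invariant across directions", {
  circ_t <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- knot_polygon(cbind(cos(circ_t), sin(circ_t), 0))
  dg <- project_diagram(circ)
  expect_identical(dg$n_crossings, 0L)

  t23 <- make_curve(torus_knot_spec(2, 3))
  d1 <- project_diagram(t23, direction = c(0, 0, 1))
  expect_identical(d1$n_crossings, 3L)
  expect_identical(diagram_writhe(d1), 3L)
  expect_true(all(d1$crossings$sign == 1L))
  d2 <- project_diagram(t23, direction = c(0.3, 0.2, 0.93))
  expect_true(homfly_equal(homfly(d1), homfly(d2)))
})

test_that("homfly engine matches the brute-force skein oracle", {
  fixtures <- list(
    braid_diagram(c(1, 1, 1)),            # right trefoil
    braid_diagram(c(-1, -1, -1)),         # left trefoil
    braid_diagram(c(1, -2, 1, -2)),       # figure-eight
    braid_diagram(c(1, 1, 1, 1, 1)),      # 5_1
    braid_diagram(c(1, 1, 1, 2, 2, 2)),   # granny
    braid_diagram(c(1, 1, 1, -2, -2, -2)),# square
    project_diagram(pretzel_polygon(c(3, 1, 1)))  # 5_2 minimal diagram
  )
  for (dg in fixtures) {
    expect_true(homfly_equal(homfly(dg), homfly_bruteforce(dg)))
  }
  # granny and square knots have different polynomials
  expect_false(homfly_equal(homfly(fixtures[[5]]), homfly(fixtures[[6]])))
  # 0-crossing diagram gives the unit polynomial
  circ_t <- seq(0, 2 * pi, length.out = 17)[-17]
  circ <- knot_polygon(cbind(cos(circ_t), sin(circ_t), 0))
  p_unknot <- homfly(project_diagram(circ))
  expect_equal(unname(p_unknot[, 3]), 1)
  expect_equal(nrow(p_unknot), 1L)
})

test_that("mirror image diagrams invert the l variable", {
  p_r <- homfly(braid_diagram(c(1, 1, 1)))
  p_l <- homfly(braid_diagram(c(-1, -1, -1)))
  expect_true(homfly_equal(homfly_mirror(p_r), p_l))
  expect_false(homfly_equal(p_r, p_l))
  # the figure-eight is amphichiral
  p_f8 <- homfly(braid_diagram(c(1, -2, 1, -2)))
  expect_true(homfly_equal(homfly_mirror(p_f8), p_f8))
})

test_that("knot determinants agree with the classical values", {
  expect_equal(knot_determinant(homfly(braid_diagram(c(1, 1, 1)))), 3)
  expect_equal(knot_determinant(homfly(braid_diagram(c(1, -2, 1, -2)))), 5)
  expect_equal(knot_determinant(homfly(braid_diagram(c(1, 1, 1, 1, 1)))), 5)
  expect_equal(
    knot_determinant(homfly(project_diagram(pretzel_polygon(c(3, 1, 1))))),
    7)
})

test_that("classification identifies all reference embeddings", {
  lab23 <- classify_polygon(make_curve(torus_knot_spec(2, 3)))
  expect_identical(lab23$type, "3_1")
  expect_identical(lab23$handedness, "right")
  lab23m <- classify_polygon(mirror_conformation(
    make_curve(torus_knot_spec(2, 3))))
  expect_identical(lab23m$type, "3_1")
  expect_identical(lab23m$handedness, "left")
  lab25 <- classify_polygon(make_curve(torus_knot_spec(2, 5)))
  expect_identical(lab25$type, "5_1")
  expect_identical(lab25$handedness, "right")
  lab8 <- classify_polygon(make_curve(figure_eight_spec()))
  expect_identical(lab8$type, "4_1")
  expect_identical(lab8$handedness, "achiral")
  lab52 <- classify_polygon(make_curve(twist52_spec(handedness = "right")))
  expect_identical(lab52$type, "5_2")
  expect_identical(lab52$handedness, "right")
  lab52l <- classify_polygon(make_curve(twist52_spec(handedness = "left")))
  expect_identical(lab52l$handedness, "left")
})

test_that("the handedness convention is tied to the crossing-sum rule", {
  # a minimal 3-crossing diagram with all positive crossings is the
  # right-handed trefoil: positive crossing sum means right-handed
  t23 <- make_curve(torus_knot_spec(2, 3))
  dg <- project_diagram(t23)
  expect_identical(dg$n_crossings, 3L)
  expect_identical(diagram_writhe(dg), 3L)
  expect_identical(classify_polygon(t23)$handedness, "right")
  # same for the geometric realization of the sigma_1^3 braid closure
  be <- braid_embedding(c(1, 1, 1))
  dbe <- project_diagram(be)
  expect_identical(diagram_writhe(dbe), 3L)
  expect_true(homfly_equal(homfly(dbe), homfly(braid_diagram(c(1, 1, 1)))))
})

test_that("classification is invariant under re-embedding operations", {
  fixtures <- list(
    make_curve(torus_knot_spec(2, 3)),
    mirror_conformation(make_curve(torus_knot_spec(2, 3))),
    make_curve(torus_knot_spec(2, 5)),
    make_curve(figure_eight_spec()),
    make_curve(twist52_spec())
  )
  set.seed(77)
  for (poly in fixtures) {
    ref <- classify_polygon(poly)
    # rigid rotation + translation
    rot <- knot_polygon(rigid_motion(poly, angles = runif(3, -pi, pi),
                                     shift = rnorm(3)))
    got <- classify_polygon(rot)
    expect_identical(got$type, ref$type)
    expect_identical(got$handedness, ref$handedness)
    # cyclic re-indexing
    v <- unclass(as.matrix(poly))
    k <- sample(nrow(v) - 1, 1)
    cyc <- knot_polygon(v[c((k + 1):nrow(v), 1:k), ])
    got <- classify_polygon(cyc)
    expect_identical(got$type, ref$type)
    expect_identical(got$handedness, ref$handedness)
    # contour direction reversal
    rev <- knot_polygon(v[nrow(v):1, ])
    got <- classify_polygon(rev)
    expect_identical(got$type, ref$type)
    expect_identical(got$handedness, ref$handedness)
    # vertex densification
    got <- classify_polygon(densify_polygon(poly))
    expect_identical(got$type, ref$type)
    expect_identical(got$handedness, ref$handedness)
  }
})

test_that("overly complex diagrams are labelled indeterminate, not wrong", {
  t27 <- make_curve(torus_knot_spec(2, 7, n_vertices = 240))
  lab <- classify_polygon(t27, cap = 4L)
  expect_identical(lab$type, "other")
  expect_true(lab$indeterminate)
  # with the default cap the same polygon is determinate "other"
  lab2 <- classify_polygon(t27)
  expect_identical(lab2$type, "other")
  expect_false(lab2$indeterminate)
})
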