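test_that("bending energy matches closed forms and the brute-force sum", {
  p <- model_params(eps_b = 4, u = 0, d = 10, R = 0, N = 10)
  rod <- straight_rod(10)
  expect_equal(bending_energy(rod, p), -4 * 9)
  p0 <- model_params(eps_b = 0, N = 10)
  expect_equal(bending_energy(rod, p0), 0)

  conf <- random_conformation(20, seed = 101)
  p20 <- model_params(eps_b = 2.5, N = 20)
  expect_equal(bending_energy(conf, p20), oracle_bending(conf, p20),
               tolerance = 1e-12)
})

test_that("bending energy is invariant under rigid motion and reflection", {
  conf <- random_conformation(15, seed = 7)
  p <- model_params(eps_b = 3, N = 15)
  e0 <- bending_energy(conf, p)
  expect_equal(bending_energy(rigid_motion(conf), p), e0, tolerance = 1e-9)
  expect_equal(bending_energy(mirror_conformation(conf), p), e0,
               tolerance = 1e-12)
})

test_that("chiral energy vanishes for straight rods and at u = 0", {
  p <- model_params(eps_b = 4, u = 0.7, d = 10, N = 12)
  expect_equal(chiral_energy(straight_rod(12), p), 0)
  conf <- random_conformation(12, seed = 3)
  p0 <- model_params(eps_b = 4, u = 0, d = 10, N = 12)
  expect_equal(chiral_energy(conf, p0), 0)
})

test_that("a right-handed helix has negative chiral energy at u > 0", {
  h <- make_curve(helix_spec(a = 1, c = 0.3, turns = 4, n_vertices = 61))
  p <- model_params(eps_b = 4, u = 0.5, d = 10, N = n_segments(h))
  e <- chiral_energy(h, p)
  expect_lt(e, 0)
  expect_equal(chiral_energy(mirror_conformation(h), p), -e,
               tolerance = 1e-12)
  expect_equal(e, oracle_chiral(h, p), tolerance = 1e-10)
})

test_that("chiral energy is odd in u and only couples pairs within d", {
  conf <- random_conformation(25, seed = 11)
  pp <- model_params(u = 0.4, d = 6, N = 25)
  pm <- model_params(u = -0.4, d = 6, N = 25)
  expect_equal(chiral_energy(conf, pp), -chiral_energy(conf, pm),
               tolerance = 1e-12)
  # widening d beyond N - 1 changes nothing further
  p_all <- model_params(u = 0.4, d = 24, N = 25)
  p_big <- model_params(u = 0.4, d = 1000, N = 25)
  expect_equal(chiral_energy(conf, p_all), chiral_energy(conf, p_big))
  expect_equal(chiral_energy(conf, p_all), oracle_chiral(conf, p_all),
               tolerance = 1e-12)
})

test_that("hard-core overlap honours the contour exclusion window", {
  # R = 0: never an overlap
  conf <- random_conformation(30, seed = 5)
  expect_false(hardcore_overlap(conf, model_params(R = 0, N = 30)))

  # hairpin: two antiparallel strands one bond apart
  hp <- conformation(rbind(
    cbind(0, 0, 0:10), cbind(0, sqrt(3) / 2, 10.5), cbind(0, sqrt(3), 10:0),
    deparse.level = 0), b = 1)
  p <- model_params(R = 2.5, b = 1, N = n_segments(hp))
  expect_equal(exclusion_window(p), 10L)
  expect_true(hardcore_overlap(hp, p))
  # same geometry, window exempts pairs closer than 10 segments: a short
  # hairpin whose contacts are all within the window is overlap-free
  hp_short <- conformation(rbind(
    cbind(0, 0, 0:3), cbind(0, sqrt(3) / 2, 3.5), cbind(0, sqrt(3), 3:0),
    deparse.level = 0), b = 1)
  p2 <- model_params(R = 2.5, b = 1, N = n_segments(hp_short))
  expect_false(hardcore_overlap(hp_short, p2))
  expect_equal(hardcore_overlap(hp, p), oracle_overlap(hp, p))
})

test_that("total energy composes the terms and respects mirror symmetry", {
  p <- model_params(eps_b = 4, u = 0.5, d = 10, R = 0, N = 10)
  e <- total_energy(straight_rod(10), p)
  expect_equal(e$E_bend, -36)
  expect_equal(e$E_chiral, 0)
  expect_false(e$hardcore_violated)
  expect_equal(e$total, -36)

  conf <- random_conformation(20, seed = 42)
  p20 <- model_params(eps_b = 2, u = 0.3, d = 5, R = 0.4, N = 20)
  e1 <- total_energy(conf, p20)
  e2 <- total_energy(mirror_conformation(conf), p20)
  expect_equal(e2$E_bend, e1$E_bend, tolerance = 1e-12)
  expect_equal(e2$E_chiral, -e1$E_chiral, tolerance = 1e-12)
  expect_identical(e2$hardcore_violated, e1$hardcore_violated)
  expect_equal(e1$E_bend, oracle_bending(conf, p20), tolerance = 1e-12)
  expect_equal(e1$E_chiral, oracle_chiral(conf, p20), tolerance = 1e-12)
})

test_that("energy symmetries hold across many random conformations", {
  set.seed(2024)
  for (k in 1:100) {
    N <- sample(6:24, 1)
    conf <- random_conformation(N)
    p <- model_params(eps_b = runif(1, 0, 5), u = runif(1, -1, 1),
                      d = sample(1:8, 1), R = runif(1, 0, 0.6), N = N)
    m <- mirror_conformation(conf)
    expect_equal(bending_energy(m, p), bending_energy(conf, p),
                 tolerance = 1e-12)
    expect_equal(chiral_energy(m, p), -chiral_energy(conf, p),
                 tolerance = 1e-12)
    expect_identical(hardcore_overlap(m, p), hardcore_overlap(conf, p))
    # contour direction reversal leaves every term unchanged
    r <- reverse_conformation(conf)
    expect_equal(bending_energy(r, p), bending_energy(conf, p),
                 tolerance = 1e-12)
    expect_equal(chiral_energy(r, p), chiral_energy(conf, p),
                 tolerance = 1e-12)
    expect_identical(hardcore_overlap(r, p), hardcore_overlap(conf, p))
    # naive O(N^2) oracle agrees with the vectorized implementation
    expect_equal(chiral_energy(conf, p), oracle_chiral(conf, p),
                 tolerance = 1e-12)
    expect_identical(hardcore_overlap(conf, p), oracle_overlap(conf, p))
  }
})

test_that("conformation validation enforces rigid bonds and shape", {
  expect_error(conformation(matrix(0, 2, 3)), "at least 2 segments")
  bad <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2.5))
  expect_error(conformation(bad, b = 1), "bond 2")
  expect_error(bending_energy(straight_rod(10), model_params(N = 11)),
               "params\\$N")
})

test_that("model parameters validate and round-trip through YAML", {
  expect_error(model_params(N = 1), "N >= 2")
  expect_error(model_params(R = -1))
  expect_error(model_params(eps_b = Inf))
  p <- model_params(eps_b = 4, u = -0.25, d = 10, R = 2.5, b = 1, N = 1000)
  expect_identical(exclusion_window(p), 10L)
  path <- tempfile(fileext = ".yaml")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(unclass(q), unclass(p))
  # unknown keys are rejected
  writeLines(c("eps_b: 1", "frobnicate: 2"), path)
  expect_error(read_params(path), "frobnicate")
})
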