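test_that("curve generators produce the advertised shapes", {
  h <- make_curve(helix_spec(a = 1, c = 0.25, turns = 4, n_vertices = 200))
  expect_s3_class(h, "conformation")
  len <- sqrt(rowSums((unclass(h)[-1, ] - unclass(h)[-nrow(h), ])^2))
  expect_lt(max(abs(len - 1)), 1e-9)
  expect_gt(discrete_torsion(h)$tau_mean, 0)
  hm <- make_curve(helix_spec(a = 1, c = 0.25, turns = 4, n_vertices = 200,
                              handedness = "left"))
  expect_equal(discrete_torsion(hm)$tau_mean, -discrete_torsion(h)$tau_mean,
               tolerance = 1e-12)

  expect_error(torus_knot_spec(2, 4), "coprime")
  expect_s3_class(make_curve(torus_knot_spec(2, 3)), "knot_polygon")
})

test_that("mirroring is an involution with the documented symmetries", {
  conf <- random_conformation(20, seed = 12)
  expect_equal(unclass(mirror_conformation(mirror_conformation(conf))),
               unclass(conf))
  p <- model_params(eps_b = 2, u = 0.5, d = 5, N = 20)
  expect_equal(chiral_energy(mirror_conformation(conf), p),
               -chiral_energy(conf, p), tolerance = 1e-12)
  expect_equal(bending_energy(mirror_conformation(conf), p),
               bending_energy(conf, p), tolerance = 1e-12)
})

test_that("XYZ files round-trip exactly and report malformed input", {
  tr_frames <- lapply(1:3, function(i) random_conformation(12, seed = i))
  path <- tempfile(fileext = ".xyz")
  write_xyz(tr_frames, path, u = 0.25, seed = 42)
  back <- read_xyz(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(unclass(back[[i]]), unclass(tr_frames[[i]]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_match(attr(back[[i]], "comment"), "u=0.25")
    expect_match(attr(back[[i]], "comment"), "seed=42")
  }
  # writing the re-read frames reproduces the file byte for byte
  path2 <- tempfile(fileext = ".xyz")
  write_xyz(back, path2, u = 0.25, seed = 42)
  expect_identical(readLines(path), readLines(path2))

  # empty trajectory
  empty <- tempfile(fileext = ".xyz")
  write_xyz(list(), empty)
  expect_length(read_xyz(empty), 0)

  # malformed vertex count: error names the line
  lines <- readLines(path)
  lines[1] <- "14"
  bad <- tempfile(fileext = ".xyz")
  writeLines(lines, bad)
  expect_error(read_xyz(bad, b = NA), ":")
})

test_that("fixture labels are stable under rotation and densification", {
  set.seed(123)
  fixtures <- list(
    right = make_curve(torus_knot_spec(2, 3)),
    left = make_curve(torus_knot_spec(2, 3, handedness = "left"))
  )
  for (nm in names(fixtures)) {
    ref <- classify_polygon(fixtures[[nm]])
    expect_identical(ref$handedness, nm)
    for (k in 1:10) {
      rot <- knot_polygon(rigid_motion(fixtures[[nm]],
                                       angles = runif(3, -pi, pi),
                                       shift = rnorm(3, sd = 5)))
      lab <- classify_polygon(rot)
      expect_identical(lab$type, ref$type)
      expect_identical(lab$handedness, ref$handedness)
    }
    lab_d <- classify_polygon(densify_polygon(fixtures[[nm]]))
    expect_identical(lab_d$handedness, ref$handedness)
  }
})

test_that("the CLI chains sample, knots, and census reproducibly", {
  dir <- tempfile("cli")
  dir.create(dir)
  out <- file.path(dir, "run")
  args <- c("pipeline", "--eps-b", "1", "--u", "0", "--d", "10", "--R", "0",
            "--N", "60", "--n-samples", "40", "--seed", "7",
            "--out", out)
  helixknot_main(args)
  expect_true(file.exists(paste0(out, ".xyz")))
  expect_true(file.exists(paste0(out, "_knots.csv")))
  expect_true(file.exists(paste0(out, "_census.json")))
  labs <- utils::read.csv(paste0(out, "_knots.csv"))
  expect_equal(nrow(labs), 40L)
  cen <- jsonlite::read_json(paste0(out, "_census.json"))
  expect_true("P_k" %in% names(cen[[1]]))
  # rerun with the same seed: identical trajectory file
  out2 <- file.path(dir, "run2")
  helixknot_main(c("pipeline", "--eps-b", "1", "--u", "0", "--d", "10",
                   "--R", "0", "--N", "60", "--n-samples", "40",
                   "--seed", "7", "--out", out2))
  expect_identical(readLines(paste0(out, ".xyz")),
                   readLines(paste0(out2, ".xyz")))
})

test_that("observables and census verbs process a trajectory", {
  dir <- tempfile("cli3")
  dir.create(dir)
  traj <- file.path(dir, "traj.xyz")
  helixknot_main(c("sample", "--eps-b", "2", "--u", "0.4", "--N", "40",
                   "--n-samples", "15", "--seed", "5", "--out", traj))
  obs <- file.path(dir, "obs.csv")
  smry <- file.path(dir, "summary.csv")
  helixknot_main(c("observables", "--traj", traj, "--eps-b", "2", "--u",
                   "0.4", "--N", "40", "--out", obs, "--summary", smry))
  o <- utils::read.csv(obs)
  expect_equal(nrow(o), 15L)
  expect_true(all(c("tau_mean", "E_chiral") %in% names(o)))
  s <- utils::read.csv(smry)
  expect_true(all(c("tau", "C_c", "se_Cc") %in% names(s)))

  knots <- file.path(dir, "knots.csv")
  helixknot_main(c("knots", "--traj", traj, "--out", knots))
  cen <- file.path(dir, "census.json")
  helixknot_main(c("census", "--labels", knots, "--u", "0.4",
                   "--traj", traj, "--screen-rmin", "1.5", "--d", "10",
                   "--out", cen))
  j <- jsonlite::read_json(cen)
  expect_true(all(c("census", "screened", "r_min") %in% names(j)))
})

test_that("sample and knots verbs write coherent artifacts", {
  dir <- tempfile("cli2")
  dir.create(dir)
  traj <- file.path(dir, "traj.xyz")
  helixknot_main(c("sample", "--eps-b", "2", "--u", "0.3", "--N", "30",
                   "--n-samples", "10", "--seed", "3", "--out", traj))
  expect_true(file.exists(traj))
  sidecar <- jsonlite::read_json(sub("xyz$", "json", traj))
  expect_equal(sidecar$params$u, 0.3)
  expect_equal(sidecar$mc$seed, 3L)
  expect_length(read_xyz(traj), 10)
  knots <- file.path(dir, "knots.csv")
  helixknot_main(c("knots", "--traj", traj, "--out", knots))
  expect_equal(nrow(utils::read.csv(knots)), 10L)
})
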