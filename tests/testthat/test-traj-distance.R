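test_that("Kabsch RMSD is zero for congruent sets and rigid motions", {
  set.seed(41)
  ref <- matrix(stats::rnorm(30, sd = 5), ncol = 3)
  expect_equal(kabsch_rmsd(ref, ref), 0, tolerance = 1e-12)

  th <- 30 * pi / 180
  rot30 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                  byrow = TRUE)
  moved <- sweep(ref %*% t(rot30), 2, c(5, 5, 5), `+`)
  expect_lt(kabsch_rmsd(ref, moved), 1e-9)
  sup <- kabsch_superpose(ref, moved)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_equal(sup$aligned, ref, tolerance = 1e-9)
})

test_that("Kabsch RMSD is symmetric and rigid-motion invariant", {
  set.seed(42)
  for (i in 1:10) {
    a <- matrix(stats::rnorm(24, sd = 4), ncol = 3)
    b <- a + matrix(stats::rnorm(24, sd = 0.7), ncol = 3)
    r1 <- kabsch_rmsd(a, b)
    expect_equal(kabsch_rmsd(b, a), r1, tolerance = 1e-9)
    moved <- sweep(b %*% t(random_rotation()), 2, stats::rnorm(3, sd = 10),
                   `+`)
    expect_equal(kabsch_rmsd(a, moved), r1, tolerance = 1e-9)
    expect_equal(det(kabsch_superpose(a, b)$rotation), 1, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD matches the rotation-grid brute-force oracle", {
  square <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), ncol = 3,
                   byrow = TRUE)
  displaced <- square
  displaced[3, ] <- displaced[3, ] + c(0, 0, 1)
  expect_equal(kabsch_rmsd(square, displaced),
               brute_force_rmsd(square, displaced), tolerance = 1e-6)

  set.seed(43)
  for (i in 1:3) {
    a <- matrix(stats::rnorm(12, sd = 2), ncol = 3)
    b <- a + matrix(stats::rnorm(12, sd = 0.5), ncol = 3)
    expect_equal(kabsch_rmsd(a, b), brute_force_rmsd(a, b),
                 tolerance = 1e-6)
  }

  expect_error(kabsch_rmsd(square, square[1:3, ]), "mismatched")
  expect_error(kabsch_rmsd(square[1:2, ], square[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD agrees with the bio3d reference implementation", {
  set.seed(44)
  a <- matrix(stats::rnorm(30, sd = 5), ncol = 3)
  b <- a + matrix(stats::rnorm(30, sd = 1), ncol = 3)
  ours <- kabsch_rmsd(a, b)
  # bio3d::rmsd rounds its result to three decimals
  theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_lt(abs(ours - theirs), 1e-3)
})

test_that("distance series computes per-frame separations and flags degeneracy", {
  tr <- trajectory_from_distances(rep(29.2, 50), 0.02)
  d <- distance_series(tr, c("siteA", "siteB"))
  expect_equal(d$values, rep(29.2, 50))
  expect_equal(d$times, (0:49) * 0.02)
  expect_error(distance_series(tr, c("siteA", "nope")), "unknown site")

  coords <- array(0, dim = c(2, 2, 3),
                  dimnames = list(NULL, c("p", "q"), c("x", "y", "z")))
  coords[1, 2, 1] <- 3
  tr2 <- labeled_trajectory(coords, 0.02)
  expect_warning(d2 <- distance_series(tr2, c("p", "q")), "coincident")
  expect_equal(d2$values, c(3, 0))
})

test_that("stationary trajectory statistics match the generator", {
  tr <- simulate_trajectory(1250, 0.02, 32.2, 1.4, 2, seed = 51)
  d <- distance_series(tr, c("siteA", "siteB"))
  v <- d$values[-(1:50)]
  phi <- exp(-1 / 2)
  se <- 1.4 * sqrt(((1 + phi) / (1 - phi)) / length(v))
  expect_lt(abs(mean(v) - 32.2), 3 * se)
  expect_lt(abs(stats::sd(v) - 1.4), 0.2)
})

test_that("equilibration detection finds plateaus and rejects monotone drift", {
  const <- list(times = (0:999) * 0.02, values = rep(22, 1000))
  r <- detect_equilibration(const, window = 1)
  expect_equal(r$t_eq, 0)
  expect_true(r$equilibrated)
  expect_equal(r$equilibrium_mean, 22)
  expect_equal(r$equilibrium_sd, 0)

  # step from 40 to 30 Angstrom at t = 10 ns
  t <- (0:999) * 0.02
  step <- list(times = t, values = ifelse(t < 10, 40, 30))
  r2 <- detect_equilibration(step, window = 1, drift_tol = 1)
  expect_true(r2$equilibrated)
  expect_lt(abs(r2$t_eq - 10), 1)
  # from the true changepoint the plateau value is recovered exactly
  expect_equal(unname(summarize_equilibrium(step, 10)["mean"]), 30)
  expect_lt(abs(r2$equilibrium_mean - 30), 0.2)

  # monotone drift throughout: criterion never satisfied
  drift <- list(times = t, values = 29 + t)
  r3 <- detect_equilibration(drift, window = 2, drift_tol = 1)
  expect_false(r3$equilibrated)
  expect_equal(r3$t_eq, max(t))
  expect_true(is.na(r3$equilibrium_mean))
})

test_that("auxiliary series extends the equilibration time", {
  t <- (0:999) * 0.02
  main <- list(times = t, values = ifelse(t < 5, 40, 30))
  aux <- list(times = t, values = ifelse(t < 10, 3, 0.5))
  r_main <- detect_equilibration(main, window = 1, drift_tol = 1)
  r_both <- detect_equilibration(main, aux = aux, window = 1,
                                 drift_tol = 1, aux_drift_tol = 0.5)
  expect_lt(abs(r_main$t_eq - 5), 1)
  expect_lt(abs(r_both$t_eq - 10), 1)
})

test_that("equilibration detection is idempotent on the equilibrated tail", {
  # deterministic exponential relaxation towards 30 Angstrom
  tr <- simulate_trajectory(2000, 0.02, 30, fluctuation_sd = 0,
                            relaxation_frames = 100, initial_offset = 8)
  d <- distance_series(tr, c("siteA", "siteB"))
  r <- detect_equilibration(d, window = 5, drift_tol = 1)
  expect_gt(r$t_eq, 0)
  post <- list(times = d$times[d$times > r$t_eq],
               values = d$values[d$times > r$t_eq])
  r2 <- detect_equilibration(post, window = 5, drift_tol = 1)
  expect_equal(r2$t_eq, 0)
})

test_that("equilibrium summary is the post-equilibration mean and SD", {
  const <- list(times = 0:9, values = rep(22, 10))
  expect_equal(summarize_equilibrium(const, 0),
               c(mean = 22, sd = 0))
  two <- list(times = c(1, 2), values = c(28, 30))
  expect_equal(summarize_equilibrium(two, 0), c(mean = 29, sd = sqrt(2)))
  expect_error(summarize_equilibrium(two, 5), "no frames")

  tr <- simulate_trajectory(1250, 0.02, 29.1, 1.6, 2, seed = 52)
  d <- distance_series(tr, c("siteA", "siteB"))
  s <- summarize_equilibrium(d, 0)
  phi <- exp(-1 / 2)
  se <- 1.6 * sqrt(((1 + phi) / (1 - phi)) / (length(d$values) - 1))
  expect_lt(abs(s["mean"] - 29.1), 3 * se)
})

test_that("pipeline recovers the generating distance in every condition", {
  conditions <- list(c(29.2, 1.3), c(29.1, 1.6), c(32.2, 1.4))
  phi <- exp(-1 / 2)
  for (cond in conditions) {
    ok <- vapply(1:20, function(s) {
      tr <- simulate_trajectory(1250, 0.02, cond[1], cond[2], 2,
                                seed = 500 + s)
      d <- distance_series(tr, c("siteA", "siteB"))
      r <- detect_equilibration(d, window = 5, drift_tol = 1)
      n_post <- sum(d$times > r$t_eq)
      se <- cond[2] * sqrt(((1 + phi) / (1 - phi)) / n_post)
      r$equilibrated && abs(r$equilibrium_mean - cond[1]) < 3 * se
    }, logical(1))
    expect_gte(sum(ok), 19)
  }
})

test_that("backbone RMSD series is zero at the reference and tracks motion", {
  set.seed(45)
  base <- matrix(stats::rnorm(60, sd = 6), ncol = 3)
  n_frames <- 20
  backbone <- array(0, dim = c(n_frames, nrow(base), 3))
  for (f in seq_len(n_frames)) {
    jitter <- matrix(stats::rnorm(60, sd = 0.1 * (f - 1)), ncol = 3)
    moved <- sweep((base + jitter) %*% t(random_rotation()), 2,
                   stats::rnorm(3, sd = 4), `+`)
    backbone[f, , ] <- moved
  }
  sites <- array(0, dim = c(n_frames, 2, 3),
                 dimnames = list(NULL, c("a", "b"), NULL))
  sites[, 2, 1] <- 29
  tr <- labeled_trajectory(sites, 0.02, backbone_coords = backbone)
  rs <- backbone_rmsd_series(tr)
  expect_equal(rs$values[1], 0, tolerance = 1e-9)
  # rigid motion removed by superposition: RMSD reflects only the jitter,
  # which grows with the frame index
  expect_gt(stats::cor(seq_len(n_frames), rs$values), 0.9)
  expect_lt(rs$values[2], 0.5)
})

test_that("XYZ and long CSV trajectory round-trips preserve coordinates", {
  tr <- simulate_trajectory(25, 0.02, 29.2, 1.3, 5, seed = 61,
                            sites = c("C1p_13", "C1p_91"))
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, xyz)
  tr2 <- read_xyz(xyz, frame_dt = 0.02)
  expect_equal(tr2$site_coords, tr$site_coords, tolerance = 1e-5)
  expect_identical(dimnames(tr2$site_coords)[[2]], c("C1p_13", "C1p_91"))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  tr3 <- read_trajectory_csv(csv, frame_dt = 0.02)
  expect_equal(tr3$site_coords, tr$site_coords, tolerance = 1e-9)

  d0 <- distance_series(tr, c("C1p_13", "C1p_91"))$values
  d1 <- distance_series(tr2, c("C1p_13", "C1p_91"))$values
  expect_equal(d1, d0, tolerance = 1e-5)
})
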