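test_that("aperture is the Euclidean tip separation", {
  up <- marker_track("upper_tip", 0:2, c(0, 3, 1), c(1, 4, 1), 300)
  lo <- marker_track("lower_tip", 0:2, c(0, 0, 1), c(0, 0, 1), 300)
  expect_equal(as.numeric(aperture_series(up, lo)), c(1, 5, 0))
  misaligned <- marker_track("lower_tip", 1:3, c(0, 0, 1), c(0, 0, 1), 300)
  expect_error(aperture_series(up, misaligned), "frame-aligned")
})

test_that("fixation detection finds the last pre-reach standstill", {
  # stationary throughout: the first frame qualifies
  still <- marker_track("head", 0:99, rep(1, 100), rep(2, 100), 300)
  expect_identical(detect_fixation(still), 0L)

  # programmed standstill at frames 40-55 between two movements
  fps <- 300
  v1 <- 10 / fps   # 10 cm/s approach
  x <- c(cumsum(rep(v1, 40)),                       # frames 0-39 moving
         rep(40 * v1, 16),                          # frames 40-55 still
         40 * v1 + cumsum(rep(30 / fps, 60)))       # reach at 30 cm/s
  tr <- marker_track("head", seq_along(x) - 1, x, rep(0, length(x)), fps)
  fix <- detect_fixation(tr, speed_threshold = 2, min_still_frames = 10)
  expect_gte(fix, 40)
  expect_lte(fix, 55)

  # constant fast motion never qualifies
  fast <- straight_track(100, step_cm = 50 / 300)
  expect_error(detect_fixation(fast, speed_threshold = 2),
               class = "peckkin_no_fixation")
})

test_that("grasp events follow the 20% rule and the post-maximum minimum", {
  # triangular aperture forces the crossing at exactly 20% of the rise
  ap <- c(seq(0, 1, length.out = 101), seq(1, 0.3, length.out = 50))
  ev <- detect_grasp_events(ap, fixation_frame = 0)
  expect_identical(ev$onset_frame, 20L)
  expect_identical(ev$max_aperture_frame, 100L)
  expect_identical(ev$offset_frame, 150L)
  expect_equal(ev$offset_aperture, 0.3)

  expect_error(detect_grasp_events(seq(1, 0, length.out = 50), 0),
               class = "peckkin_no_opening")

  # simulator ground truth, noise-free: onset within one frame
  pk <- noisefree_peck(seed = 11)
  sm <- lapply(pk$trial[c("head", "upper_tip", "lower_tip")], smooth_track)
  ap2 <- aperture_series(sm$upper_tip, sm$lower_tip)
  ev2 <- detect_grasp_events(ap2, detect_fixation(sm$head),
                             baseline_frames = 10, sustain_frames = 3)
  expect_lte(abs(ev2$onset_frame - pk$truth$true_onset_frame), 1)
})

test_that("event ordering is enforced by the peck_events invariant", {
  expect_error(peck_events(10, 5, 20, 30, 1, 0.2),
               class = "peckkin_event_order")
  expect_error(peck_events(0, 5, 20, 30, 0.1, 0.2),
               class = "peckkin_event_order")
})

test_that("movement distance sums per-frame displacements", {
  expect_equal(movement_distance(straight_track(30), 0, 29), 2.9)
  expect_equal(movement_distance(straight_track(30, step_cm = 0), 0, 29), 0)
  # unit semicircle sampled at 1000 points: arc length pi
  th <- seq(0, pi, length.out = 1000)
  semi <- marker_track("head", 0:999, cos(th), sin(th), 300)
  expect_equal(movement_distance(semi, 0, 999), pi, tolerance = 1e-4)
})

test_that("mean velocity and acceleration obey their algebraic identities", {
  expect_equal(mean_velocity(straight_track(30), 0, 29), 30)
  expect_equal(mean_velocity(straight_track(30, step_cm = 0), 0, 29), 0)
  expect_equal(mean_acceleration(straight_track(40), 0, 39), 0)

  # quadratic position x = 0.5 * 100 * t^2: finite differences exact
  fps <- 300
  t <- (0:89) / fps
  quad <- marker_track("head", 0:89, 0.5 * 100 * t^2, rep(0, 90), fps)
  expect_equal(mean_acceleration(quad, 0, 89), 100, tolerance = 1e-9)

  # identities on irregular wiggly tracks, several windows
  set.seed(42)
  for (k in 1:5) {
    n <- 60
    wig <- marker_track("head", 0:(n - 1), cumsum(rnorm(n, 0, 0.05)),
                        cumsum(rnorm(n, 0, 0.05)), fps)
    a <- sample(0:20, 1)
    b <- a + sample(10:30, 1)
    dur <- (b - a) / fps
    expect_equal(mean_velocity(wig, a, b) * dur,
                 movement_distance(wig, a, b), tolerance = 1e-10)
    v <- sqrt(diff(wig$x[(a + 1):(b + 1)])^2 +
              diff(wig$y[(a + 1):(b + 1)])^2) * fps
    expect_equal(mean_acceleration(wig, a, b),
                 (v[length(v)] - v[1]) / ((length(v) - 1) / fps),
                 tolerance = 1e-10)
  }
})

test_that("path length is invariant under rigid rotation and translation", {
  set.seed(9)
  n <- 80
  x <- cumsum(rnorm(n, 0.05, 0.02))
  y <- cumsum(rnorm(n, 0, 0.03))
  base <- marker_track("head", 0:(n - 1), x, y, 300)
  th <- 0.83
  rot <- marker_track("head", 0:(n - 1),
                      cos(th) * x - sin(th) * y + 4.2,
                      sin(th) * x + cos(th) * y - 1.7, 300)
  expect_equal(movement_distance(rot, 0, n - 1),
               movement_distance(base, 0, n - 1), tolerance = 1e-10)
})

test_that("extraction recovers noise-free simulator ground truth within 2%", {
  for (s in c(3, 17, 29)) {
    pk <- noisefree_peck(seed = s)
    rec <- extract_kinematics(pk$trial)
    expect_true(rec$retained)
    expect_lte(abs(round(rec$onset_s * 300) - pk$truth$true_onset_frame), 1)
    expect_equal(rec$distance_cm, pk$truth$true_path_cm, tolerance = 0.02)
    expect_equal(rec$velocity_cm_s, pk$truth$true_velocity_cm_s,
                 tolerance = 0.02)
    expect_equal(rec$accel_cm_s2, pk$truth$true_accel_cm_s2,
                 tolerance = 0.02)
  }
})

test_that("a marker gap inside the peck window excludes the peck as 'gap'", {
  pk <- noisefree_peck(seed = 13)
  tr <- pk$trial
  drop_at <- pk$truth$true_onset_frame - 2
  keep <- tr$head$frames[tr$head$frames != drop_at]
  i <- match(keep, tr$head$frames)
  tr$head <- marker_track("head", keep, tr$head$x[i], tr$head$y[i], 300)
  rec <- extract_kinematics(tr)
  expect_false(rec$retained)
  expect_identical(rec$exclusion_reason, "gap")
  expect_true(is.na(rec$onset_s))

  # a gap well outside the analysed window does not exclude the peck
  tr2 <- pk$trial
  nfr <- length(tr2$head$frames)
  keep2 <- tr2$head$frames[-(nfr - 1)]   # drop the penultimate tail frame
  i2 <- match(keep2, tr2$head$frames)
  tr2$head <- marker_track("head", keep2, tr2$head$x[i2], tr2$head$y[i2], 300)
  rec2 <- extract_kinematics(tr2)
  expect_true(rec2$retained || rec2$exclusion_reason != "gap")
})

test_that("batch extraction keeps one record per peck and accounts exclusions", {
  sim <- simulate_experiment(sim_config(
    "pigeon", individuals = 2,
    pecks_per_phase = setNames(rep(3, 7), phase_levels()), seed = 8
  ))
  kin <- kinematics_table(sim$trials)
  expect_identical(nrow(kin), 21L)
  expect_identical(sum(kin$retained) + sum(!kin$retained), 21L)
  # retained pecks respect the event-derived sign constraints
  r <- kin[kin$retained, ]
  expect_true(all(r$onset_s >= 0))
  expect_true(all(r$distance_cm >= 0))
  expect_true(all(r$velocity_cm_s >= 0))
})

test_that("onset recovery at study-scale tracking noise stays within 2 frames", {
  hits <- vapply(1:200, function(s) {
    pk <- simulate_peck(species_params("pigeon"), seed = 1000 + s)
    rec <- extract_kinematics(pk$trial)
    isTRUE(rec$retained) &&
      abs(round(rec$onset_s * 300) - pk$truth$true_onset_frame) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("mean trajectories average path-resampled pecks", {
  pk <- noisefree_peck(seed = 21)$trial
  # five identical copies: zero dispersion everywhere
  mt <- mean_trajectory(rep(list(pk), 5), marker = "head", n_points = 50)
  expect_lt(max(mt$x_sd, mt$y_sd), 1e-10)
  expect_identical(attr(mt, "n_pecks"), 5L)

  # mirror image about y = c: mean path has y identically c
  c0 <- 1.4
  mirror <- pk
  for (role in c("head", "upper_tip", "lower_tip")) {
    mirror[[role]]$y <- 2 * c0 - mirror[[role]]$y
  }
  mt2 <- mean_trajectory(list(pk, mirror), marker = "head", n_points = 40)
  expect_equal(mt2$y_mean, rep(c0, 40), tolerance = 1e-8)

  expect_error(mean_trajectory(list(pk), marker = "head"), "at least 2")
})
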