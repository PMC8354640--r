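test_that("zero motion, noise and drift yield identical frames", {
  gen <- generate_heart(synthetic_heart_params(noise_sigma_um = 0, seed = 3))
  r <- gen$tracks$records
  f0 <- r[r$t_index == 0, c("x_um", "y_um", "z_um")]
  for (k in unique(r$t_index)) {
    fk <- r[r$t_index == k, c("x_um", "y_um", "z_um")]
    expect_equal(unname(as.matrix(fk)), unname(as.matrix(f0)), tolerance = 1e-12)
  }
})

test_that("the same seed reproduces the track set exactly; different seeds differ", {
  p <- synthetic_heart_params(omega_ventricle_deg_h = -8, seed = 17)
  g1 <- generate_heart(p)
  g2 <- generate_heart(p)
  expect_identical(g1$tracks$records, g2$tracks$records)
  expect_identical(g1$truth$frames, g2$truth$frames)
  p2 <- synthetic_heart_params(omega_ventricle_deg_h = -8, seed = 18)
  g3 <- generate_heart(p2)
  expect_false(isTRUE(all.equal(g1$tracks$records$x_um,
                                g3$tracks$records$x_um)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_heart(synthetic_heart_params(seed = 1)))
  expect_identical(runif(1), before)
})

test_that("noise-free frame-to-frame cell motion equals the imposed spin", {
  p <- synthetic_heart_params(omega_ventricle_deg_h = -8,
                              omega_atrium_deg_h = 6,
                              noise_sigma_um = 0, seed = 5)
  gen <- generate_heart(p)
  r <- gen$tracks$records
  dt <- p$frame_period_hours
  # rotation-matrix oracle: positions at frame k must equal the frame k-1
  # positions advanced by one interval's spin about the segment axis
  for (reg in c("ventricle", "atrium")) {
    axis <- if (reg == "ventricle") c(1, 0, 0) else c(-1, 0, 0)
    om <- if (reg == "ventricle") -8 else 6
    R_step <- quat_rotation(axis, om * dt)
    rr <- r[r$region == reg, ]
    for (k in 1:3) {
      prev <- as.matrix(rr[rr$t_index == k - 1, c("x_um", "y_um", "z_um")])
      cur <- as.matrix(rr[rr$t_index == k, c("x_um", "y_um", "z_um")])
      expect_equal(cur, prev %*% t(R_step), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("ground truth records the imposed kinematics", {
  p <- synthetic_heart_params(omega_ventricle_deg_h = -8,
                              omega_atrium_deg_h = 6,
                              bend_rate_deg_h = 2,
                              drift_um_per_h = c(1, 0, -1), seed = 2)
  tr <- generate_heart(p)$truth$frames
  t_end <- tr$t_hours[nrow(tr)]
  expect_equal(t_end, 45 * 13 / 60)
  expect_equal(tr$spin_ventricle_deg[nrow(tr)], -8 * t_end)
  expect_equal(tr$spin_atrium_deg[nrow(tr)], 6 * t_end)
  expect_equal(tr$hinge_angle_deg[nrow(tr)], 2 * t_end)
  expect_equal(tr$drift_x_um, tr$t_hours * 1)
})

test_that("piecewise omega accumulates interval by interval", {
  om <- c(rep(-10, 20), rep(0, 25))
  p <- synthetic_heart_params(omega_ventricle_deg_h = om,
                              noise_sigma_um = 0, seed = 2)
  tr <- generate_heart(p)$truth$frames
  expect_equal(tr$spin_ventricle_deg[21], -10 * 20 * 13 / 60)
  expect_equal(tr$spin_ventricle_deg[46], -10 * 20 * 13 / 60)
})

test_that("dropout interacts with the length filter as a brute-force count predicts", {
  p <- synthetic_heart_params(dropout = 0.5, seed = 23)
  gen <- generate_heart(p)
  lens <- table(gen$tracks$records$track_id)
  expected <- sum(as.integer(lens) >= 15L)
  f <- suppressMessages(filter_min_length(gen$tracks, 15L))
  expect_equal(length(unique(f$records$track_id)), expected)
  expect_lt(expected, 140L)   # dropout did truncate some tracks
})

test_that("invalid parameters are rejected", {
  expect_error(synthetic_heart_params(radius_chamber_um = 2000), "radius")
  expect_error(synthetic_heart_params(dropout = 1.5), "dropout")
  expect_error(synthetic_heart_params(n_frames = 1), "two frames")
  expect_error(synthetic_heart_params(omega_ventricle_deg_h = c(1, 2, 3)),
               "per inter-frame interval")
})

test_that("the fixture suite writes five scenarios with ground-truth sidecars", {
  dir <- withr::local_tempdir()
  paths <- make_fixture_suite(dir, seed = 1)
  expect_length(paths, 5L)
  expect_setequal(names(paths),
                  c("wt_like", "oug_like", "bending_only", "drift_only",
                    "noise_sweep"))
  expect_true(all(file.exists(paths)))
  sidecars <- file.path(dir, paste0(names(paths), "_truth.json"))
  expect_true(all(file.exists(sidecars)))
  oug <- jsonlite::read_json(file.path(dir, "oug_like_truth.json"),
                             simplifyVector = TRUE)
  expect_true(all(oug$frames$spin_ventricle_deg == 0))
  expect_true(all(oug$frames$spin_atrium_deg == 0))
  wt <- jsonlite::read_json(file.path(dir, "wt_like_truth.json"),
                            simplifyVector = TRUE)
  tw <- wt$frames$spin_atrium_deg - wt$frames$spin_ventricle_deg
  t_h <- wt$frames$t_hours
  # imposed twist after 9 h of (6 - (-8)) deg/h
  expect_equal(stats::approx(t_h, tw, xout = 9)$y, 14 * 9, tolerance = 1e-9)
  # the CSVs are readable track sets
  ts <- read_tracks(paths[["wt_like"]])
  expect_equal(length(unique(ts$records$track_id)), 140L)
})
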