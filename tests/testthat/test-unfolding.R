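test_that("compute_axes returns per-frame centroid axes and names missing regions", {
  d <- rbind(
    make_records(c("av1", "av2"), 0L, c(1, -1), c(1, -1), 0, "avcanal"),
    make_records("v1", 0L, 5, 0, 0, "ventricle"),
    make_records("a1", 0L, 0, -5, 0, "atrium")
  )
  af <- compute_axes(track_set(d))
  expect_equal(as.numeric(af[1, c("av_x", "av_y", "av_z")]), c(0, 0, 0))
  expect_equal(as.numeric(af[1, c("ventricle_x", "ventricle_y", "ventricle_z")]),
               c(1, 0, 0))
  expect_equal(as.numeric(af[1, c("atrium_x", "atrium_y", "atrium_z")]),
               c(0, -1, 0))
  # identical frames give identical axis rows
  ts2 <- toy_heart_movie(spin_v_deg = c(0, 0, 0))
  af2 <- compute_axes(ts2)
  for (cc in setdiff(names(af2), c("t_index", "t_hours"))) {
    expect_equal(af2[[cc]], rep(af2[[cc]][1], 3))
  }
  # a frame lacking a region is an error naming frame and region
  miss <- d[d$region != "atrium", ]
  expect_error(compute_axes(track_set(miss)), "frame 0.*'atrium'")
})

test_that("compute_axes matches an independent centroid/normalize oracle per frame", {
  gen <- generate_heart(synthetic_heart_params(
    n_ventricle = 8L, n_avcanal = 4L, n_atrium = 8L, n_frames = 5L,
    omega_ventricle_deg_h = -8, omega_atrium_deg_h = 6,
    bend_rate_deg_h = 3, seed = 13
  ))
  af <- compute_axes(gen$tracks)
  r <- gen$tracks$records
  for (k in seq_len(nrow(af))) {
    fr <- r[r$t_index == af$t_index[k], ]
    av <- colMeans(as.matrix(fr[fr$region == "avcanal", c("x_um", "y_um", "z_um")]))
    for (reg in c("ventricle", "atrium")) {
      cm <- colMeans(as.matrix(fr[fr$region == reg, c("x_um", "y_um", "z_um")]))
      ax <- (cm - av) / sqrt(sum((cm - av)^2))
      expect_equal(as.numeric(af[k, paste0(reg, c("_x", "_y", "_z"))]),
                   unname(ax), tolerance = 1e-12)
    }
  }
})

test_that("unfolding is the identity for a static, already-rooted heart", {
  ts <- toy_heart_movie(spin_v_deg = c(0, 0, 0))
  u <- root_and_unfold(ts)
  expect_equal(u$records[, c("x_um", "y_um", "z_um")],
               ts$records[, c("x_um", "y_um", "z_um")], tolerance = 1e-12)
})

test_that("rooting removes any whole-heart translation drift exactly", {
  spins <- c(0, 2, 4, 6)
  clean <- root_and_unfold(toy_heart_movie(spin_v_deg = spins))
  set.seed(7)
  shifts <- matrix(rnorm(12, sd = 20), 4, 3)
  drifted <- root_and_unfold(toy_heart_movie(spin_v_deg = spins, shifts = shifts))
  expect_equal(drifted$records[, c("x_um", "y_um", "z_um")],
               clean$records[, c("x_um", "y_um", "z_um")], tolerance = 1e-9)
})

test_that("after unfolding, every frame's chamber axes equal the reference axes", {
  gen <- generate_heart(synthetic_heart_params(
    omega_ventricle_deg_h = -8, omega_atrium_deg_h = 6,
    bend_rate_deg_h = 3, seed = 4
  ))
  u <- root_and_unfold(gen$tracks)
  af <- compute_axes(u)
  ref <- u$reference_axes
  for (cc in c("av_x", "av_y", "av_z")) {
    expect_lt(max(abs(af[[cc]])), 1e-9)
  }
  for (cc in paste0(rep(c("ventricle", "atrium"), each = 3), c("_x", "_y", "_z"))) {
    expect_lt(max(abs(af[[cc]] - ref[[cc]])), 1e-9)
  }
})

test_that("unfolding preserves within-chamber pairwise distances (rigidity)", {
  gen <- generate_heart(synthetic_heart_params(
    n_ventricle = 12L, n_avcanal = 6L, n_atrium = 12L, n_frames = 8L,
    omega_ventricle_deg_h = -8, omega_atrium_deg_h = 6, bend_rate_deg_h = 3,
    seed = 6
  ))
  u <- root_and_unfold(gen$tracks)
  for (k in c(0L, 4L, 7L)) {
    for (reg in c("ventricle", "atrium", "avcanal")) {
      sel <- gen$tracks$records$t_index == k & gen$tracks$records$region == reg
      before <- dist(as.matrix(gen$tracks$records[sel, c("x_um", "y_um", "z_um")]))
      after <- dist(as.matrix(u$records[sel, c("x_um", "y_um", "z_um")]))
      expect_lt(max(abs(before - after)), 1e-9)
    }
  }
})

test_that("a rigid constant spin is recovered in closed form", {
  # +2 degrees per 13-min frame about the ventricle axis
  n <- 46
  ts <- toy_heart_movie(spin_v_deg = 2 * (seq_len(n) - 1))
  rs <- chamber_rotation(root_and_unfold(ts), "ventricle")
  expect_equal(rs$mean_alpha_deg, rep(2, n - 1), tolerance = 1e-9)
  expect_equal(rs$omega_deg_per_h, rep(2 / (13 / 60), n - 1), tolerance = 1e-9)
  expect_equal(rs$cum_angle_deg[n - 1], 90, tolerance = 1e-9)
  expect_true(all(rs$n_cells == 4))
  # static cells: zero everywhere
  rs0 <- chamber_rotation(root_and_unfold(toy_heart_movie(numeric(5))), "atrium")
  expect_equal(rs0$mean_alpha_deg, rep(0, 4))
  expect_equal(rs0$cum_angle_deg, rep(0, 4))
})

test_that("the AV canal needs an explicit reference axis", {
  u <- root_and_unfold(toy_heart_movie(c(0, 2, 4)))
  expect_error(chamber_rotation(u, "avcanal"), "explicit reference axis")
  rs_v <- chamber_rotation(u, "avcanal", axis = "ventricle")
  rs_a <- chamber_rotation(u, "avcanal", axis = "atrium")
  expect_equal(nrow(rs_v), 2L)
  # the hinge is static here: zero rotation about both axes
  expect_equal(rs_v$cum_angle_deg, c(0, 0), tolerance = 1e-9)
  expect_equal(rs_a$cum_angle_deg, c(0, 0), tolerance = 1e-9)
})

test_that("per-frame global translations leave every rotation value unchanged", {
  p <- synthetic_heart_params(omega_ventricle_deg_h = -8,
                              omega_atrium_deg_h = 6, seed = 8)
  gen <- generate_heart(p)
  base <- run_pipeline(gen$tracks)
  set.seed(15)
  shifted <- gen$tracks
  for (k in unique(shifted$records$t_index)) {
    sel <- shifted$records$t_index == k
    sh <- rnorm(3, sd = 50)
    shifted$records$x_um[sel] <- shifted$records$x_um[sel] + sh[1]
    shifted$records$y_um[sel] <- shifted$records$y_um[sel] + sh[2]
    shifted$records$z_um[sel] <- shifted$records$z_um[sel] + sh[3]
  }
  moved <- run_pipeline(shifted)
  for (nm in names(base$rotation)) {
    for (cc in c("mean_alpha_deg", "omega_deg_per_h", "cum_angle_deg")) {
      expect_lt(max(abs(base$rotation[[nm]][[cc]] - moved$rotation[[nm]][[cc]])),
                1e-9)
    }
  }
})

test_that("one fixed global rotation changes no rotation value beyond 1e-6", {
  gen <- generate_heart(synthetic_heart_params(
    omega_ventricle_deg_h = -8, omega_atrium_deg_h = 6, seed = 10
  ))
  base <- run_pipeline(gen$tracks)
  R <- quat_rotation(c(1, 2, 2) / 3, 37)
  rot <- gen$tracks
  m <- as.matrix(rot$records[, c("x_um", "y_um", "z_um")]) %*% t(R)
  rot$records$x_um <- m[, 1]; rot$records$y_um <- m[, 2]; rot$records$z_um <- m[, 3]
  turned <- run_pipeline(rot)
  for (nm in names(base$rotation)) {
    expect_lt(max(abs(base$rotation[[nm]]$cum_angle_deg -
                      turned$rotation[[nm]]$cum_angle_deg)), 1e-6)
  }
})

test_that("cumulative rotation is additive across a split when the halves share reference axes", {
  gen <- generate_heart(synthetic_heart_params(
    omega_ventricle_deg_h = -8, omega_atrium_deg_h = 6, bend_rate_deg_h = 2,
    seed = 12
  ))
  full_u <- root_and_unfold(gen$tracks)
  full <- chamber_rotation(full_u, "atrium")
  split_at <- 22L
  lo <- gen$tracks; lo$records <- lo$records[lo$records$t_index <= split_at, ]
  hi <- gen$tracks; hi$records <- hi$records[hi$records$t_index >= split_at, ]
  ref <- full_u$reference_axes
  th_lo <- chamber_rotation(root_and_unfold(lo, reference = ref), "atrium")
  th_hi <- chamber_rotation(root_and_unfold(hi, reference = ref), "atrium")
  expect_lt(abs(full$cum_angle_deg[nrow(full)] -
                (th_lo$cum_angle_deg[nrow(th_lo)] +
                 th_hi$cum_angle_deg[nrow(th_hi)])), 1e-9)
})

test_that("track gaps contribute their angle spread over the spanned intervals", {
  # one cell with a missing middle frame, constant spin 2 deg/frame
  n <- 5
  ts <- toy_heart_movie(spin_v_deg = 2 * (seq_len(n) - 1))
  gap <- ts
  gap$records <- gap$records[!(gap$records$track_id == "c05" &
                               gap$records$t_index == 2L), ]
  u <- root_and_unfold(gap)
  rs_scale <- chamber_rotation(u, "ventricle", gap_policy = "scale")
  # intervals 2 and 3 get the gapped cell's 4-degree angle split evenly
  expect_equal(rs_scale$mean_alpha_deg, rep(2, n - 1), tolerance = 1e-9)
  expect_equal(rs_scale$cum_angle_deg[n - 1], 2 * (n - 1), tolerance = 1e-9)
  rs_drop <- chamber_rotation(u, "ventricle", gap_policy = "drop")
  expect_true(all(rs_drop$n_cells[c(2, 3)] == 3))
  expect_equal(rs_drop$mean_alpha_deg, rep(2, n - 1), tolerance = 1e-9)
})

test_that("windowed angular velocity matches a brute-force grouping oracle", {
  # constant omega: every window equals it
  n <- 46
  ts <- toy_heart_movie(spin_v_deg = 2 * (seq_len(n) - 1))
  rs <- chamber_rotation(root_and_unfold(ts), "ventricle")
  w <- windowed_angular_velocity(rs, 1.5)
  expect_equal(w$mean_omega_deg_per_h[!w$partial],
               rep(2 / (13 / 60), sum(!w$partial)), tolerance = 1e-9)
  expect_true(w$partial[nrow(w)])
  # piecewise +4 then -4 deg/h over two exact windows (dt = 0.25 h)
  ts2 <- toy_heart_movie(spin_v_deg = cumsum(c(0, rep(1, 6), rep(-1, 6))),
                         frame_period = 0.25)
  rs2 <- chamber_rotation(root_and_unfold(ts2), "ventricle")
  w2 <- windowed_angular_velocity(rs2, 1.5)
  expect_equal(w2$mean_omega_deg_per_h, c(4, -4), tolerance = 1e-9)
  # noisy profile against an independent grouping computation
  gen <- generate_heart(synthetic_heart_params(
    omega_ventricle_deg_h = -8, omega_atrium_deg_h = 6, seed = 20
  ))
  rs3 <- chamber_rotation(root_and_unfold(gen$tracks), "atrium")
  w3 <- windowed_angular_velocity(rs3, 1.5)
  grp <- floor((rs3$t_mid - rs3$t_start[1]) / 1.5)
  oracle <- tapply(rs3$omega_deg_per_h, grp, mean)
  expect_equal(w3$mean_omega_deg_per_h, unname(as.numeric(oracle)),
               tolerance = 1e-9)
})

test_that("the twisting angle is the atrium-minus-ventricle cumulative difference", {
  n <- 10
  ts <- toy_heart_movie(spin_v_deg = -4 * (seq_len(n) - 1),
                        spin_a_deg = 3 * (seq_len(n) - 1))
  u <- root_and_unfold(ts)
  rs_v <- chamber_rotation(u, "ventricle")
  rs_a <- chamber_rotation(u, "atrium")
  tw <- twisting(rs_v, rs_a)
  expect_equal(tw$series$twist_angle_deg[1], 0)
  expect_equal(tail(tw$series$twist_angle_deg, 1),
               (3 - (-4)) * (n - 1), tolerance = 1e-9)
  # identical series twist to zero
  tw0 <- twisting(rs_v, rs_v)
  expect_true(all(abs(tw0$series$twist_angle_deg) < 1e-12))
  # disjoint grids cannot be aligned
  rs_b <- rs_a
  rs_b$t_mid <- rs_b$t_mid + 100
  expect_error(twisting(rs_v, rs_b), "alignment error")
})
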