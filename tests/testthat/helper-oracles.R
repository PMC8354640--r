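# Independent oracles used across tests. These deliberately take different
# computational routes than the package code they check.

# Rotation matrix via unit quaternion (independent of the package's
# Rodrigues construction).
quat_rotation <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  h <- angle_deg * pi / 180 / 2
  w <- cos(h); x <- sin(h) * a[1]; y <- sin(h) * a[2]; z <- sin(h) * a[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_unit_vectors <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# Area-weighted covariance of a convex polygon's enclosed region by fan
# triangulation from the first vertex, using exact uniform-triangle
# moments E[u] = 1/3, E[u^2] = 1/6, E[uv] = 1/12.
fan_covariance <- function(p) {
  a <- p[1, ]
  S <- matrix(0, 2, 2); M <- c(0, 0); A <- 0
  for (i in 2:(nrow(p) - 1)) {
    b <- p[i, ]; c_ <- p[i + 1, ]
    d1 <- b - a; d2 <- c_ - a
    area <- abs(d1[1] * d2[2] - d1[2] * d2[1]) / 2
    Exx <- tcrossprod(a) +
      (tcrossprod(a, d1) + tcrossprod(d1, a) +
       tcrossprod(a, d2) + tcrossprod(d2, a)) / 3 +
      (tcrossprod(d1) + tcrossprod(d2)) / 6 +
      (tcrossprod(d1, d2) + tcrossprod(d2, d1)) / 12
    S <- S + area * Exx
    M <- M + area * (a + b + c_) / 3
    A <- A + area
  }
  mu <- M / A
  list(area = A, centroid = mu, cov = S / A - tcrossprod(mu))
}

# A seeded random convex polygon (convex hull of random points).
random_convex_polygon <- function(n, seed, scale = 10) {
  set.seed(seed)
  pts <- matrix(runif(2 * n, -scale, scale), ncol = 2)
  hull <- chull(pts)
  pts[hull[length(hull):1], , drop = FALSE]   # counterclockwise order
}

# Minimal valid tracking table builder.
make_records <- function(track_id, t_index, x, y, z, region,
                         t_hours = NULL) {
  d <- data.frame(track_id = track_id, t_index = t_index,
                  x_um = x, y_um = y, z_um = z, region = region,
                  stringsAsFactors = FALSE)
  if (!is.null(t_hours)) d$t_hours <- t_hours
  d
}

# A small rigid three-region heart at one or more frames: AV cells
# symmetric about the origin, chambers offset along +x / -x.
toy_heart_frame <- function(t_index, t_hours, rot_v = diag(3), rot_a = diag(3),
                            shift = c(0, 0, 0)) {
  av <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  ven <- rbind(c(10, 3, 0), c(10, -3, 0), c(14, 0, 3), c(14, 0, -3))
  atr <- rbind(c(-10, 3, 0), c(-10, -3, 0), c(-14, 0, 3), c(-14, 0, -3))
  pos <- rbind(av, ven %*% t(rot_v), atr %*% t(rot_a))
  pos <- sweep(pos, 2, shift, "+")
  make_records(
    track_id = sprintf("c%02d", seq_len(12)),
    t_index = t_index, t_hours = t_hours,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    region = rep(c("avcanal", "ventricle", "atrium"), each = 4)
  )
}

# Multi-frame toy heart with chambers rigidly spun by per-frame angles
# about +x (ventricle) and -x (atrium), optional per-frame shifts.
toy_heart_movie <- function(spin_v_deg, spin_a_deg = NULL,
                            shifts = NULL, frame_period = 13 / 60) {
  n <- length(spin_v_deg)
  if (is.null(spin_a_deg)) spin_a_deg <- numeric(n)
  recs <- lapply(seq_len(n), function(k) {
    sh <- if (is.null(shifts)) c(0, 0, 0) else shifts[k, ]
    toy_heart_frame(k - 1L, (k - 1L) * frame_period,
                    rot_v = quat_rotation(c(1, 0, 0), spin_v_deg[k]),
                    rot_a = quat_rotation(c(-1, 0, 0), spin_a_deg[k]),
                    shift = sh)
  })
  track_set(do.call(rbind, recs), frame_period_hours = frame_period)
}
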