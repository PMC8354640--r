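#' Synthetic heart-tube track generator with known kinematics
#'
#' Stands in for microscopy-derived cardiomyocyte tracks: a two-chamber
#' tube (ventricle and atrium cylinders joined at the AV canal) whose
#' chambers spin about their own axes at imposed angular velocities, with
#' optional planar bending of the atrium about the hinge, whole-heart
#' drift, isotropic Gaussian positional noise and track dropout. The
#' imposed kinematics are returned as ground truth so recovery by the
#' analysis pipeline can be tested.
#'
#' Geometry at the first frame: the AV canal is a cylinder of radius
#' `radius_av_um` spanning `[-length_av_um/2, +length_av_um/2]` along +x;
#' the ventricle cylinder (radius `radius_chamber_um`) continues along +x
#' and the atrium along -x. Cells are uniform random points on each
#' cylinder's lateral surface (the myocardium is an epithelial shell).
#' The ventricle axis stays fixed in space; bending swings only the
#' atrium about the +z hinge axis (one hinge degree of freedom suffices to
#' emulate planar buckling). Per frame the composition order is: spin
#' about the chamber's instantaneous axis, then bending, then drift, then
#' noise.
#'
#' @name synthetic_tube
NULL

#' Parameters of a synthetic heart
#'
#' Defaults emulate the acquisition regime the analysis is designed for:
#' a ~10 h movie (46 frames at ~13 min) of a two-chamber tube at 28-38
#' hpf scale, with ~1 um positional noise.
#'
#' @param n_ventricle,n_avcanal,n_atrium cells per region.
#' @param radius_chamber_um,radius_av_um cylinder radii, microns.
#' @param length_ventricle_um,length_av_um,length_atrium_um segment
#'   lengths, microns.
#' @param n_frames number of frames.
#' @param frame_period_hours frame period, hours (default 13/60).
#' @param omega_ventricle_deg_h,omega_atrium_deg_h imposed spin about the
#'   chamber axis, degrees/hour; a scalar (constant) or a numeric vector
#'   of per-interval values (length `n_frames - 1`).
#' @param bend_rate_deg_h hinge-angle change rate (planar buckling),
#'   degrees/hour; swings the atrium about +z.
#' @param drift_um_per_h whole-heart drift velocity, microns/hour
#'   (3-vector).
#' @param noise_sigma_um isotropic Gaussian positional noise SD, microns.
#' @param dropout per-cell probability that the track is truncated at a
#'   uniform random frame.
#' @param seed integer; fixes the entire output.
#' @return a validated parameter list of class `synthetic_heart_params`.
#' @export
synthetic_heart_params <- function(n_ventricle = 60L, n_avcanal = 20L,
                                   n_atrium = 60L,
                                   radius_chamber_um = 25, radius_av_um = 12,
                                   length_ventricle_um = 60, length_av_um = 20,
                                   length_atrium_um = 60,
                                   n_frames = 46L,
                                   frame_period_hours = 13 / 60,
                                   omega_ventricle_deg_h = 0,
                                   omega_atrium_deg_h = 0,
                                   bend_rate_deg_h = 0,
                                   drift_um_per_h = c(0, 0, 0),
                                   noise_sigma_um = 1.0,
                                   dropout = 0,
                                   seed = 1L) {
  p <- list(n_ventricle = as.integer(n_ventricle),
            n_avcanal = as.integer(n_avcanal),
            n_atrium = as.integer(n_atrium),
            radius_chamber_um = radius_chamber_um,
            radius_av_um = radius_av_um,
            length_ventricle_um = length_ventricle_um,
            length_av_um = length_av_um,
            length_atrium_um = length_atrium_um,
            n_frames = as.integer(n_frames),
            frame_period_hours = frame_period_hours,
            omega_ventricle_deg_h = omega_ventricle_deg_h,
            omega_atrium_deg_h = omega_atrium_deg_h,
            bend_rate_deg_h = bend_rate_deg_h,
            drift_um_per_h = as.numeric(drift_um_per_h),
            noise_sigma_um = noise_sigma_um,
            dropout = dropout,
            seed = as.integer(seed))
  with(p, {
    if (any(c(n_ventricle, n_avcanal, n_atrium) < 0L))
      stop("cell counts must be >= 0", call. = FALSE)
    if (any(c(radius_chamber_um, radius_av_um, length_ventricle_um,
              length_av_um, length_atrium_um, noise_sigma_um) < 0))
      stop("radii, lengths and noise sigma must be >= 0", call. = FALSE)
    if (radius_chamber_um > 10 * length_ventricle_um ||
        radius_chamber_um > 10 * length_atrium_um ||
        radius_av_um > 10 * length_av_um)
      stop("parameter error: radius exceeds 10x segment length", call. = FALSE)
    if (n_frames < 2L) stop("need at least two frames", call. = FALSE)
    if (frame_period_hours <= 0) stop("frame period must be positive", call. = FALSE)
    if (dropout < 0 || dropout > 1) stop("dropout must be in [0, 1]", call. = FALSE)
    if (length(drift_um_per_h) != 3L) stop("drift must be a 3-vector", call. = FALSE)
  })
  for (nm in c("omega_ventricle_deg_h", "omega_atrium_deg_h")) {
    v <- p[[nm]]
    if (!length(v) %in% c(1L, p$n_frames - 1L)) {
      stop(nm, " must be a scalar or have one value per inter-frame interval",
           call. = FALSE)
    }
  }
  class(p) <- "synthetic_heart_params"
  p
}

# cumulative imposed angle at each frame time (0 at frame 1)
.cum_angle <- function(omega, dt, n_frames) {
  per_interval <- if (length(omega) == 1L) rep(omega, n_frames - 1L) else omega
  c(0, cumsum(per_interval * dt))
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic heart with known kinematics
#'
#' @param params a [synthetic_heart_params()] object.
#' @return list with `tracks` (a [track_set()], region labels assigned by
#'   construction) and `truth` (a `ground_truth` list: the params and a
#'   per-frame data.frame of imposed spin angles, hinge angle and drift).
#' @export
generate_heart <- function(params) {
  stopifnot(inherits(params, "synthetic_heart_params"))
  p <- params
  dt <- rep(p$frame_period_hours, p$n_frames - 1L)
  t_hours <- c(0, cumsum(dt))
  spin_v <- .cum_angle(p$omega_ventricle_deg_h, dt, p$n_frames)
  spin_a <- .cum_angle(p$omega_atrium_deg_h, dt, p$n_frames)
  hinge <- .cum_angle(p$bend_rate_deg_h, dt, p$n_frames)
  drift <- outer(t_hours, p$drift_um_per_h)      # n_frames x 3

  res <- .with_seed(p$seed, {
    # Antipodal-pair placement on the lateral surface: each drawn (s, phi)
    # yields cells at phi and phi + pi, so the empirical centroid of a
    # region lies exactly on its segment axis (and stays there under any
    # rigid spin/bend); AV-canal pairs are additionally mirrored in s so
    # the hinge centroid sits exactly at the origin. Marginally the cells
    # are still uniform on the surface; for odd n the last antipode is
    # dropped.
    place <- function(n, radius, x_lo, x_hi, flip = FALSE, mirror_s = FALSE) {
      if (n == 0L) return(matrix(numeric(0), 0, 3))
      m2 <- ceiling(n / 2)
      s <- runif(m2, x_lo, x_hi)
      phi <- runif(m2, 0, 2 * pi)
      s2 <- if (mirror_s) as.vector(rbind(s, x_lo + x_hi - s)) else rep(s, each = 2)
      phi2 <- as.vector(rbind(phi, phi + pi))
      m <- cbind(s2, radius * cos(phi2), radius * sin(phi2))[seq_len(n), , drop = FALSE]
      if (flip) m[, 1] <- -m[, 1]
      m
    }
    hl <- p$length_av_um / 2
    base_v <- place(p$n_ventricle, p$radius_chamber_um, hl, hl + p$length_ventricle_um)
    base_c <- place(p$n_avcanal, p$radius_av_um, -hl, hl, mirror_s = TRUE)
    base_a <- place(p$n_atrium, p$radius_chamber_um, hl, hl + p$length_atrium_um,
                    flip = TRUE)
    n_total <- p$n_ventricle + p$n_avcanal + p$n_atrium
    last_frame <- rep(p$n_frames, n_total)
    if (p$dropout > 0 && n_total > 0L) {
      cut <- runif(n_total) < p$dropout
      last_frame[cut] <- sample.int(p$n_frames, sum(cut), replace = TRUE)
    }
    noise <- if (p$noise_sigma_um > 0) {
      array(rnorm(n_total * p$n_frames * 3, sd = p$noise_sigma_um),
            dim = c(n_total, p$n_frames, 3))
    } else {
      array(0, dim = c(n_total, p$n_frames, 3))
    }
    list(base_v = base_v, base_c = base_c, base_a = base_a,
         last_frame = last_frame, noise = noise)
  })

  axis_v <- c(1, 0, 0)
  axis_a0 <- c(-1, 0, 0)
  recs <- vector("list", p$n_frames)
  region <- c(rep("ventricle", p$n_ventricle), rep("avcanal", p$n_avcanal),
              rep("atrium", p$n_atrium))
  track_id <- sprintf("cell_%03d", seq_along(region))
  for (k in seq_len(p$n_frames)) {
    Rv <- rotation_matrix(axis_v, spin_v[k])
    Ra_spin <- rotation_matrix(axis_a0, spin_a[k])
    Rbend <- rotation_matrix(c(0, 0, 1), hinge[k])
    pv <- res$base_v %*% t(Rv)
    pc <- res$base_c
    pa <- res$base_a %*% t(Ra_spin) %*% t(Rbend)
    pos <- rbind(pv, pc, pa)
    pos <- sweep(pos, 2, drift[k, ], "+") + res$noise[, k, ]
    alive <- res$last_frame >= k
    recs[[k]] <- data.frame(track_id = track_id[alive],
                            t_index = k - 1L,
                            t_hours = t_hours[k],
                            x_um = pos[alive, 1],
                            y_um = pos[alive, 2],
                            z_um = pos[alive, 3],
                            region = region[alive],
                            stringsAsFactors = FALSE)
  }
  tracks <- track_set(do.call(rbind, recs),
                      frame_period_hours = p$frame_period_hours,
                      provenance = sprintf("synthetic (seed %d)", p$seed))
  truth <- structure(list(
    params = p,
    frames = data.frame(t_index = seq_len(p$n_frames) - 1L,
                        t_hours = t_hours,
                        spin_ventricle_deg = spin_v,
                        spin_atrium_deg = spin_a,
                        hinge_angle_deg = hinge,
                        drift_x_um = drift[, 1],
                        drift_y_um = drift[, 2],
                        drift_z_um = drift[, 3])
  ), class = "ground_truth")
  list(tracks = tracks, truth = truth)
}

.fixture_scenarios <- function(seed) {
  list(
    wt_like = list(omega_ventricle_deg_h = -8, omega_atrium_deg_h = 6,
                   seed = seed),
    oug_like = list(omega_ventricle_deg_h = 0, omega_atrium_deg_h = 0,
                    seed = seed + 1L),
    bending_only = list(bend_rate_deg_h = 30 / (45 * 13 / 60),
                        noise_sigma_um = 0, seed = seed + 2L),
    drift_only = list(drift_um_per_h = c(3, -2, 1), noise_sigma_um = 0,
                      seed = seed + 3L),
    noise_sweep = list(omega_ventricle_deg_h = -8, omega_atrium_deg_h = 6,
                       noise_sigma_um = 2, seed = seed + 4L)
  )
}

#' Write the named fixture scenario suite
#'
#' Writes the five scenario datasets used by the tests and documentation,
#' each as a canonical track CSV plus a JSON ground-truth sidecar:
#' `wt_like` (opposite chamber spins, -8 and +6 deg/h), `oug_like` (no
#' spin, noise only), `bending_only` (30-degree hinge swing over the
#' movie, noise-free), `drift_only`, and `noise_sweep` (wt-like kinematics
#' at doubled noise).
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed base seed; each scenario derives its own from it.
#' @return named character vector of the CSV paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scen <- .fixture_scenarios(as.integer(seed))
  paths <- character(0)
  for (nm in names(scen)) {
    params <- do.call(synthetic_heart_params, scen[[nm]])
    gen <- generate_heart(params)
    csv <- file.path(out_dir, paste0(nm, ".csv"))
    write_tracks(gen$tracks, csv)
    side <- file.path(out_dir, paste0(nm, "_truth.json"))
    jsonlite::write_json(
      list(params = unclass(gen$truth$params), frames = gen$truth$frames),
      side, auto_unbox = TRUE, digits = NA)
    paths[nm] <- csv
  }
  invisible(paths)
}
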