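#' Hinge-rooted computational unfolding and chamber rotation
#'
#' The core procedure: (1) stabilise residual drift by translating every
#' frame so the AV-canal centroid sits at the origin; (2) per frame,
#' rigidly rotate the entire ventricle and the entire atrium about the AV
#' hinge so each chamber's axis overlaps its first-frame direction
#' ("computational unfolding" — this removes bending/buckling of the tube
#' and leaves only rotation about the chamber axes in the data); (3) for
#' each cell and consecutive frame pair, measure the signed angle alpha
#' about the chamber axis, average over cells, divide by the inter-frame
#' interval to get the angular velocity omega, and accumulate the
#' per-interval means into the cumulative rotation angle Theta; (4) the
#' twisting angle is the difference between atrial and ventricular
#' cumulative rotation.
#'
#' @name unfolding
NULL

.frame_grid <- function(records) {
  ord <- order(records$t_index)
  ti <- records$t_index[ord]
  th <- records$t_hours[ord]
  keep <- !duplicated(ti)
  data.frame(t_index = ti[keep], t_hours = th[keep])
}

#' Per-frame AV centroid and chamber axes
#'
#' For every frame present in the track set, computes the AV-canal
#' centroid and the two unit axes running from it to the ventricle and
#' atrium centroids.
#'
#' @param ts a [track_set()].
#' @return a data.frame of class `axis_frames` with columns `t_index`,
#'   `t_hours`, `av_x/y/z` (AV centroid, microns) and `ventricle_x/y/z`,
#'   `atrium_x/y/z` (unit axes).
#' @export
compute_axes <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  r <- ts$records
  grid <- .frame_grid(r)
  out <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    fi <- grid$t_index[k]
    fr <- r[r$t_index == fi, , drop = FALSE]
    for (reg in REGIONS) {
      if (!any(fr$region == reg)) {
        stop(sprintf("axis error: frame %d has no cells in region '%s'", fi, reg),
             call. = FALSE)
      }
    }
    pts <- function(reg) as.matrix(fr[fr$region == reg, c("x_um", "y_um", "z_um")])
    av <- centroid(pts("avcanal"))
    vax <- chamber_axis(av, pts("ventricle"), frame = fi)
    aax <- chamber_axis(av, pts("atrium"), frame = fi)
    out[[k]] <- c(av, vax, aax)
  }
  m <- do.call(rbind, out)
  af <- data.frame(grid,
                   av_x = m[, 1], av_y = m[, 2], av_z = m[, 3],
                   ventricle_x = m[, 4], ventricle_y = m[, 5], ventricle_z = m[, 6],
                   atrium_x = m[, 7], atrium_y = m[, 8], atrium_z = m[, 9])
  class(af) <- c("axis_frames", "data.frame")
  af
}

#' Root the AV centroid at the origin and unfold the chambers
#'
#' Every frame is translated by minus its AV-canal centroid (so the hinge
#' is rooted at the origin throughout, removing whole-heart drift). Then,
#' per frame, ventricle cells are rotated by the minimal rotation taking
#' the frame's ventricle axis onto the first frame's ventricle axis, and
#' atrium cells likewise onto the first-frame atrium axis. Frames are
#' aligned directly to the first frame (not incrementally), so per-step
#' rotation error does not compound. AV-canal cells are translated but
#' never rotated: they are the hinge.
#'
#' @param ts a [track_set()].
#' @param reference optional one-row [compute_axes()] data.frame to align
#'   to instead of this set's own first frame. Splitting a movie and
#'   analysing the parts against the full movie's first-frame axes makes
#'   the cumulative rotation exactly additive across the split.
#' @return an object of class `unfolded_track_set` (also a `track_set`)
#'   with transformed `records`, plus `transforms` (per frame: the
#'   translation and the two [minimal_rotation()]s applied), and
#'   `reference_axes` (the axis row every frame was aligned to).
#' @export
root_and_unfold <- function(ts, reference = NULL) {
  stopifnot(inherits(ts, "track_set"))
  axes <- compute_axes(ts)
  ref <- if (is.null(reference)) axes[1, , drop = FALSE] else {
    stopifnot(is.data.frame(reference), nrow(reference) == 1L)
    reference
  }
  ref_v <- as.numeric(ref[, c("ventricle_x", "ventricle_y", "ventricle_z")])
  ref_a <- as.numeric(ref[, c("atrium_x", "atrium_y", "atrium_z")])
  r <- ts$records
  pos <- as.matrix(r[, c("x_um", "y_um", "z_um")])
  transforms <- vector("list", nrow(axes))
  names(transforms) <- as.character(axes$t_index)
  for (k in seq_len(nrow(axes))) {
    fi <- axes$t_index[k]
    av <- as.numeric(axes[k, c("av_x", "av_y", "av_z")])
    Rv <- minimal_rotation(as.numeric(axes[k, c("ventricle_x", "ventricle_y", "ventricle_z")]), ref_v)
    Ra <- minimal_rotation(as.numeric(axes[k, c("atrium_x", "atrium_y", "atrium_z")]), ref_a)
    in_frame <- r$t_index == fi
    p <- sweep(pos[in_frame, , drop = FALSE], 2, av)   # root hinge at origin
    reg <- r$region[in_frame]
    p[reg == "ventricle", ] <- p[reg == "ventricle", , drop = FALSE] %*% t(Rv$matrix)
    p[reg == "atrium", ] <- p[reg == "atrium", , drop = FALSE] %*% t(Ra$matrix)
    pos[in_frame, ] <- p
    transforms[[k]] <- list(t_index = fi, translation = -av,
                            ventricle = Rv, atrium = Ra)
  }
  out <- ts
  out$records$x_um <- pos[, 1]
  out$records$y_um <- pos[, 2]
  out$records$z_um <- pos[, 3]
  out$transforms <- transforms
  out$reference_axes <- ref
  class(out) <- c("unfolded_track_set", "track_set")
  out
}

.reference_axis <- function(uts, chamber, axis = NULL) {
  if (is.numeric(axis) && length(axis) == 3L) return(.unit(axis))
  pick <- if (is.null(axis)) chamber else axis
  if (identical(pick, "avcanal") || !pick %in% c("ventricle", "atrium")) {
    stop("chamber_rotation for the AV canal needs an explicit reference axis: ",
         "'ventricle', 'atrium', or a unit 3-vector", call. = FALSE)
  }
  as.numeric(uts$reference_axes[, paste0(pick, c("_x", "_y", "_z"))])
}

#' Per-chamber rotation series: alpha, omega, cumulative Theta
#'
#' For each cell of `chamber` present at two consecutive observed frames,
#' the signed angle alpha about the (first-frame, shared-after-unfolding)
#' chamber axis is measured between the two positions. Per inter-frame
#' interval, `mean_alpha` is the unweighted mean over contributing cells,
#' `omega = mean_alpha / dt` with `dt` the actual time difference, and the
#' cumulative rotation `cum_angle` is the running sum of the per-interval
#' means (0 at the start of the movie).
#'
#' Cells lying within `eps_proj` of the axis at either frame have no
#' defined angle and are skipped for that pair (counted in the
#' `n_skipped_pairs` attribute). A cell pair spanning a gap (missing
#' frames) contributes, under `gap_policy = "scale"`, its angle spread
#' over the spanned grid intervals in proportion to each interval's
#' duration (so the total contribution is still the measured angle);
#' under `"drop"` gapped pairs are ignored. Intervals to which no cell
#' contributes are flagged `excluded` and skipped by the accumulation,
#' with a warning.
#'
#' @param uts an [root_and_unfold()] result.
#' @param chamber `"ventricle"`, `"atrium"` or `"avcanal"`.
#' @param axis reference axis override. Required for `"avcanal"` (the
#'   hinge has no axis of its own): `"ventricle"`, `"atrium"`, or a unit
#'   3-vector.
#' @param eps_proj minimum perpendicular distance from the axis, microns.
#' @param gap_policy `"scale"` (default) or `"drop"`, see above.
#' @return data.frame of class `rotation_series` with one row per
#'   inter-frame interval: `chamber`, `t_start`, `t_mid`, `t_end`,
#'   `dt_hours`, `mean_alpha_deg`, `omega_deg_per_h`, `cum_angle_deg`,
#'   `n_cells`, `excluded`. Attributes: `chamber`, `axis`, `t0`,
#'   `n_skipped_pairs`.
#' @export
chamber_rotation <- function(uts, chamber, axis = NULL, eps_proj = 0.5,
                             gap_policy = c("scale", "drop")) {
  stopifnot(inherits(uts, "unfolded_track_set"))
  chamber <- match.arg(chamber, REGIONS)
  gap_policy <- match.arg(gap_policy)
  a <- .reference_axis(uts, chamber, axis)
  grid <- .frame_grid(uts$records)
  K <- nrow(grid)
  if (K < 2L) stop("need at least two frames for a rotation series", call. = FALSE)
  grid_dt <- diff(grid$t_hours)

  r <- uts$records[uts$records$region == chamber, , drop = FALSE]
  # consecutive observed pairs within each track (records are sorted)
  same <- r$track_id[-nrow(r)] == r$track_id[-1]
  i0 <- which(same); i1 <- i0 + 1L
  contrib_val <- numeric(0); contrib_int <- integer(0)
  n_skipped <- 0L
  if (length(i0)) {
    P <- as.matrix(r[i0, c("x_um", "y_um", "z_um")])
    Q <- as.matrix(r[i1, c("x_um", "y_um", "z_um")])
    alpha <- signed_angles_about_axis(P, Q, a, eps_proj = eps_proj)
    k0 <- match(r$t_index[i0], grid$t_index)
    k1 <- match(r$t_index[i1], grid$t_index)
    n_skipped <- sum(is.na(alpha))
    ok <- !is.na(alpha)
    simple <- ok & (k1 == k0 + 1L)
    contrib_val <- alpha[simple]
    contrib_int <- k0[simple]
    gapped <- which(ok & (k1 > k0 + 1L))
    if (length(gapped) && gap_policy == "scale") {
      for (g in gapped) {
        spans <- k0[g]:(k1[g] - 1L)
        actual_dt <- grid$t_hours[k1[g]] - grid$t_hours[k0[g]]
        contrib_val <- c(contrib_val, alpha[g] * grid_dt[spans] / actual_dt)
        contrib_int <- c(contrib_int, spans)
      }
    }
  }
  mean_alpha <- rep(NA_real_, K - 1L)
  n_cells <- integer(K - 1L)
  if (length(contrib_int)) {
    sums <- tapply(contrib_val, factor(contrib_int, levels = seq_len(K - 1L)), sum)
    cnts <- tapply(contrib_val, factor(contrib_int, levels = seq_len(K - 1L)), length)
    n_cells <- ifelse(is.na(cnts), 0L, as.integer(cnts))
    mean_alpha[n_cells > 0L] <- as.numeric(sums)[n_cells > 0L] / n_cells[n_cells > 0L]
  }
  excluded <- n_cells == 0L
  if (any(excluded)) {
    warning(sprintf("chamber_rotation(%s): %d interval(s) with no contributing cells excluded from the cumulative angle",
                    chamber, sum(excluded)), call. = FALSE)
  }
  cum <- cumsum(ifelse(excluded, 0, mean_alpha))
  rs <- data.frame(
    chamber = chamber,
    t_start = grid$t_hours[-K],
    t_mid = (grid$t_hours[-K] + grid$t_hours[-1L]) / 2,
    t_end = grid$t_hours[-1L],
    dt_hours = grid_dt,
    mean_alpha_deg = mean_alpha,
    omega_deg_per_h = mean_alpha / grid_dt,
    cum_angle_deg = cum,
    n_cells = n_cells,
    excluded = excluded
  )
  attr(rs, "chamber") <- chamber
  attr(rs, "axis") <- a
  attr(rs, "t0") <- grid$t_hours[1L]
  attr(rs, "n_skipped_pairs") <- n_skipped
  class(rs) <- c("rotation_series", "data.frame")
  rs
}

.assign_windows <- function(t_mid, t0, window_hours) {
  as.integer(floor((t_mid - t0) / window_hours + 1e-12))
}

#' Tumbling-window mean angular velocity
#'
#' Windows of `window_hours` are anchored at the start of the movie; each
#' interval is assigned to the window containing its midpoint and the
#' window value is the mean of omega over its intervals. A trailing window
#' not fully covered by the series is reported with `partial = TRUE`.
#'
#' @param rs a [chamber_rotation()] result.
#' @param window_hours window width in hours (default 1.5).
#' @return data.frame: `window`, `t_start`, `t_end`,
#'   `mean_omega_deg_per_h`, `n_intervals`, `partial`.
#' @export
windowed_angular_velocity <- function(rs, window_hours = 1.5) {
  stopifnot(inherits(rs, "rotation_series"), window_hours > 0)
  t0 <- attr(rs, "t0")
  span_end <- max(rs$t_end)
  if (span_end - t0 < window_hours) {
    warning("series shorter than one window; single partial window reported",
            call. = FALSE)
  }
  use <- !rs$excluded
  win <- .assign_windows(rs$t_mid, t0, window_hours)
  levs <- seq(0L, max(win))
  f <- factor(win[use], levels = levs)
  mean_omega <- as.numeric(tapply(rs$omega_deg_per_h[use], f, mean))
  n_int <- as.integer(tapply(rep(1L, sum(use)), f, sum))
  n_int[is.na(n_int)] <- 0L
  data.frame(
    window = levs,
    t_start = t0 + levs * window_hours,
    t_end = t0 + (levs + 1L) * window_hours,
    mean_omega_deg_per_h = mean_omega,
    n_intervals = n_int,
    partial = (t0 + (levs + 1L) * window_hours) > span_end + 1e-9
  )
}

#' Twisting angle and twisting velocity
#'
#' The twisting angle is the difference between the cumulative rotation of
#' the atrium and that of the ventricle, `T(t) = Theta_atrium(t) -
#' Theta_ventricle(t)`, zero at the start of the movie; its growth
#' quantifies torsion of the heart tube. The twisting velocity is reported
#' as tumbling-window means of `omega_atrium - omega_ventricle`.
#'
#' The two series are aligned on common interval midpoints (their
#' intersection); both normally come from one [run_pipeline()] call and
#' share the grid exactly.
#'
#' @param rs_ventricle,rs_atrium [chamber_rotation()] results.
#' @param window_hours window width for the twisting velocity, hours.
#' @return object of class `twist_series`: list with `series` (data.frame
#'   `t_hours`, `twist_angle_deg` — includes a leading row at t0 with
#'   angle 0) and `windows` (data.frame `window`, `t_start`, `t_end`,
#'   `twist_velocity_deg_per_h`, `n_intervals`, `partial`).
#' @export
twisting <- function(rs_ventricle, rs_atrium, window_hours = 1.5) {
  stopifnot(inherits(rs_ventricle, "rotation_series"),
            inherits(rs_atrium, "rotation_series"))
  key_v <- sprintf("%.9f", rs_ventricle$t_mid)
  key_a <- sprintf("%.9f", rs_atrium$t_mid)
  common <- intersect(key_v, key_a)
  if (!length(common)) {
    stop("alignment error: the ventricle and atrium series share no interval midpoints",
         call. = FALSE)
  }
  v <- rs_ventricle[match(common, key_v), , drop = FALSE]
  a <- rs_atrium[match(common, key_a), , drop = FALSE]
  excl <- v$excluded | a$excluded
  d_alpha <- ifelse(excl, 0, a$mean_alpha_deg - v$mean_alpha_deg)
  t0 <- min(v$t_start)
  series <- data.frame(
    t_hours = c(t0, v$t_end),
    twist_angle_deg = c(0, cumsum(d_alpha))
  )
  d_omega <- a$omega_deg_per_h - v$omega_deg_per_h
  span_end <- max(v$t_end)
  win <- .assign_windows(v$t_mid, t0, window_hours)
  levs <- seq(0L, max(win))
  f <- factor(win[!excl], levels = levs)
  tv <- as.numeric(tapply(d_omega[!excl], f, mean))
  n_int <- as.integer(tapply(rep(1L, sum(!excl)), f, sum))
  n_int[is.na(n_int)] <- 0L
  windows <- data.frame(
    window = levs,
    t_start = t0 + levs * window_hours,
    t_end = t0 + (levs + 1L) * window_hours,
    twist_velocity_deg_per_h = tv,
    n_intervals = n_int,
    partial = (t0 + (levs + 1L) * window_hours) > span_end + 1e-9
  )
  structure(list(series = series, windows = windows),
            class = "twist_series")
}

#' @export
print.twist_series <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("twist_series: %d timepoints, final twisting angle %.2f deg\n",
              n, x$series$twist_angle_deg[n]))
  invisible(x)
}
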