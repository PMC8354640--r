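#' End-to-end rotation/twist analysis of a track set
#'
#' Runs the full chain: minimum-track-length filter, per-frame axes,
#' hinge rooting and unfolding, per-chamber rotation series (the AV canal
#' twice, once about each chamber's reference axis, since the hinge has no
#' axis of its own), tumbling-window angular velocities, and the twisting
#' series. Optionally writes tidy CSV outputs plus a run log; nothing is
#' written unless every stage succeeded.
#'
#' The mathematical sign convention (counterclockwise-positive viewed from
#' the tip of each chamber's reference axis) is the default. With
#' `view_from_outflow = TRUE` the reported chamber series are re-signed to
#' a single biological viewpoint at the outflow of the heart: the
#' ventricle axis points toward the outflow so its sign is kept, while the
#' atrium axis points away, so atrium (and AV-canal-about-atrium) angles
#' are negated. The twisting series is always computed in the mathematical
#' convention.
#'
#' @param ts a [track_set()].
#' @param min_points minimum acquisition points per track (default 15).
#' @param window_hours tumbling window width, hours (default 1.5).
#' @param eps_proj minimum perpendicular distance from the axis, microns.
#' @param gap_policy `"scale"` or `"drop"`, see [chamber_rotation()].
#' @param view_from_outflow logical; apply the outflow-viewpoint sign map
#'   to the reported chamber series.
#' @param out_dir optional output directory for tidy CSVs + run log.
#' @return object of class `twist_analysis`: list with `rotation` (named
#'   list of [chamber_rotation()] series: `ventricle`, `atrium`,
#'   `avcanal_about_ventricle`, `avcanal_about_atrium`), `windows` (one
#'   tidy data.frame across chambers), `twist` (a [twisting()] result),
#'   and `log` (filter counts, skipped pairs, excluded intervals).
#' @export
run_pipeline <- function(ts, min_points = 15L, window_hours = 1.5,
                         eps_proj = 0.5, gap_policy = c("scale", "drop"),
                         view_from_outflow = FALSE, out_dir = NULL) {
  stopifnot(inherits(ts, "track_set"))
  gap_policy <- match.arg(gap_policy)
  n_tracks_in <- length(unique(ts$records$track_id))
  fts <- withCallingHandlers(
    filter_min_length(ts, min_points = min_points),
    message = function(m) invokeRestart("muffleMessage")
  )
  n_tracks_kept <- length(unique(fts$records$track_id))
  uts <- root_and_unfold(fts)
  series_spec <- list(
    ventricle = list(chamber = "ventricle", axis = NULL),
    atrium = list(chamber = "atrium", axis = NULL),
    avcanal_about_ventricle = list(chamber = "avcanal", axis = "ventricle"),
    avcanal_about_atrium = list(chamber = "avcanal", axis = "atrium")
  )
  rotation <- lapply(series_spec, function(s) {
    chamber_rotation(uts, s$chamber, axis = s$axis, eps_proj = eps_proj,
                     gap_policy = gap_policy)
  })
  twist <- twisting(rotation$ventricle, rotation$atrium,
                    window_hours = window_hours)
  if (isTRUE(view_from_outflow)) {
    for (nm in c("atrium", "avcanal_about_atrium")) {
      for (cc in c("mean_alpha_deg", "omega_deg_per_h", "cum_angle_deg")) {
        rotation[[nm]][[cc]] <- -rotation[[nm]][[cc]]
      }
    }
  }
  windows <- do.call(rbind, lapply(names(rotation), function(nm) {
    w <- windowed_angular_velocity(rotation[[nm]], window_hours = window_hours)
    cbind(series = nm, w)
  }))
  log <- list(
    n_tracks_in = n_tracks_in,
    n_tracks_kept = n_tracks_kept,
    min_points = as.integer(min_points),
    skipped_pairs = vapply(rotation, function(r) attr(r, "n_skipped_pairs"),
                           integer(1)),
    excluded_intervals = vapply(rotation, function(r) sum(r$excluded),
                                integer(1)),
    view_from_outflow = isTRUE(view_from_outflow),
    gap_policy = gap_policy,
    window_hours = window_hours,
    eps_proj = eps_proj
  )
  res <- structure(list(rotation = rotation, windows = windows,
                        twist = twist, log = log),
                   class = "twist_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' Write the tidy CSV outputs of a pipeline run
#'
#' One CSV per rotation series, a combined window table, the twisting
#' series and its windows, and a plain-text run log (filter counts,
#' skipped cell/frame pairs, excluded intervals, parameters).
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(res, out_dir) {
  stopifnot(inherits(res, "twist_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$rotation)) {
    utils::write.csv(res$rotation[[nm]],
                     file.path(out_dir, paste0("rotation_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(res$windows, file.path(out_dir, "windows.csv"),
                   row.names = FALSE)
  utils::write.csv(res$twist$series, file.path(out_dir, "twist_series.csv"),
                   row.names = FALSE)
  utils::write.csv(res$twist$windows, file.path(out_dir, "twist_windows.csv"),
                   row.names = FALSE)
  lg <- res$log
  lines <- c(
    sprintf("tracks in: %d", lg$n_tracks_in),
    sprintf("tracks kept (>= %d points): %d", lg$min_points, lg$n_tracks_kept),
    sprintf("window_hours: %g; eps_proj: %g um; gap_policy: %s; view_from_outflow: %s",
            lg$window_hours, lg$eps_proj, lg$gap_policy, lg$view_from_outflow),
    sprintf("skipped cell/frame pairs (on-axis): %s",
            paste(sprintf("%s=%d", names(lg$skipped_pairs), lg$skipped_pairs),
                  collapse = ", ")),
    sprintf("excluded empty intervals: %s",
            paste(sprintf("%s=%d", names(lg$excluded_intervals),
                          lg$excluded_intervals), collapse = ", "))
  )
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.twist_analysis <- function(x, ...) {
  thv <- x$rotation$ventricle
  tha <- x$rotation$atrium
  cat("twist_analysis\n")
  cat(sprintf("  tracks: %d in, %d kept (min %d points)\n",
              x$log$n_tracks_in, x$log$n_tracks_kept, x$log$min_points))
  cat(sprintf("  Theta_ventricle(end) = %+.2f deg; Theta_atrium(end) = %+.2f deg\n",
              thv$cum_angle_deg[nrow(thv)], tha$cum_angle_deg[nrow(tha)]))
  n <- nrow(x$twist$series)
  cat(sprintf("  twisting angle(end)  = %+.2f deg over %.2f h\n",
              x$twist$series$twist_angle_deg[n],
              x$twist$series$t_hours[n] - x$twist$series$t_hours[1]))
  invisible(x)
}
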