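#' Track tables: containers, reading, filtering, writing
#'
#' A `track_set` holds one row per cell per timepoint of a 3D+t
#' cardiomyocyte tracking experiment, with each track labelled by the
#' anatomical region it starts in (ventricle, AV canal or atrium). The
#' canonical on-disk form is a plain CSV with header
#' `track_id,t_index,t_hours,x_um,y_um,z_um,region`; a column-mapping
#' dialect adapts foreign exports (e.g. Imaris spot/track tables) to it.
#'
#' @name track_io
NULL

REGIONS <- c("ventricle", "avcanal", "atrium")

CANONICAL_COLUMNS <- c("track_id", "t_index", "t_hours",
                       "x_um", "y_um", "z_um", "region")

# Spellings accepted (after lower-casing and stripping spaces/_/-)
.region_aliases <- c(
  ventricle = "ventricle", v = "ventricle",
  avcanal = "avcanal", avc = "avcanal", av = "avcanal",
  atrium = "atrium", a = "atrium"
)

.normalize_region <- function(x) {
  key <- gsub("[ _-]", "", tolower(trimws(x)))
  out <- unname(.region_aliases[key])
  bad <- unique(x[is.na(out) | is.na(x)])
  if (length(bad)) {
    stop("unknown region label(s): ", paste(sQuote(bad), collapse = ", "),
         "; expected one of ", paste(REGIONS, collapse = ", "), call. = FALSE)
  }
  out
}

#' Construct and validate a track set
#'
#' @param records data.frame with columns `track_id`, `t_index`, `t_hours`
#'   (optional; synthesized as `t_index * frame_period_hours` when absent),
#'   `x_um`, `y_um`, `z_um`, `region`.
#' @param frame_period_hours nominal frame period in hours (default 13/60,
#'   i.e. the ~13 min full-stack acquisition period of the timelapses this
#'   container is modelled on).
#' @param voxel_size_um acquisition voxel size metadata, microns (x, y, z).
#' @param provenance free-text source tag.
#' @return an object of class `track_set`: list with elements `records`
#'   (sorted by track then frame), `frame_period_hours`, `voxel_size_um`,
#'   `provenance`.
#' @export
track_set <- function(records, frame_period_hours = 13 / 60,
                      voxel_size_um = c(0.889, 0.889, 2.000),
                      provenance = "") {
  stopifnot(is.data.frame(records))
  if (!is.numeric(frame_period_hours) || length(frame_period_hours) != 1L ||
      !is.finite(frame_period_hours) || frame_period_hours <= 0) {
    stop("frame_period_hours must be a positive number", call. = FALSE)
  }
  need <- setdiff(c("track_id", "t_index", "x_um", "y_um", "z_um", "region"),
                  names(records))
  if (length(need)) {
    stop("schema error: missing column(s) ", paste(sQuote(need), collapse = ", "),
         call. = FALSE)
  }
  records$track_id <- as.character(records$track_id)
  records$t_index <- as.integer(records$t_index)
  if (anyNA(records$t_index) || any(records$t_index < 0L)) {
    stop("t_index must be non-negative integers", call. = FALSE)
  }
  if (!("t_hours" %in% names(records)) || all(is.na(records$t_hours))) {
    records$t_hours <- records$t_index * frame_period_hours
  }
  records$t_hours <- as.numeric(records$t_hours)
  for (cc in c("t_hours", "x_um", "y_um", "z_um")) {
    if (!all(is.finite(records[[cc]]))) {
      stop("non-finite values in column ", sQuote(cc), call. = FALSE)
    }
  }
  records$region <- .normalize_region(records$region)
  key <- paste(records$track_id, records$t_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop("integrity error: duplicate (track_id, t_index) pair(s), e.g. track ",
         sQuote(d$track_id[1]), " frame ", d$t_index[1], call. = FALSE)
  }
  ord <- order(records$track_id, records$t_index)
  records <- records[ord, CANONICAL_COLUMNS, drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 frame_period_hours = frame_period_hours,
                 voxel_size_um = as.numeric(voxel_size_um),
                 provenance = provenance),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  r <- x$records
  cat(sprintf("track_set: %d tracks, %d records, %d frames\n",
              length(unique(r$track_id)), nrow(r), length(unique(r$t_index))))
  tab <- table(r$region[!duplicated(r$track_id)])
  cat("  tracks per region:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  cat(sprintf("  frame period: %.4f h; provenance: %s\n",
              x$frame_period_hours,
              if (nzchar(x$provenance)) x$provenance else "<none>"))
  invisible(x)
}

#' Read a track CSV
#'
#' Reads either the canonical schema directly, or a foreign dialect via a
#' column mapping. The dialect is a named list: entries named after
#' canonical columns give the foreign column name (e.g.
#' `list(track_id = "TrackID", x_um = "Position X")`); the optional entry
#' `region_map` is a named character vector translating foreign region
#' strings (matched case-insensitively) to canonical labels.
#'
#' @param path CSV file path.
#' @param dialect optional column-mapping list as described above.
#' @param frame_period_hours,voxel_size_um,provenance metadata passed to
#'   [track_set()].
#' @return a [track_set()].
#' @export
read_tracks <- function(path, dialect = NULL, frame_period_hours = 13 / 60,
                        voxel_size_um = c(0.889, 0.889, 2.000),
                        provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!is.null(dialect)) {
    maps <- dialect[intersect(names(dialect), CANONICAL_COLUMNS)]
    for (canon in names(maps)) {
      foreign <- maps[[canon]]
      if (!foreign %in% names(raw)) {
        stop("schema error: mapped column ", sQuote(foreign),
             " (for ", canon, ") not present in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == foreign] <- canon
    }
    if (!is.null(dialect$region_map) && "region" %in% names(raw)) {
      rm <- dialect$region_map
      names(rm) <- tolower(trimws(names(rm)))
      hit <- rm[tolower(trimws(raw$region))]
      raw$region[!is.na(hit)] <- unname(hit[!is.na(hit)])
    }
  }
  need <- setdiff(c("track_id", "t_index", "x_um", "y_um", "z_um", "region"),
                  names(raw))
  if (length(need)) {
    stop("schema error: missing column(s) ", paste(sQuote(need), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  for (cc in intersect(c("t_index", "t_hours", "x_um", "y_um", "z_um"), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !(is.na(raw[[cc]]) | raw[[cc]] == ""))
    if (length(bad)) {
      stop("parse error: non-numeric value ", sQuote(raw[[cc]][bad[1]]),
           " in column ", sQuote(cc), " at data row ", bad[1], call. = FALSE)
    }
    raw[[cc]] <- v
  }
  track_set(raw, frame_period_hours = frame_period_hours,
            voxel_size_um = voxel_size_um, provenance = provenance)
}

#' Write a track set to the canonical CSV
#'
#' Coordinates are serialized at full double precision (17 significant
#' digits) so that `read_tracks(write_tracks(ts))` reproduces every field
#' bit-comparably.
#'
#' @param ts a [track_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  r <- ts$records
  out <- data.frame(
    track_id = r$track_id,
    t_index = r$t_index,
    t_hours = sprintf("%.17g", r$t_hours),
    x_um = sprintf("%.17g", r$x_um),
    y_um = sprintf("%.17g", r$y_um),
    z_um = sprintf("%.17g", r$z_um),
    region = r$region,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only tracks with at least `min_points` acquisition points
#'
#' The track-selection rule of the study design: a track is retained iff it
#' contains at least `min_points` records (boundary inclusive; the default
#' 15 matches the minimum of 15 acquisition points used for ~13-min frames
#' over a ~10 h movie). Surviving records are untouched and order is
#' preserved; the kept/dropped counts are reported via `message()`.
#'
#' @param ts a [track_set()].
#' @param min_points positive integer, minimum records per track.
#' @return a filtered [track_set()] (possibly with zero records).
#' @export
filter_min_length <- function(ts, min_points = 15L) {
  stopifnot(inherits(ts, "track_set"))
  min_points <- as.integer(min_points)
  if (is.na(min_points) || min_points < 1L) {
    stop("min_points must be a positive integer", call. = FALSE)
  }
  len <- table(ts$records$track_id)
  keep_ids <- names(len)[as.integer(len) >= min_points]
  out <- ts
  out$records <- ts$records[ts$records$track_id %in% keep_ids, , drop = FALSE]
  rownames(out$records) <- NULL
  message(sprintf("filter_min_length: kept %d of %d tracks (min_points = %d)",
                  length(keep_ids), length(len), min_points))
  out
}
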