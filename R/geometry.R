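#' Rigid-body geometry for the hinge-and-axis construction
#'
#' Pure helpers used by the unfolding pipeline: centroids, chamber axes,
#' the minimal rotation mapping one unit vector onto another (Rodrigues),
#' and the signed rotation angle of a point about an axis through the
#' origin. All angles are in degrees; the coordinate system is
#' right-handed and a positive angle is counterclockwise when viewed from
#' the tip of the axis vector looking toward the origin.
#'
#' @name geometry
NULL

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

#' Arithmetic centroid of a point set
#'
#' @param points numeric matrix with one row per point and 3 columns
#'   (x, y, z in microns), or a single 3-vector.
#' @return numeric 3-vector, the component-wise mean.
#' @export
#' @examples
#' centroid(rbind(c(0, 0, 0), c(2, 0, 0)))  # (1, 0, 0)
centroid <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(points) < 1L) stop("centroid of an empty point set is undefined", call. = FALSE)
  colMeans(points)
}

#' Unit axis from the AV-canal centroid to a chamber centroid
#'
#' The chamber axis runs from the AV-canal centroid to the centroid of the
#' chamber's cells; it is the axis about which that chamber's rotation is
#' measured.
#'
#' @param av_centroid numeric 3-vector, AV-canal centroid (microns).
#' @param chamber_points matrix of chamber cell positions (rows = cells).
#' @param frame optional frame index, used only in error messages.
#' @return unit 3-vector.
#' @export
chamber_axis <- function(av_centroid, chamber_points, frame = NA) {
  d <- centroid(chamber_points) - av_centroid
  if (sqrt(sum(d^2)) <= 1e-6) {
    stop(sprintf("degenerate chamber axis at frame %s: chamber centroid coincides with the AV centroid",
                 as.character(frame)), call. = FALSE)
  }
  d / sqrt(sum(d^2))
}

#' Rotation matrix about an axis (Rodrigues' formula)
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle in degrees, right-handed about `axis`.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  a <- .unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Smallest rotation mapping one unit vector onto another
#'
#' Returns the rotation of minimal angle carrying `u` onto `v`, with axis
#' along `u x v`. For antiparallel inputs (`u x v` vanishing, `u . v < 0`)
#' the 180-degree rotation axis is the component of the global +z axis
#' perpendicular to `u`; if `u` is itself parallel to z, the global +x
#' axis is used. This tie-break is arbitrary but fixed, so results are
#' reproducible.
#'
#' @param u,v unit 3-vectors.
#' @return an object of class `rigid_rotation`: list with `axis` (unit
#'   3-vector), `angle_deg` in \[0, 180\] and `matrix` (3x3, det +1).
#' @export
minimal_rotation <- function(u, v) {
  u <- .unit(u); v <- .unit(v)
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2))
  d <- sum(u * v)
  if (s < 1e-9) {
    if (d > 0) {                      # identical directions
      axis <- c(0, 0, 1); angle <- 0
    } else {                          # antiparallel: documented tie-break
      z <- c(0, 0, 1)
      perp <- z - sum(z * u) * u
      axis <- if (sqrt(sum(perp^2)) < 1e-9) c(1, 0, 0) else .unit(perp)
      angle <- 180
    }
  } else {
    axis <- w / s
    angle <- atan2(s, d) * 180 / pi
  }
  structure(list(axis = axis, angle_deg = angle,
                 matrix = rotation_matrix(axis, angle)),
            class = "rigid_rotation")
}

#' @export
print.rigid_rotation <- function(x, ...) {
  cat(sprintf("rigid rotation: %.4f deg about (%.4f, %.4f, %.4f)\n",
              x$angle_deg, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Signed rotation angle of a cell about an axis through the origin
#'
#' Both positions are projected onto the plane through the origin
#' perpendicular to `axis`; the returned angle is the signed angle (in
#' degrees, range (-180, 180\]) from the projection of `p_prev` to that of
#' `p_next`, positive counterclockwise when viewed from the tip of `axis`.
#' Positions must already be expressed in the hinge-rooted frame, i.e. the
#' axis passes through the origin.
#'
#' A cell lying essentially on the axis has no defined rotation angle: if
#' either projected position has norm `<= eps_proj` the result is `NA` and
#' the caller must skip that cell/frame pair.
#'
#' @param p_prev,p_next numeric 3-vectors (microns, hinge-rooted frame).
#' @param axis unit 3-vector.
#' @param eps_proj minimum perpendicular distance from the axis (microns)
#'   for the angle to be defined. Default 0.5 um: below roughly half a
#'   voxel the perpendicular offset is noise-dominated.
#' @return angle in degrees, or `NA_real_` if undefined.
#' @export
signed_angle_about_axis <- function(p_prev, p_next, axis, eps_proj = 0.5) {
  as.numeric(signed_angles_about_axis(matrix(p_prev, ncol = 3),
                                      matrix(p_next, ncol = 3),
                                      axis, eps_proj))
}

# Vectorized form: P, Q are n x 3 matrices of previous/next positions.
# Returns a length-n vector of angles in degrees with NA where either
# projection is within eps_proj of the axis.
signed_angles_about_axis <- function(P, Q, axis, eps_proj = 0.5) {
  a <- .unit(axis)
  proj <- function(M) M - tcrossprod(drop(M %*% a), a)
  Pp <- proj(P); Qp <- proj(Q)
  np <- sqrt(rowSums(Pp^2)); nq <- sqrt(rowSums(Qp^2))
  ok <- np > eps_proj & nq > eps_proj
  # cross(Pp, Qp) . a  and  Pp . Qp, on unit projections
  cx <- Pp[, 2] * Qp[, 3] - Pp[, 3] * Qp[, 2]
  cy <- Pp[, 3] * Qp[, 1] - Pp[, 1] * Qp[, 3]
  cz <- Pp[, 1] * Qp[, 2] - Pp[, 2] * Qp[, 1]
  sin_t <- (cx * a[1] + cy * a[2] + cz * a[3]) / (np * nq)
  cos_t <- rowSums(Pp * Qp) / (np * nq)
  ang <- atan2(sin_t, cos_t) * 180 / pi
  ang[!ok] <- NA_real_
  ang
}
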