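#' Shape measurements: roundness, boundary straightness, AV-canal angle
#'
#' Secondary morphometrics on cell outlines and tissue boundaries:
#' the Fiji-style roundness descriptor of a 2D cell outline, the
#' straightness index of a 3D boundary polyline, and the AV-canal
#' (looping) angle between the two chamber axes in a projection plane.
#'
#' @name morphometrics
NULL

.as_poly <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("polygon must have 2 columns (x, y)", call. = FALSE)
  # drop an explicitly repeated closing vertex
  n <- nrow(p)
  if (n >= 2L && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3L) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  if (!all(is.finite(p))) stop("polygon vertices must be finite", call. = FALSE)
  p
}

# Signed area, centroid and central second-moment (covariance) matrix of
# the region enclosed by a simple polygon, by exact shoelace-type
# integrals (Green's theorem); no sampling involved.
polygon_moments <- function(p) {
  p <- .as_poly(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) stop("degenerate polygon: zero area", call. = FALSE)
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12        # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12        # integral of x^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # central moments, normalized to a covariance of the enclosed region
  cov <- matrix(c(iyy / A - cx^2, ixy / A - cx * cy,
                  ixy / A - cx * cy, ixx / A - cy^2), 2, 2)
  if (A < 0) { A <- -A }   # orientation-independent
  list(area = A, centroid = c(cx, cy), cov = cov)
}

.check_simple <- function(p) {
  n <- nrow(p)
  if (n > 2000L) return(invisible(TRUE))   # skip O(n^2) check on huge outlines
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):n) {
      if (j == i || j == i2[i] || i == i2[j]) next
      # segment i -> i2[i] vs segment j -> i2[j]
      d1 <- c(x[i2[i]] - x[i], y[i2[i]] - y[i])
      d2 <- c(x[i2[j]] - x[j], y[i2[j]] - y[j])
      dd <- c(x[j] - x[i], y[j] - y[i])
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < 1e-15) next
      t1 <- (dd[1] * d2[2] - dd[2] * d2[1]) / den
      t2 <- (dd[1] * d1[2] - dd[2] * d1[1]) / den
      if (t1 > 1e-12 && t1 < 1 - 1e-12 && t2 > 1e-12 && t2 < 1 - 1e-12) {
        stop("polygon is self-intersecting", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Roundness of a 2D cell outline
#'
#' The default is the Fiji "Roundness" descriptor,
#' `4 * area / (pi * major_axis^2)`, where `major_axis` is the major-axis
#' length of the best-fit ellipse of the enclosed region (the ellipse
#' with the same area and second moments); a circle scores 1 and
#' elongated shapes score lower. `method = "circularity"` instead returns
#' `4 * pi * area / perimeter^2`.
#'
#' @param polygon matrix (or data.frame) of ordered vertices, 2 columns,
#'   microns; open or explicitly closed.
#' @param method `"roundness"` (default) or `"circularity"`.
#' @return a number in (0, 1\].
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' roundness(cbind(cos(th), sin(th)))          # ~1
#' roundness(cbind(2 * cos(th), sin(th)))      # ~0.5 for a 2:1 ellipse
roundness <- function(polygon, method = c("roundness", "circularity")) {
  method <- match.arg(method)
  p <- .as_poly(polygon)
  .check_simple(p)
  m <- polygon_moments(p)
  if (method == "circularity") {
    per <- sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2)))
    return(4 * pi * m$area / per^2)
  }
  # best-fit ellipse with matching second moments: semi-axes 2*sqrt(lambda)
  lam_max <- max(eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values)
  major <- 4 * sqrt(lam_max)
  4 * m$area / (pi * major^2)
}

#' Straightness index of a boundary polyline
#'
#' Ratio of the straight-line (chord) distance between the first and last
#' vertex to the arc length of the polyline as measured along the
#' surface. A straight boundary scores 1; a meandering (anisotropically
#' grown) boundary scores lower; a closed loop scores 0.
#'
#' @param border matrix (or data.frame) of ordered vertices; 2 or 3
#'   columns, microns.
#' @return a number in \[0, 1\].
#' @export
straightness_index <- function(border) {
  b <- as.matrix(border)
  if (!ncol(b) %in% c(2L, 3L)) stop("border must have 2 or 3 columns", call. = FALSE)
  if (nrow(b) < 2L) stop("border needs at least 2 vertices", call. = FALSE)
  if (!all(is.finite(b))) stop("border vertices must be finite", call. = FALSE)
  seg <- sqrt(rowSums((b[-1, , drop = FALSE] - b[-nrow(b), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive border vertices must be distinct", call. = FALSE)
  arc <- sum(seg)
  if (arc <= 0) stop("zero path length", call. = FALSE)
  chord <- sqrt(sum((b[nrow(b), ] - b[1, ])^2))
  chord / arc
}

#' AV-canal (looping) angle between the chamber axes
#'
#' The angle subtended by the ventricle and atrium axes after projecting
#' both into the viewing plane (default: the ventral view, plane normal
#' +z). An unlooped straight tube has antiparallel limbs (180 degrees);
#' looping closes the angle.
#'
#' @param ventricle_axis,atrium_axis 3-vectors (normalized internally).
#' @param view_normal unit 3-vector normal to the viewing plane (default
#'   `c(0, 0, 1)`, ventral view).
#' @return angle in degrees, in \[0, 180\].
#' @export
av_canal_angle <- function(ventricle_axis, atrium_axis,
                           view_normal = c(0, 0, 1)) {
  nrm <- .unit(view_normal)
  proj <- function(v, which) {
    q <- v - sum(v * nrm) * nrm
    if (sqrt(sum(q^2)) <= 1e-6) {
      stop("degenerate projection: ", which, " axis is parallel to the view normal",
           call. = FALSE)
    }
    q / sqrt(sum(q^2))
  }
  u <- proj(.unit(ventricle_axis), "ventricle")
  v <- proj(.unit(atrium_axis), "atrium")
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}
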