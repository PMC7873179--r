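#' Construct a midline curve from ordered 2-D points
#'
#' @param points matrix or data frame with two columns (`x_mm`, `y_mm`),
#'   ordered proximal to distal; arc length starts at 0 at the first point
#' @return a `midline_curve` with cumulative arc length per point
#' @export
midline_curve <- function(points) {
  pts <- as.matrix(points)
  check_that(ncol(pts) == 2 && nrow(pts) >= 2,
             "midline_curve: need >= 2 two-dimensional points")
  check_that(all(is.finite(pts)), "midline_curve: points must be finite")
  seg <- sqrt(rowSums(diff(pts)^2))
  check_that(all(seg > 0), "midline_curve: consecutive points must be distinct")
  structure(list(points = unname(pts), arc_length = c(0, cumsum(seg))),
            class = "midline_curve")
}

#' Total arc length of a midline curve (mm)
#' @param curve a [midline_curve()]
#' @return length in mm
#' @export
total_arc_length <- function(curve) {
  check_that(inherits(curve, "midline_curve"), "total_arc_length: not a midline_curve")
  curve$arc_length[length(curve$arc_length)]
}

## Densely resample a polyline at (at most) `step` mm by linear
## interpolation against cumulative arc length. Returns an n x 2 matrix
## that always includes both endpoints.
resample_polyline <- function(pts, step) {
  pts <- as.matrix(pts)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  s <- unique(c(seq(0, arc[length(arc)], by = step), arc[length(arc)]))
  cbind(stats::approx(arc, pts[, 1], xout = s)$y,
        stats::approx(arc, pts[, 2], xout = s)$y)
}

#' Resample a midline at regular arc-length spacing
#'
#' Samples at arc lengths `0, spacing, 2*spacing, ...`, and attaches unit
#' tangents (centred finite differences; one-sided at the endpoints) and
#' unit normals (tangent rotated +90 degrees), the directions along which
#' perpendicular diameters are measured.
#'
#' @param curve a [midline_curve()]
#' @param spacing_mm arc-length sampling step (mm), positive and no larger
#'   than the total arc length
#' @return list with `positions_mm`, `points` (n x 2 mm), `tangents`,
#'   `normals` (n x 2 unit vectors)
#' @export
resample_midline <- function(curve, spacing_mm) {
  check_that(inherits(curve, "midline_curve"), "resample_midline: not a midline_curve")
  len <- total_arc_length(curve)
  check_that(is_scalar_num(spacing_mm) && spacing_mm > 0 && spacing_mm <= len,
             "resample_midline: spacing_mm must be in (0, total arc length]")
  s <- seq(0, len, by = spacing_mm)
  xy <- cbind(stats::approx(curve$arc_length, curve$points[, 1], xout = s)$y,
              stats::approx(curve$arc_length, curve$points[, 2], xout = s)$y)
  n <- length(s)
  tang <- matrix(NA_real_, n, 2)
  if (n >= 3) {
    tang[2:(n - 1), ] <- xy[3:n, ] - xy[1:(n - 2), ]
  }
  tang[1, ] <- xy[2, ] - xy[1, ]
  tang[n, ] <- xy[n, ] - xy[n - 1, ]
  tang <- tang / sqrt(rowSums(tang^2))
  normals <- cbind(-tang[, 2], tang[, 1])
  list(positions_mm = s, points = xy, tangents = tang, normals = normals)
}

#' Define a wall-search corridor around the midline
#'
#' The two polylines delineate the colon walls once for the whole
#' recording; because the walls move frame to frame, they are interpreted
#' as the centre of a search corridor of half-width `margin_mm` within
#' which the wall edge is located per frame.
#'
#' @param wall1,wall2 matrices of 2-D points in mm, one open polyline per
#'   wall side
#' @param margin_mm search margin beyond the delineated wall (mm)
#' @return a `wall_corridor`
#' @export
wall_corridor <- function(wall1, wall2, margin_mm = 10) {
  w1 <- as.matrix(wall1); w2 <- as.matrix(wall2)
  check_that(ncol(w1) == 2 && ncol(w2) == 2 && nrow(w1) >= 2 && nrow(w2) >= 2,
             "wall_corridor: walls must be polylines of >= 2 two-dimensional points")
  check_that(is_scalar_num(margin_mm) && margin_mm > 0,
             "wall_corridor: margin_mm must be > 0")
  structure(list(wall1 = unname(w1), wall2 = unname(w2),
                 margin_mm = margin_mm), class = "wall_corridor")
}
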