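#' Construct a diameter profile series
#'
#' @param diameter_mm positions x times matrix of lumen diameters (mm);
#'   invalid cells are `NA`
#' @param positions_mm regularly spaced arc-length positions (mm)
#' @param times_s regularly spaced frame times (s)
#' @return a `diameter_profile_series`
#' @export
diameter_profile_series <- function(diameter_mm, positions_mm, times_s) {
  d <- as.matrix(diameter_mm)
  check_that(nrow(d) == length(positions_mm) && ncol(d) == length(times_s),
             "diameter_profile_series: matrix shape must be positions x times")
  if (length(positions_mm) > 2)
    check_that(max(abs(diff(diff(positions_mm)))) < 1e-6,
               "diameter_profile_series: positions must be regularly spaced")
  if (length(times_s) > 2)
    check_that(max(abs(diff(diff(times_s)))) < 1e-6,
               "diameter_profile_series: times must be regularly spaced")
  check_that(all(d >= 0, na.rm = TRUE),
             "diameter_profile_series: diameters must be >= 0 where valid")
  structure(list(diameter_mm = unname(d), positions_mm = positions_mm,
                 times_s = times_s, valid = !is.na(unname(d))),
            class = "diameter_profile_series")
}

## Precompute bilinear interpolation stencils for sample points given in
## mm (origin at the first pixel centre). Out-of-image samples get NA.
bilinear_stencil <- function(x_mm, y_mm, pixel_spacing, rows, cols) {
  col <- x_mm / pixel_spacing + 1
  row <- y_mm / pixel_spacing + 1
  inside <- row >= 1 & row <= rows & col >= 1 & col <= cols
  r0 <- clamp(floor(row), 1, rows - 1); c0 <- clamp(floor(col), 1, cols - 1)
  wr <- row - r0; wc <- col - c0
  idx <- function(r, c) (c - 1) * rows + r
  list(i00 = idx(r0, c0), i10 = idx(r0 + 1, c0),
       i01 = idx(r0, c0 + 1), i11 = idx(r0 + 1, c0 + 1),
       w00 = (1 - wr) * (1 - wc), w10 = wr * (1 - wc),
       w01 = (1 - wr) * wc, w11 = wr * wc, inside = inside)
}

bilinear_eval <- function(stencil, frame) {
  v <- stencil$w00 * frame[stencil$i00] + stencil$w10 * frame[stencil$i10] +
    stencil$w01 * frame[stencil$i01] + stencil$w11 * frame[stencil$i11]
  v[!stencil$inside] <- NA_real_
  v
}

## Per-side search limit: distance from each midline sample to the
## nearest delineated wall point lying on that side (positive projection
## onto the side normal), plus the corridor margin.
side_search_limits <- function(mid, corridor, side_sign) {
  wall_pts <- rbind(resample_polyline(corridor$wall1, 1),
                    resample_polyline(corridor$wall2, 1))
  n <- nrow(mid$points)
  lim <- numeric(n)
  for (i in seq_len(n)) {
    d <- sweep(wall_pts, 2, mid$points[i, ])
    proj <- d %*% (side_sign * mid$normals[i, ])
    dist2 <- rowSums(d^2)
    on_side <- proj > 0
    lim[i] <- if (any(on_side)) sqrt(min(dist2[on_side])) else 0
  }
  lim + corridor$margin_mm
}

#' Measure perpendicular lumen diameters along the midline
#'
#' For every frame and every midline sample, image intensity is read by
#' bilinear interpolation along the perpendicular line at steps of half a
#' pixel. On each side, the lumen extent is the distance to the
#' half-maximum crossing between the local lumen intensity (at the
#' midline) and the local background (outermost corridor samples),
#' searched only inside the wall corridor plus its margin; the diameter is
#' the sum of the two side extents. Cells with no crossing on either side
#' (or whose perpendicular leaves the field of view before a crossing) are
#' masked invalid, never recorded as zero.
#'
#' @param frames an [image_series()]
#' @param curve a [midline_curve()] in mm image coordinates
#' @param corridor a [wall_corridor()]
#' @param spacing_mm arc-length sampling step (mm)
#' @return a [diameter_profile_series()]
#' @export
measure_diameters <- function(frames, curve, corridor, spacing_mm = 2) {
  check_that(inherits(frames, "image_series"), "measure_diameters: frames must be an image_series")
  check_that(inherits(corridor, "wall_corridor"), "measure_diameters: corridor must be a wall_corridor")
  mid <- resample_midline(curve, spacing_mm)
  dims <- dim(frames$data)
  rows <- dims[1]; cols <- dims[2]; n_t <- dims[3]
  p <- frames$pixel_spacing_mm
  step <- p / 2
  n_pos <- length(mid$positions_mm)

  lim_plus <- side_search_limits(mid, corridor, +1)
  lim_minus <- side_search_limits(mid, corridor, -1)
  k_max <- ceiling(max(lim_plus, lim_minus) / step)
  dist_steps <- seq_len(k_max) * step

  ## stencils: midline points and both side rakes (n_pos x k_max each)
  centre_st <- bilinear_stencil(mid$points[, 1], mid$points[, 2], p, rows, cols)
  side_st <- lapply(c(1, -1), function(sgn) {
    x <- outer(mid$points[, 1], dist_steps, function(px, d) px) +
      outer(sgn * mid$normals[, 1], dist_steps)
    y <- outer(mid$points[, 2], dist_steps, function(py, d) py) +
      outer(sgn * mid$normals[, 2], dist_steps)
    bilinear_stencil(as.vector(x), as.vector(y), p, rows, cols)
  })
  lim_mat <- list(matrix(lim_plus, n_pos, k_max),
                  matrix(lim_minus, n_pos, k_max))
  step_mat <- matrix(dist_steps, n_pos, k_max, byrow = TRUE)

  extent_one_side <- function(profile, i_mid, limits) {
    profile[step_mat > limits] <- NA
    ## background: mean of the outer three in-corridor samples
    outer_mask <- step_mat > limits - 3 * step & step_mat <= limits
    bgm <- profile
    bgm[!outer_mask] <- NA
    i_bg <- rowMeans(bgm, na.rm = TRUE)
    thr <- (i_mid + i_bg) / 2
    ok <- is.finite(i_mid) & is.finite(i_bg) & i_mid > i_bg
    below <- profile < thr
    k1 <- first_true_col(below)
    ext <- rep(NA_real_, n_pos)
    hit <- ok & !is.na(k1)
    if (any(hit)) {
      ii <- which(hit)
      kk <- k1[ii]
      i_after <- profile[cbind(ii, kk)]
      i_before <- ifelse(kk == 1, i_mid[ii], profile[cbind(ii, pmax(kk - 1, 1))])
      denom <- i_before - i_after
      frac <- ifelse(is.finite(denom) & denom > 0,
                     (i_before - thr[ii]) / denom, 0)
      frac <- clamp(frac, 0, 1)
      ext[ii] <- (kk - 1 + frac) * step
    }
    ext
  }

  d_out <- matrix(NA_real_, n_pos, n_t)
  for (t in seq_len(n_t)) {
    frame <- frames$data[, , t]
    i_mid <- bilinear_eval(centre_st, frame)
    e1 <- extent_one_side(matrix(bilinear_eval(side_st[[1]], frame), n_pos),
                          i_mid, lim_mat[[1]])
    e2 <- extent_one_side(matrix(bilinear_eval(side_st[[2]], frame), n_pos),
                          i_mid, lim_mat[[2]])
    d_out[, t] <- e1 + e2
  }
  times <- (seq_len(n_t) - 1) * frames$frame_interval_s
  diameter_profile_series(d_out, mid$positions_mm, times)
}

#' Frame-to-frame activity map
#'
#' First difference of the diameter series along time:
#' `delta_d(s, t) = d(s, t+1) - d(s, t)`. A difference involving any
#' invalid cell is invalid.
#'
#' @param diams a [diameter_profile_series()]
#' @return an `activity_map` whose time dimension is one frame shorter;
#'   `times_s` are the interval start times
#' @export
frame_to_frame_activity <- function(diams) {
  check_that(inherits(diams, "diameter_profile_series"),
             "frame_to_frame_activity: input must be a diameter_profile_series")
  n_t <- length(diams$times_s)
  check_that(n_t >= 2, "frame_to_frame_activity: need at least 2 frames")
  delta <- diams$diameter_mm[, 2:n_t, drop = FALSE] -
    diams$diameter_mm[, 1:(n_t - 1), drop = FALSE]
  structure(list(delta_mm = delta, positions_mm = diams$positions_mm,
                 times_s = diams$times_s[-n_t],
                 valid = !is.na(delta)),
            class = "activity_map")
}

#' Per-position linearly detrended residual map
#'
#' For each arc-length position, an ordinary least-squares line
#' `d(s, .) ~ a_s + b_s * t` is fitted over the valid frames of the whole
#' recording, and the residuals `r(s, t) = d(s, t) - (a_s + b_s * t)` form
#' the spatiotemporal motility map. Negative residuals indicate luminal
#' narrowing (contraction). Positions with fewer than `min_valid` valid
#' frames are masked, not failed.
#'
#' @param diams a [diameter_profile_series()]
#' @param min_valid minimum number of valid frames per position (>= 3)
#' @return a `residual_map` with `residual_mm`, the fit coefficients
#'   `intercept_mm` and `slope_mm_per_s`, positions, times and validity
#' @export
residual_map <- function(diams, min_valid = 3) {
  check_that(inherits(diams, "diameter_profile_series"),
             "residual_map: input must be a diameter_profile_series")
  check_that(min_valid >= 3, "residual_map: min_valid must be >= 3")
  d <- diams$diameter_mm
  v <- diams$valid
  t_s <- diams$times_s
  d0 <- d; d0[!v] <- 0
  vn <- v * 1

  n <- rowSums(vn)
  st <- as.vector(vn %*% t_s)
  st2 <- as.vector(vn %*% t_s^2)
  sd_ <- rowSums(d0)
  std <- as.vector(d0 %*% t_s)
  det <- n * st2 - st^2
  fit_ok <- n >= min_valid & det > 1e-12
  b <- ifelse(fit_ok, (n * std - st * sd_) / det, NA_real_)
  a <- ifelse(fit_ok, (sd_ - b * st) / pmax(n, 1), NA_real_)

  r <- d - (a + outer(b, t_s))
  r[!v | !fit_ok] <- NA_real_
  structure(list(residual_mm = r, positions_mm = diams$positions_mm,
                 times_s = t_s, valid = !is.na(r),
                 intercept_mm = a, slope_mm_per_s = b),
            class = "residual_map")
}

#' Propagation velocity of a residual trough ridge
#'
#' Traces the deepest residual trough frame by frame (optionally inside a
#' time window) and regresses trough position on time; the slope recovers
#' the propagation velocity of a contraction wave (mm/s, positive =
#' antegrade). Frames whose trough is shallower than `depth_fraction` of
#' the deepest trough are ignored so that quiescent frames do not dilute
#' the fit.
#'
#' @param rmap a [residual_map()]
#' @param window optional `c(start, end)` time window in seconds,
#'   half-open
#' @param depth_fraction minimum trough depth relative to the window
#'   maximum
#' @return list with `velocity_mm_s` (NA when fewer than 3 usable frames)
#'   and `n_frames`
#' @export
estimate_ridge_velocity <- function(rmap, window = NULL, depth_fraction = 0.5) {
  check_that(inherits(rmap, "residual_map"), "estimate_ridge_velocity: input must be a residual_map")
  keep <- if (is.null(window)) rep(TRUE, length(rmap$times_s))
  else rmap$times_s >= window[1] & rmap$times_s < window[2]
  r <- rmap$residual_mm[, keep, drop = FALSE]
  tt <- rmap$times_s[keep]
  depth <- apply(r, 2, function(col)
    if (all(is.na(col))) NA_real_ else max(-col, na.rm = TRUE))
  dmax <- suppressWarnings(max(depth, na.rm = TRUE))
  if (!is.finite(dmax) || dmax <= 0)
    return(list(velocity_mm_s = NA_real_, n_frames = 0L))
  use <- which(!is.na(depth) & depth >= depth_fraction * dmax)
  if (length(use) < 3)
    return(list(velocity_mm_s = NA_real_, n_frames = length(use)))
  pos <- vapply(use, function(j) rmap$positions_mm[which.min(r[, j])],
                numeric(1))
  fit <- stats::lm.fit(cbind(1, tt[use]), pos)
  list(velocity_mm_s = unname(fit$coefficients[2]), n_frames = length(use))
}
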