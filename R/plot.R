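## Colour convention of the spatiotemporal motility plot: red = strongly
## negative residual (diameter well below trend, i.e. contraction),
## yellow = intermediate negative residual ("minimal" activity), blue =
## near-zero or positive residual (no activity).
motility_palette <- function(n = 64) {
  grDevices::colorRampPalette(c("#2166AC", "#FFD92F", "#B2182B"))(n)
}

#' Render the spatiotemporal motility plot
#'
#' Writes a PNG with recording time in minutes on the x-axis and
#' arc-length position in mm on the y-axis. The colour scale maps the
#' magnitude of negative residuals (luminal narrowing): blue for no
#' activity, yellow for minimal activity, red for strong contraction.
#' Colour limits are symmetric at the `clim_quantile` quantile of `|r|`;
#' invalid cells are left blank. Rendering is deterministic: the same map
#' yields a byte-identical file.
#'
#' @param rmap a [residual_map()]
#' @param out_path output PNG path
#' @param clim_quantile quantile of `|r|` setting the colour limit
#' @param width,height device size in pixels
#' @return `out_path`, invisibly
#' @export
render_motility_plot <- function(rmap, out_path, clim_quantile = 0.98,
                                 width = 900, height = 500) {
  check_that(inherits(rmap, "residual_map"), "render_motility_plot: input must be a residual_map")
  r <- rmap$residual_mm
  clim <- stats::quantile(abs(r), clim_quantile, na.rm = TRUE, names = FALSE)
  if (!is.finite(clim) || clim <= 0) clim <- 1
  z <- clamp(-r, 0, clim)
  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4.5, 4.5, 2, 1))
  graphics::image(x = rmap$times_s / 60, y = rmap$positions_mm, z = t(z),
                  zlim = c(0, clim), col = motility_palette(),
                  xlab = "Time (min)", ylab = "Position along colon (mm)",
                  main = "Spatiotemporal motility map", useRaster = TRUE)
  invisible(out_path)
}

#' Render the cross-modality overlay plot
#'
#' The motility map with the manometric HAPC windows (translated to the
#' MRI clock) drawn as vertical bands and the included channel positions
#' as horizontal tick lines, for visual comparison of the two modalities.
#'
#' @param session an [aligned_session()]
#' @param out_path output PNG path
#' @param clim_quantile quantile of `|r|` setting the colour limit
#' @param width,height device size in pixels
#' @return `out_path`, invisibly
#' @export
render_overlay_plot <- function(session, out_path, clim_quantile = 0.98,
                                width = 900, height = 500) {
  check_that(inherits(session, "aligned_session"),
             "render_overlay_plot: input must be an aligned_session")
  rmap <- session$rmap
  r <- rmap$residual_mm
  clim <- stats::quantile(abs(r), clim_quantile, na.rm = TRUE, names = FALSE)
  if (!is.finite(clim) || clim <= 0) clim <- 1
  z <- clamp(-r, 0, clim)
  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4.5, 4.5, 2, 1))
  graphics::image(x = rmap$times_s / 60, y = rmap$positions_mm, z = t(z),
                  zlim = c(0, clim), col = motility_palette(),
                  xlab = "Time (min)", ylab = "Position along colon (mm)",
                  main = "Cine-MRI motility map with manometric HAPC windows",
                  useRaster = TRUE)
  for (h in session$hapcs) {
    w <- (h$window_s - session$clock_offset_s) / 60
    graphics::rect(w[1], min(rmap$positions_mm), w[2], max(rmap$positions_mm),
                   border = "black", lty = 2, lwd = 1.5)
  }
  ch <- session$channel_positions_mm[session$included_channels]
  graphics::abline(h = ch, col = "grey20", lty = 3)
  graphics::axis(4, at = ch, labels = paste0("ch", session$included_channels),
                 las = 1, tick = FALSE, line = -1.2, cex.axis = 0.8)
  invisible(out_path)
}
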