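# Spot-level expression maps and overlays on tissue images: filled circles
# at spot centers, colored by normalized value on a continuous blue-to-
# yellow (viridis) scale — low expression renders blue, high yellow.

#' Overlay rendering configuration
#'
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (continuous, low = blue, high = yellow).
#' @param radius Spot marker radius in pixels.
#' @param alpha Blend factor in `[0, 1]` for overlays (1 = opaque marker).
#' @param range Value normalization: `NULL` for min/max of the rendered
#'   values, a length-2 numeric for fixed limits, or `"percentile"` for the
#'   1st-99th percentile of the values.
#' @return An `overlay_config` list.
#' @export
overlay_config <- function(colormap = "viridis", radius = 8, alpha = 0.6,
                           range = NULL) {
  if (alpha < 0 || alpha > 1) hx_validation_error("alpha must be in [0, 1]")
  if (radius <= 0) hx_validation_error("radius must be > 0")
  structure(
    list(colormap = colormap, radius = radius, alpha = alpha, range = range),
    class = "overlay_config"
  )
}

# Map values to RGB rows (0..255) through a continuous palette; monotone in
# the value.  Returns n x 3 matrix.
value_colors <- function(values, config, limits = NULL) {
  pal <- grDevices::hcl.colors(256L, config$colormap)
  rgb_pal <- t(grDevices::col2rgb(pal))
  if (is.null(limits)) {
    limits <- if (identical(config$range, "percentile")) {
      stats::quantile(values, c(0.01, 0.99), names = FALSE)
    } else if (is.numeric(config$range) && length(config$range) == 2L) {
      config$range
    } else {
      range(values)
    }
  }
  span <- limits[2] - limits[1]
  t01 <- if (span <= 0) rep(0.5, length(values)) else pmin(pmax((values - limits[1]) / span, 0), 1)
  rgb_pal[round(t01 * 255) + 1L, , drop = FALSE]
}

# Paint filled circles onto an image array in place; color_rows is n x 3.
paint_spots <- function(canvas, spots, color_rows, radius, alpha) {
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  r <- ceiling(radius)
  for (i in seq_len(nrow(spots))) {
    cx <- spots$pixel_x[i]; cy <- spots$pixel_y[i]
    if (cx < 0 || cx >= w || cy < 0 || cy >= h) {
      hx_validation_error("spot ", spots$spot_id[i], " outside image bounds")
    }
    rows <- max(1L, cy + 1L - r):min(h, cy + 1L + r)
    cols <- max(1L, cx + 1L - r):min(w, cx + 1L + r)
    disc <- outer((rows - (cy + 1L))^2, (cols - (cx + 1L))^2, `+`) <= radius^2
    for (ch in 1:3) {
      sub <- canvas[rows, cols, ch]
      sub[disc] <- (1 - alpha) * sub[disc] + alpha * color_rows[i, ch]
      canvas[rows, cols, ch] <- sub
    }
  }
  canvas
}

#' Render a spot-level expression map on a blank canvas
#'
#' @param spot_table Data frame with `spot_id`, `pixel_x`, `pixel_y`.
#' @param values Numeric vector aligned with the spots; must be finite.
#' @param image_size `c(height, width)` of the canvas in pixels.
#' @param config An [overlay_config()] (`alpha` is ignored here: markers
#'   are opaque on the blank canvas).
#' @return `H x W x 3` image array in `[0, 255]`.
#' @export
render_spot_map <- function(spot_table, values, image_size,
                            config = overlay_config()) {
  if (length(values) != nrow(spot_table)) {
    hx_validation_error("values must align with the spot table")
  }
  if (any(!is.finite(values))) {
    hx_validation_error(
      "non-finite values for spots: ",
      paste(utils::head(spot_table$spot_id[!is.finite(values)], 10), collapse = ", ")
    )
  }
  canvas <- array(255, c(image_size[1], image_size[2], 3L))
  cols <- value_colors(values, config)
  paint_spots(canvas, spot_table, cols, config$radius, alpha = 1)
}

#' Overlay spot expression on a tissue image
#'
#' Alpha-blends value-colored spot markers over the section image.  With
#' `truth` supplied, a side-by-side truth/prediction panel is produced
#' under a shared color scale (1st-99th percentile of the union of both
#' value sets), so equal values take equal colors in both panels.
#'
#' @param section_image `H x W x 3` image array in `[0, 255]`.
#' @param spot_table Data frame with `spot_id`, `pixel_x`, `pixel_y` in the
#'   image's coordinate frame.
#' @param values Numeric predictions aligned with the spots.
#' @param config An [overlay_config()].
#' @param truth Optional numeric vector of true values for the panel mode.
#' @return `H x W x 3` image (or `H x (2W) x 3` for the panel mode).
#' @export
render_overlay <- function(section_image, spot_table, values,
                           config = overlay_config(), truth = NULL) {
  check_rgb_image(section_image)
  if (length(values) != nrow(spot_table)) {
    hx_validation_error("values must align with the spot table")
  }
  if (is.null(truth)) {
    cols <- value_colors(values, config)
    return(paint_spots(section_image, spot_table, cols, config$radius, config$alpha))
  }
  pool <- c(truth, values)
  limits <- stats::quantile(pool, c(0.01, 0.99), names = FALSE)
  if (diff(limits) <= 0) limits <- range(pool)
  left <- paint_spots(
    section_image, spot_table,
    value_colors(truth, config, limits), config$radius, config$alpha
  )
  right <- paint_spots(
    section_image, spot_table,
    value_colors(values, config, limits), config$radius, config$alpha
  )
  d <- dim(section_image)
  out <- array(0, c(d[1], 2L * d[2], 3L))
  out[, seq_len(d[2]), ] <- left
  out[, d[2] + seq_len(d[2]), ] <- right
  out
}
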