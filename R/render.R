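#' Render a spot table as a synthetic phosphorimager scan
#'
#' Draws each spot as a 2-D Gaussian (FWHM equal to the nominal spot
#' diameter) whose disc-mean intensity equals `2^net_log2`, on a noisy
#' background, optionally adds artifacts (stripes, blemishes, oversized
#' spots), applies the scanner's forward square-root transform and quantizes
#' to 16 bits. Deterministic given `seed`. Intensities exceeding 16 bits
#' after the forward transform are clipped and the clipped pixel count
#' recorded (a source of saturated test spots).
#'
#' @param tab Spot table carrying target `net_log2` intensities (`NA` or
#'   off-spots render as background).
#' @param layout The [array_layout()].
#' @param artifacts Optional list of artifact specs, each a list with
#'   `type = "stripe"` (`row_px`, `height_px`, `level`),
#'   `type = "blemish"` (`x_px`, `y_px`, `radius_px`, `level`) or
#'   `type = "oversize"` (`set`, `row`, `col`, `scale`); positions in pixels
#'   of the rendered image, levels on the reverse-transformed scale.
#' @param seed Integer seed for the background noise.
#' @param pixel_pitch Pixel size in micrometres (default 50).
#' @param margin_px Blank margin around the spotted area (default 12 px).
#' @param bg_level,bg_sd Background mean and SD on the reverse-transformed
#'   scale (defaults 50 and 5).
#' @param rotation_deg Rotate the rendered scene by this angle before
#'   quantization (default 0), for testing rotation alignment.
#' @param spec The [transform_spec()] used for the forward transform.
#' @return A raw-state [phosphor_image()] with attributes `centers` (tibble
#'   of true spot centres in pixels), `bounds` (`c(x0, y0, x1, y1)` of the
#'   spotted area) and `clipped` (count of clipped pixels).
#' @export
render_slide <- function(tab, layout, artifacts = NULL, seed = 1L,
                         pixel_pitch = 50, margin_px = 12L,
                         bg_level = 50, bg_sd = 5, rotation_deg = 0,
                         spec = transform_spec()) {
  assert_spot_table(tab)
  pitch_px <- layout$spot_pitch / pixel_pitch
  n_rows <- layout$n_sets * layout$set_rows
  height <- ceiling((n_rows - 1) * pitch_px) + 2L * margin_px + 1L
  width <- ceiling((layout$set_cols - 1) * pitch_px) + 2L * margin_px + 1L
  canvas <- with_substream(seed, "render_bg",
    matrix(pmax(stats::rnorm(height * width, bg_level, bg_sd), 0),
           height, width))
  sigma_px <- (layout$spot_diameter / 2.355) / pixel_pitch  # FWHM = diameter
  centers <- dplyr::mutate(
    tab,
    x_px = margin_px + 1 + .data$x_um / pixel_pitch,
    y_px = margin_px + 1 + .data$y_um / pixel_pitch)

  disc_r2 <- ((layout$spot_diameter / 2) / pixel_pitch)^2
  h <- ceiling(3.5 * sigma_px)
  off <- tidyr::expand_grid(dy = -h:h, dx = -h:h)

  oversize <- list()
  for (a in artifacts %||% list()) {
    if (identical(a$type, "oversize")) {
      oversize[[length(oversize) + 1L]] <- a
    }
  }
  os_key <- vapply(oversize, function(a)
    paste(a$set, a$row, a$col), character(1))

  for (i in seq_len(nrow(centers))) {
    v <- centers$net_log2[i]
    if (is.na(v)) next
    cx <- centers$x_px[i]; cy <- centers$y_px[i]
    key <- paste(centers$set[i], centers$row[i], centers$col[i])
    s <- sigma_px
    if (key %in% os_key) {
      s <- sigma_px * (oversize[[match(key, os_key)]]$scale %||% 2)
    }
    ix <- round(cx) + off$dx
    iy <- round(cy) + off$dy
    ok <- ix >= 1 & ix <= width & iy >= 1 & iy <= height
    g <- exp(-((ix - cx)^2 + (iy - cy)^2) / (2 * s^2))
    in_disc <- (ix - round(cx))^2 + (iy - round(cy))^2 <= disc_r2
    f <- mean(g[in_disc])          # disc-mean of the unit kernel
    amp <- 2^v / f
    idx <- cbind(iy[ok], ix[ok])
    canvas[idx] <- canvas[idx] + amp * g[ok]
  }

  for (a in artifacts %||% list()) {
    if (identical(a$type, "stripe")) {
      r0 <- max(1L, round(a$row_px))
      r1 <- min(height, round(a$row_px + a$height_px - 1))
      canvas[r0:r1, ] <- canvas[r0:r1, ] + a$level
    } else if (identical(a$type, "blemish")) {
      yy <- matrix(seq_len(height), height, width)
      xx <- matrix(seq_len(width), height, width, byrow = TRUE)
      hit <- (xx - a$x_px)^2 + (yy - a$y_px)^2 <= a$radius_px^2
      canvas[hit] <- canvas[hit] + a$level
    }
  }

  if (rotation_deg != 0) {
    canvas <- as.matrix(EBImage::rotate(canvas, rotation_deg,
                                        bg.col = bg_level))
  }

  q <- forward_transform_quantized(canvas, spec)
  img <- phosphor_image(q$pixels, pixel_pitch, "raw")
  attr(img, "centers") <- dplyr::select(
    centers, "set", "row", "col", "substrate_id", "x_px", "y_px")
  attr(img, "bounds") <- c(
    x0 = margin_px + 1 - pitch_px / 2,
    y0 = margin_px + 1 - pitch_px / 2,
    x1 = margin_px + 1 + (layout$set_cols - 1) * pitch_px + pitch_px / 2,
    y1 = margin_px + 1 + (n_rows - 1) * pitch_px + pitch_px / 2)
  attr(img, "clipped") <- q$clipped
  img
}
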