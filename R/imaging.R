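#' Phosphorimager image container
#'
#' Wraps a 2-D pixel intensity matrix with its physical scale. Raw scans are
#' 16-bit (values 0..65535) and carry the scanner's square-root compression;
#' [reverse_transform()] undoes it before any quantification.
#'
#' @param pixels Numeric matrix of non-negative pixel intensities
#'   (rows = y, columns = x).
#' @param pixel_pitch Physical pixel size in micrometres (default 50).
#' @param transform_state `"raw"` (scanner output) or
#'   `"reverse_transformed"`.
#' @return An object of class `phosphor_image`.
#' @export
phosphor_image <- function(pixels, pixel_pitch = 50,
                           transform_state = c("raw", "reverse_transformed")) {
  transform_state <- match.arg(transform_state)
  stopifnot(is.matrix(pixels), pixel_pitch > 0, all(pixels >= 0, na.rm = TRUE))
  if (transform_state == "raw" && any(pixels > 65535)) {
    stop("raw pixel values must fit 16 bits (<= 65535)", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_pitch = pixel_pitch,
                 transform_state = transform_state),
            class = "phosphor_image")
}

#' @export
print.phosphor_image <- function(x, ...) {
  cat(sprintf("<phosphor_image> %d x %d px @ %g um/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch,
              x$transform_state))
  invisible(x)
}

#' Read / write a 16-bit grayscale TIFF scan
#'
#' @param path TIFF file path.
#' @param pixel_pitch Pixel size in micrometres.
#' @param transform_state State of the stored pixels (scans from the
#'   instrument are `"raw"`).
#' @return `read_phosphor_tiff()` returns a [phosphor_image()].
#' @export
read_phosphor_tiff <- function(path, pixel_pitch = 50,
                               transform_state = "raw") {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  phosphor_image(round(px * 65535), pixel_pitch, transform_state)
}

#' @param image A [phosphor_image()] in raw state.
#' @rdname read_phosphor_tiff
#' @export
write_phosphor_tiff <- function(image, path) {
  stopifnot(inherits(image, "phosphor_image"))
  if (image$transform_state != "raw") {
    stop("only raw images are written as 16-bit TIFF", call. = FALSE)
  }
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Intensity transform specification
#'
#' The phosphorimager stores square-root-compressed pixel values; analysis
#' works on reverse-transformed intensities
#' `I_transformed = I_raw^2 / TF` with transformation factor `TF = 42752`.
#' The functional form is configurable through `reverse`/`forward`.
#'
#' @param TF Transformation factor (> 0).
#' @param reverse,forward Callables `(intensity, TF)` implementing the
#'   reverse transform and its inverse.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(TF = 42752,
                           reverse = function(i, tf) i^2 / tf,
                           forward = function(i, tf) sqrt(i * tf)) {
  stopifnot(TF > 0, is.function(reverse), is.function(forward))
  structure(list(TF = TF, reverse = reverse, forward = forward),
            class = "transform_spec")
}

#' Reverse the scanner's square-root compression
#'
#' Applies `I_transformed = I_raw^2 / TF` per pixel; monotone and
#' order-preserving. The result is the intensity scale on which
#' quantification, saturation checks (level 95000) and flagging operate.
#'
#' @param image A [phosphor_image()] in `"raw"` state.
#' @param spec A [transform_spec()].
#' @return The reverse-transformed [phosphor_image()].
#' @export
#' @examples
#' img <- phosphor_image(matrix(c(0, 65535), 1))
#' reverse_transform(img)$pixels   # 0 and 65535^2 / 42752
reverse_transform <- function(image, spec = transform_spec()) {
  stopifnot(inherits(image, "phosphor_image"))
  if (image$transform_state != "raw") {
    stop("image is already reverse-transformed", call. = FALSE)
  }
  phosphor_image(spec$reverse(image$pixels, spec$TF), image$pixel_pitch,
                 "reverse_transformed")
}

# forward (scanner) transform with 16-bit quantization; used by the renderer
forward_transform_quantized <- function(pixels, spec = transform_spec()) {
  raw <- round(spec$forward(pmax(pixels, 0), spec$TF))
  clipped <- sum(raw > 65535)
  raw <- pmin(raw, 65535)
  list(pixels = raw, clipped = clipped)
}

enhance_defaults <- function(layout, pixel_pitch) {
  spot_radius_px <- (layout$spot_diameter / 2) / pixel_pitch
  list(
    median_size = 1L,                       # 3x3 median filter
    log_sigma = spot_radius_px / sqrt(2),   # matched-filter LoG scale
    opening_radius = 1L,                    # disc, removes objects < 100 um
    smooth_sigma = 1                        # final Gaussian smoothing
  )
}

log_kernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  x <- -h:h
  g <- outer(x, x, function(y, x) {
    r2 <- x^2 + y^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  k <- -g            # negated LoG: bright round blobs give positive response
  k - mean(k)        # zero-sum: constant images map to exactly zero
}

#' Enhance a scan for gridding and quality control
#'
#' Noise reduction and contrast chain applied to the reverse-transformed
#' image: 3x3 median filter, negated Laplacian-of-Gaussian matched to the
#' spot radius (enhancing round objects of the right size), morphological
#' opening with a 1-pixel disc removing objects smaller than 100 um, and a
#' final Gaussian smoothing. The enhanced image drives gridding and flags
#' only; intensity quantification always reads the reverse-transformed
#' pixels.
#'
#' @param image A reverse-transformed [phosphor_image()].
#' @param layout The slide [array_layout()] (sets the LoG scale).
#' @param params Optional list overriding the enhancement defaults
#'   (`median_size`, `log_sigma`, `opening_radius`, `smooth_sigma`).
#' @return An object of class `enhanced_image` (signed pixel matrix plus the
#'   parameters used).
#' @export
enhance_image <- function(image, layout, params = NULL) {
  stopifnot(inherits(image, "phosphor_image"))
  if (image$transform_state != "reverse_transformed") {
    stop("enhance_image() expects a reverse-transformed image", call. = FALSE)
  }
  p <- utils::modifyList(enhance_defaults(layout, image$pixel_pitch),
                         params %||% list())
  k <- log_kernel(p$log_sigma)
  if (nrow(image$pixels) < nrow(k) || ncol(image$pixels) < ncol(k)) {
    stop("image smaller than the enhancement filter support", call. = FALSE)
  }
  px <- image$pixels
  scale <- max(px, 1)
  med <- EBImage::medianFilter(px / scale, size = p$median_size) * scale
  enh <- EBImage::filter2(med, k, boundary = "replicate")
  mask <- (enh > 0) * 1
  opened <- EBImage::opening(mask,
    EBImage::makeBrush(2L * p$opening_radius + 1L, "disc"))
  enh[mask & !(opened > 0)] <- 0
  enh <- EBImage::gblur(enh, sigma = p$smooth_sigma)
  structure(list(pixels = as.matrix(enh), pixel_pitch = image$pixel_pitch,
                 params = p),
            class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image> %d x %d px @ %g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch))
  invisible(x)
}

#' Align spot columns vertically by small rotation
#'
#' Thresholds the enhanced image at its 87th percentile and scans rotation
#' angles in 0.1 degree steps over \[-3, +3\] degrees, choosing the angle that
#' maximizes the variance of the column-wise sum profile of the thresholded
#' image (sharp column peaks indicate vertical alignment). If the optimum
#' sits on the bound a warning is raised and the bound returned.
#'
#' @param enh An [enhance_image()] result.
#' @param angle_range Maximum absolute rotation in degrees (default 3).
#' @param step Angle step in degrees (default 0.1).
#' @return A list with `image` (the rotated `enhanced_image`) and `angle`
#'   (degrees applied).
#' @export
auto_rotate <- function(enh, angle_range = 3, step = 0.1) {
  stopifnot(inherits(enh, "enhanced_image"))
  thr <- stats::quantile(enh$pixels, 0.87)
  mask <- (enh$pixels > thr) * 1
  angles <- seq(-angle_range, angle_range, by = step)
  score <- vapply(angles, function(a) {
    m <- if (a == 0) mask else
      as.matrix(EBImage::rotate(mask, a, bg.col = 0))
    stats::var(colSums(m))
  }, numeric(1))
  best <- angles[which.max(score)]
  if (abs(abs(best) - angle_range) < step / 2) {
    warning(sprintf("rotation optimum at the +/-%g degree bound", angle_range),
            call. = FALSE)
  }
  rotated <- enh
  if (best != 0) {
    rotated$pixels <- as.matrix(EBImage::rotate(enh$pixels, best, bg.col = 0))
  }
  list(image = rotated, angle = best)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
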