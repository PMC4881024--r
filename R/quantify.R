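#' Quantification and flagging parameters
#'
#' All physical constants of spot quantification and quality flagging, on the
#' reverse-transformed intensity scale. Defaults correspond to a 250 um spot
#' at 50 um/px: a 21-pixel measurement disc, centre refinement within 100 um,
#' background in a 550 um square minus a 275 um exclusion circle, saturation
#' at level 95000 in more than 3 of the 21 disc pixels, two-sample KS test of
#' disc vs background pixels at alpha 0.01, shape assessment in a 500 um
#' window thresholded at the 80th percentile with aspect limits 1.6 (bright
#' spots, log2 > 8) and 2.0 (weak), position tolerance 100 um, and overshine
#' requiring the disc mean to exceed the background median by 3 background
#' SDs.
#'
#' @param disc_radius_um Measurement disc radius.
#' @param refine_range_um Centre refinement range.
#' @param bg_halfwidth_um Background square half-width.
#' @param bg_exclusion_um Background exclusion circle radius.
#' @param saturation_level,saturation_count Saturation intensity and maximum
#'   tolerated saturated disc pixels.
#' @param ks_alpha KS-flag significance level.
#' @param shape_window_um,shape_percentile Shape/position window and
#'   threshold.
#' @param aspect_bright,aspect_weak,bright_log2 Aspect-ratio limits and the
#'   log2 level separating bright from weak spots.
#' @param position_tolerance_um Centroid-to-grid distance tolerance
#'   (user-configurable).
#' @param overshine_sd_mult Background SD multiplier of the overshine test.
#' @param min_bg_pixels Minimum usable background pixels before the spot is
#'   flagged as artifact-shadowed.
#' @param artifact_cover_frac Fraction of the background window covered by a
#'   large artifact object that triggers the artifact flag.
#' @return A `quantify_params` list.
#' @export
quantify_params <- function(disc_radius_um = 125, refine_range_um = 100,
                            bg_halfwidth_um = 275, bg_exclusion_um = 275,
                            saturation_level = 95000, saturation_count = 3,
                            ks_alpha = 0.01, shape_window_um = 500,
                            shape_percentile = 80, aspect_bright = 1.6,
                            aspect_weak = 2.0, bright_log2 = 8,
                            position_tolerance_um = 100,
                            overshine_sd_mult = 3, min_bg_pixels = 10,
                            artifact_cover_frac = 0.3) {
  stopifnot(disc_radius_um > 0, bg_halfwidth_um > 0,
            shape_percentile > 0, shape_percentile < 100,
            ks_alpha > 0, ks_alpha < 1)
  structure(as.list(environment()), class = "quantify_params")
}

# pixel offset sets for the disc / background / shape windows
pixel_offsets <- function(params, pixel_pitch) {
  r_disc <- params$disc_radius_um / pixel_pitch
  h_bg <- floor(params$bg_halfwidth_um / pixel_pitch + 0.5)
  r_exc <- params$bg_exclusion_um / pixel_pitch
  disc <- tidyr::expand_grid(dy = -floor(r_disc):floor(r_disc),
                             dx = -floor(r_disc):floor(r_disc))
  disc <- disc[disc$dx^2 + disc$dy^2 <= r_disc^2, ]
  bg <- tidyr::expand_grid(dy = -h_bg:h_bg, dx = -h_bg:h_bg)
  bg <- bg[bg$dx^2 + bg$dy^2 > r_exc^2, ]
  half_w <- round(params$shape_window_um / pixel_pitch / 2)
  win <- tidyr::expand_grid(dy = (-half_w):(half_w + 1),
                            dx = (-half_w):(half_w + 1))
  list(disc = disc, bg = bg, win = win)
}

extract_px <- function(pixels, cx, cy, off) {
  ix <- round(cx) + off$dx
  iy <- round(cy) + off$dy
  ok <- ix >= 1 & ix <= ncol(pixels) & iy >= 1 & iy <= nrow(pixels)
  list(values = pixels[cbind(iy[ok], ix[ok])], ix = ix[ok], iy = iy[ok])
}

#' Refine a spot centre within the allowed range
#'
#' Searches integer pixel positions within `refine_range_um` (default
#' 100 um, i.e. 2 px) of the nominal grid centre for the position maximizing
#' the mean intensity over the measurement disc; the clamp guarantees the
#' refined centre never strays further than the range from the grid.
#'
#' @param image A reverse-transformed [phosphor_image()].
#' @param center Numeric `c(x, y)` nominal centre in pixels.
#' @param params [quantify_params()].
#' @return Refined `c(x, y)` centre in pixels.
#' @export
refine_center <- function(image, center, params = quantify_params()) {
  off <- pixel_offsets(params, image$pixel_pitch)$disc
  r <- floor(params$refine_range_um / image$pixel_pitch)
  cand <- tidyr::expand_grid(dx = -r:r, dy = -r:r)
  score <- mapply(function(dx, dy) {
    px <- extract_px(image$pixels, center[1] + dx, center[2] + dy, off)
    if (length(px$values) == 0) -Inf else mean(px$values)
  }, cand$dx, cand$dy)
  b <- which.max(score)
  c(round(center[1]) + cand$dx[b], round(center[2]) + cand$dy[b])
}

#' Quantify one spot
#'
#' Mean intensity over the 21-pixel measurement disc minus the median over
#' the background region (the 550 um square minus the 275 um exclusion
#' circle, minus any excluded artifact pixels), log2-transformed. A
#' non-positive net intensity gives a missing `net_log2` (a No-Contrast
#' candidate); fewer than `min_bg_pixels` usable background pixels marks the
#' spot artifact-shadowed.
#'
#' @inheritParams refine_center
#' @param exclusions Optional logical matrix (same shape as the image)
#'   marking pixels excluded from the background (large artifacts, oversized
#'   spots).
#' @return A list: `net_log2` (or `NA`), `net`, `disc_mean`, `bg_median`,
#'   `bg_sd`, `disc_values`, `bg_values`, `n_bg`, `bg_failed`.
#' @export
quantify_spot <- function(image, center, params = quantify_params(),
                          exclusions = NULL) {
  stopifnot(image$transform_state == "reverse_transformed")
  off <- pixel_offsets(params, image$pixel_pitch)
  disc <- extract_px(image$pixels, center[1], center[2], off$disc)
  bg <- extract_px(image$pixels, center[1], center[2], off$bg)
  keep <- rep(TRUE, length(bg$values))
  if (!is.null(exclusions)) keep <- !exclusions[cbind(bg$iy, bg$ix)]
  bg_vals <- bg$values[keep]
  bg_failed <- length(bg_vals) < params$min_bg_pixels
  disc_mean <- mean(disc$values)
  bg_median <- if (length(bg_vals)) stats::median(bg_vals) else NA_real_
  bg_sd <- if (length(bg_vals) > 1) stats::sd(bg_vals) else NA_real_
  net <- disc_mean - bg_median
  list(
    net_log2 = if (!is.na(net) && net > 0) log2(net) else NA_real_,
    net = net, disc_mean = disc_mean, bg_median = bg_median, bg_sd = bg_sd,
    disc_values = disc$values, bg_values = bg_vals,
    n_bg = length(bg_vals), bg_failed = bg_failed)
}

# slide-level artifact mask: connected regions of the reverse-transformed
# image above its 90th percentile that are either much larger than a spot
# (> 20x disc area: blemishes) or large and elongated (> 2x disc area with
# aspect > 2: stripes, scratches)
detect_artifact_mask <- function(image, params = quantify_params()) {
  disc_area <- 21
  thr <- stats::quantile(image$pixels, 0.90)
  lab <- EBImage::bwlabel((image$pixels > thr) * 1)
  if (max(lab) == 0) {
    return(matrix(FALSE, nrow(image$pixels), ncol(image$pixels)))
  }
  obj <- mask_objects(image$pixels > thr)
  bad <- obj$label[obj$area > 20 * disc_area |
                     (obj$area > 2 * disc_area & obj$aspect > 2)]
  matrix(lab %in% bad, nrow(image$pixels), ncol(image$pixels))
}

#' Quality flags of one spot
#'
#' Computes the eight binary reliability flags:
#' \describe{
#'   \item{artifact}{a large artifact object (stripe, mark, blemish) covers
#'     more than `artifact_cover_frac` of the spot's background window, or
#'     too few background pixels remain.}
#'   \item{overshine}{a directly neighbouring bright spot (log2 > 8) shows
#'     uniformly decreasing intensity into the spot area while the disc mean
#'     exceeds the background median + 3 SD.}
#'   \item{ks}{the two-sample Kolmogorov-Smirnov test cannot distinguish
#'     disc from background pixels at `ks_alpha` (the spot is
#'     indistinguishable from background, i.e. an off-spot).}
#'   \item{no_contrast}{all enhanced-image disc pixels are < 0, or the net
#'     intensity is non-positive.}
#'   \item{saturated}{more than `saturation_count` of the disc pixels exceed
#'     the saturation level.}
#'   \item{shape}{the above-threshold object in the shape window has aspect
#'     ratio above the bright/weak limit.}
#'   \item{position}{the intensity-weighted centroid of the 20% brightest
#'     window pixels lies further than the position tolerance from the grid.}
#'   \item{overall}{logical OR of the seven flags above.}
#' }
#' Missing inputs set the corresponding flag to 1 conservatively.
#'
#' @inheritParams quantify_spot
#' @param enh The matching [enhance_image()] result.
#' @param nominal Grid centre `c(x, y)` in pixels (position flag reference).
#' @param quant Result of [quantify_spot()] for this spot.
#' @param neighbors Optional tibble of directly neighbouring spots with
#'   columns `x_px`, `y_px`, `net_log2` (for the overshine test).
#' @param artifact_mask Optional logical matrix of large-artifact pixels
#'   (see the artifact flag).
#' @return Named integer vector over [flag_columns()].
#' @export
flag_spot <- function(image, enh, center, nominal, quant,
                      params = quantify_params(), neighbors = NULL,
                      artifact_mask = NULL) {
  pp <- image$pixel_pitch
  off <- pixel_offsets(params, pp)
  f <- stats::setNames(integer(length(FLAG_COLS)), FLAG_COLS)

  # artifact
  if (quant$bg_failed) f["artifact"] <- 1L
  if (!is.null(artifact_mask)) {
    bgw <- extract_px(artifact_mask * 1, center[1], center[2], off$bg)
    if (length(bgw$values) && mean(bgw$values) > params$artifact_cover_frac) {
      f["artifact"] <- 1L
    }
  }

  # saturated
  f["saturated"] <-
    as.integer(sum(quant$disc_values > params$saturation_level) >
                 params$saturation_count)

  # KS: flag when disc is NOT distinguishable from background
  if (length(quant$bg_values) >= 2 && length(quant$disc_values) >= 2) {
    p_ks <- suppressWarnings(
      stats::ks.test(quant$disc_values, quant$bg_values)$p.value)
    f["ks"] <- as.integer(p_ks >= params$ks_alpha)
  } else {
    f["ks"] <- 1L
  }

  # no contrast
  enh_disc <- extract_px(enh$pixels, center[1], center[2], off$disc)
  f["no_contrast"] <- as.integer(
    all(enh_disc$values < 0) || is.na(quant$net) || quant$net <= 0)

  # shape & position from the 500 um window of the reverse-transformed image:
  # the window is thresholded and the spot is the connected object at the
  # window centre (largest object if the centre pixel is below threshold)
  win <- extract_px(image$pixels, center[1], center[2], off$win)
  if (length(win$values) >= 4) {
    thr <- stats::quantile(win$values, params$shape_percentile / 100)
    sel <- win$values > thr
    obj_sel <- rep(FALSE, length(sel))
    if (sum(sel) >= 3) {
      wm <- matrix(0L, max(win$iy) - min(win$iy) + 1L,
                   max(win$ix) - min(win$ix) + 1L)
      ly <- win$iy - min(win$iy) + 1L
      lx <- win$ix - min(win$ix) + 1L
      wm[cbind(ly[sel], lx[sel])] <- 1L
      lab <- EBImage::bwlabel(wm)
      cy0 <- round(center[2]) - min(win$iy) + 1L
      cx0 <- round(center[1]) - min(win$ix) + 1L
      centre_lab <- if (cy0 >= 1 && cy0 <= nrow(lab) &&
                        cx0 >= 1 && cx0 <= ncol(lab)) lab[cy0, cx0] else 0L
      if (centre_lab == 0L) {
        centre_lab <- which.max(tabulate(lab[lab > 0], max(lab)))
      }
      obj_sel <- lab[cbind(ly, lx)] == centre_lab
    }
    if (sum(obj_sel) >= 3) {
      pts <- cbind(win$iy[obj_sel], win$ix[obj_sel])
      cv <- stats::cov(pts) + diag(1 / 12, 2)
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      aspect <- sqrt(max(ev) / max(min(ev), 1e-9))
      lim <- if (!is.na(quant$net_log2) && quant$net_log2 > params$bright_log2)
        params$aspect_bright else params$aspect_weak
      f["shape"] <- as.integer(aspect > lim)
      # intensity-weighted centroid of the object formed by the 20%
      # brightest window pixels
      w <- win$values[obj_sel]
      cx_w <- sum(win$ix[obj_sel] * w) / sum(w)
      cy_w <- sum(win$iy[obj_sel] * w) / sum(w)
      d_um <- sqrt((cx_w - nominal[1])^2 + (cy_w - nominal[2])^2) * pp
      f["position"] <- as.integer(d_um > params$position_tolerance_um)
    } else {
      f["shape"] <- 1L
      f["position"] <- 1L
    }
  } else {
    f["shape"] <- 1L
    f["position"] <- 1L
  }

  # overshine from bright direct neighbours: intensity along a 5-sample ray
  # from the neighbour centre into the spot area must decrease uniformly and
  # still exceed the background level + 3 robust SD (MAD) where it reaches
  # the measurement disc, i.e. the bleed dominates the spot's own signal
  if (!is.null(neighbors) && nrow(neighbors) > 0 &&
      !is.na(quant$bg_median) && length(quant$bg_values) > 1) {
    bg_spread <- stats::mad(quant$bg_values)
    lim <- quant$bg_median + params$overshine_sd_mult * bg_spread
    for (i in seq_len(nrow(neighbors))) {
      nb <- neighbors[i, ]
      if (is.na(nb$net_log2) || nb$net_log2 <= params$bright_log2) next
      tt <- seq(0.15, 0.85, length.out = 5)
      ray <- vapply(tt, function(t) {
        x <- nb$x_px + t * (center[1] - nb$x_px)
        y <- nb$y_px + t * (center[2] - nb$y_px)
        image$pixels[round(y), round(x)]
      }, numeric(1))
      if (all(diff(ray) < 0) && ray[length(ray)] > lim) {
        f["overshine"] <- 1L
        break
      }
    }
  }

  f["overall"] <- as.integer(any(f[setdiff(FLAG_COLS, "overall")] == 1L))
  f
}

#' Quantify a full slide image into a spot table
#'
#' The complete image-analysis pipeline: reverse transform (if needed),
#' enhancement, optional rotation alignment, large-artifact detection, pin
#' block location within the user-supplied bounds, per-block grid fitting,
#' per-spot centre refinement, intensity quantification and quality
#' flagging.
#'
#' @param image A [phosphor_image()] (raw or reverse-transformed).
#' @param bounds `c(x0, y0, x1, y1)` pixel rectangle enclosing the spotted
#'   area (replaces interactive boundary selection).
#' @param layout The [array_layout()].
#' @param params [quantify_params()].
#' @param spec [transform_spec()] for the reverse transform.
#' @param rotate Run [auto_rotate()] before gridding (default FALSE; the
#'   supplied bounds must refer to the rotated image).
#' @param slide_id,condition Identifier columns of the output table.
#' @return A spot table (see [read_spot_table()]) with one row per grid
#'   position, plus `x_px`/`y_px` refined centre columns.
#' @export
quantify_image <- function(image, bounds, layout, params = quantify_params(),
                           spec = transform_spec(), rotate = FALSE,
                           slide_id = "slide", condition = NA_character_) {
  if (image$transform_state == "raw") image <- reverse_transform(image, spec)
  enh <- enhance_image(image, layout)
  if (rotate) {
    rot <- auto_rotate(enh)
    enh <- rot$image
    if (rot$angle != 0) {
      image$pixels <- as.matrix(
        EBImage::rotate(image$pixels, rot$angle, bg.col = 0))
    }
  }
  artifact_mask <- detect_artifact_mask(image, params)
  blocks <- locate_blocks(enh, bounds, layout)
  centers <- dplyr::bind_rows(lapply(blocks, function(b) {
    g <- fit_grid(b, layout)
    g$set <- b$set
    g$row <- g$row + b$block_row * layout$block_size
    g$col <- g$col + b$block_col * layout$block_size
    g
  }))
  centers <- dplyr::arrange(centers, .data$set, .data$row, .data$col)

  quants <- vector("list", nrow(centers))
  refined <- matrix(NA_real_, nrow(centers), 2)
  for (i in seq_len(nrow(centers))) {
    nominal <- c(centers$x_px[i], centers$y_px[i])
    ctr <- refine_center(image, nominal, params)
    refined[i, ] <- ctr
    quants[[i]] <- quantify_spot(image, ctr, params, artifact_mask)
  }
  centers$x_ref <- refined[, 1]
  centers$y_ref <- refined[, 2]
  centers$net_log2 <- vapply(quants, function(q) q$net_log2, numeric(1))

  key <- paste(centers$set, centers$row, centers$col)
  flags <- matrix(0L, nrow(centers), length(FLAG_COLS),
                  dimnames = list(NULL, FLAG_COLS))
  for (i in seq_len(nrow(centers))) {
    nb_key <- paste(centers$set[i],
                    rep(centers$row[i] + (-1:1), each = 3),
                    rep(centers$col[i] + (-1:1), times = 3))
    nb <- centers[match(setdiff(nb_key, key[i]), key), , drop = FALSE]
    nb <- nb[!is.na(nb$set), , drop = FALSE]
    nb <- tibble::tibble(x_px = nb$x_ref, y_px = nb$y_ref,
                         net_log2 = nb$net_log2)
    flags[i, ] <- flag_spot(
      image, enh, c(centers$x_ref[i], centers$y_ref[i]),
      c(centers$x_px[i], centers$y_px[i]), quants[[i]], params,
      neighbors = nb, artifact_mask = artifact_mask)
  }

  tab <- new_spot_table(layout, slide_id = slide_id, condition = condition)
  ord <- match(paste(tab$set, tab$row, tab$col), key)
  tab$net_log2 <- centers$net_log2[ord]
  for (fc in FLAG_COLS) tab[[fc]] <- flags[ord, fc]
  tab$x_px <- centers$x_ref[ord]
  tab$y_px <- centers$y_ref[ord]
  tab
}
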