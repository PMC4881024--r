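# connected components of a binary mask with area, centroid (x, y in px,
# 1-based) and aspect ratio (sqrt of second-moment eigenvalue ratio)
mask_objects <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n == 0) {
    return(tibble::tibble(label = integer(), area = integer(),
                          cx = numeric(), cy = numeric(), aspect = numeric()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  lb <- lab[lab > 0]
  area <- tabulate(lb, n)
  cy <- tapply(idx[, 1], lb, mean)
  cx <- tapply(idx[, 2], lb, mean)
  aspect <- vapply(seq_len(n), function(i) {
    pts <- idx[lb == i, , drop = FALSE]
    if (nrow(pts) < 3) return(1)
    cv <- stats::cov(pts) + diag(1 / 12, 2)   # pixel extent regularization
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    sqrt(max(ev) / max(min(ev), 1e-9))
  }, numeric(1))
  tibble::tibble(label = seq_len(n), area = area,
                 cx = as.numeric(cx), cy = as.numeric(cy), aspect = aspect)
}

#' Partition the spotted area into pin blocks
#'
#' Given the user-indicated rectangle enclosing the spotted area (replacing
#' the interactive boundary clicks of a GUI), splits it into the pin blocks
#' of the layout: `(set_rows / block_size) * (set_cols / block_size)` blocks
#' per set, sets stacked vertically. Bounds are accepted within a 10%
#' tolerance of the nominal layout dimensions and the partition rescales
#' proportionally.
#'
#' @param enh An [enhance_image()] result.
#' @param bounds Numeric `c(x0, y0, x1, y1)` in pixels (1-based, inclusive)
#'   enclosing the spot area: spot centres plus half a pitch of margin.
#' @param layout The [array_layout()].
#' @return A list of blocks, each a list with the enhanced `pixels`
#'   subimage, `set`, `block_row`, `block_col` (0-based), the block `origin`
#'   (x, y of its top-left corner in full-image pixels) and the per-spot
#'   steps `col_step`, `row_step` in pixels.
#' @export
locate_blocks <- function(enh, bounds, layout) {
  stopifnot(inherits(enh, "enhanced_image"), length(bounds) == 4)
  bounds <- unname(as.numeric(bounds))
  x0 <- bounds[1]; y0 <- bounds[2]; x1 <- bounds[3]; y1 <- bounds[4]
  stopifnot(x1 > x0, y1 > y0)
  pp <- enh$pixel_pitch
  exp_w <- layout$set_cols * layout$spot_pitch / pp
  exp_h <- layout$n_sets * layout$set_rows * layout$spot_pitch / pp
  w <- x1 - x0; h <- y1 - y0
  if (abs(w - exp_w) / exp_w > 0.10 || abs(h - exp_h) / exp_h > 0.10) {
    stop(sprintf(
      "bounds (%.0f x %.0f px) inconsistent with layout (%.0f x %.0f px, 10%% tolerance)",
      w, h, exp_w, exp_h), call. = FALSE)
  }
  bs <- layout$block_size
  col_step <- w / layout$set_cols
  row_step <- h / (layout$n_sets * layout$set_rows)
  nbr <- layout$set_rows %/% bs
  nbc <- layout$set_cols %/% bs
  blocks <- list()
  for (s in seq_len(layout$n_sets) - 1L) {
    for (br in seq_len(nbr) - 1L) {
      for (bc in seq_len(nbc) - 1L) {
        oy <- y0 + (s * layout$set_rows + br * bs) * row_step
        ox <- x0 + bc * bs * col_step
        ry <- max(1L, floor(oy)):min(nrow(enh$pixels), ceiling(oy + bs * row_step))
        rx <- max(1L, floor(ox)):min(ncol(enh$pixels), ceiling(ox + bs * col_step))
        blocks[[length(blocks) + 1L]] <- list(
          pixels = enh$pixels[ry, rx, drop = FALSE],
          set = s, block_row = br, block_col = bc,
          origin = c(x = ox, y = oy),
          col_step = col_step, row_step = row_step,
          crop = c(x = rx[1], y = ry[1]),
          pixel_pitch = pp)
      }
    }
  }
  blocks
}

# detect candidate spot objects in a block: round features of the expected
# size at the bright (96th pct) and weak (85th pct) thresholds; objects found
# only at the weak threshold are classified weak (weight 1 vs 3)
detect_block_objects <- function(block, layout) {
  px <- block$pixels
  pp <- block$pixel_pitch
  r_px <- (layout$spot_diameter / 2) / pp
  amin <- pi * (r_px / 2)^2
  amax <- pi * (2 * r_px)^2
  if (max(px) < 1e-8) {   # featureless block: nothing above numeric noise
    return(tibble::tibble(label = integer(), area = integer(),
                          cx = numeric(), cy = numeric(), aspect = numeric()))
  }
  # percentile thresholds assume a mostly populated block; the MAD floor
  # keeps pure-noise responses from spawning objects in sparse blocks
  noise_floor <- 6 * stats::mad(px)
  thr_b <- max(stats::quantile(px, 0.96), noise_floor)
  thr_w <- max(stats::quantile(px, 0.85), noise_floor)
  obj <- mask_objects(px > thr_w)
  obj <- obj[obj$area >= amin & obj$area <= amax & obj$aspect < 1.6, ,
             drop = FALSE]
  if (nrow(obj) == 0) return(obj)
  obj$bright <- vapply(seq_len(nrow(obj)), function(i) {
    px[round(obj$cy[i]), round(obj$cx[i])] > thr_b
  }, logical(1))
  obj$weight <- ifelse(obj$bright, 3, 1)
  obj
}

# score candidate grid placements (vectors ox, oy of node-(0,0) positions):
# sum of object weights whose centroid falls within `tol_px` of the nearest
# grid node (nearest node by rounding, clamped to the block)
grid_score <- function(obj, ox, oy, step_x, step_y, n, tol_px) {
  cy <- outer(oy, obj$cy, function(o, c) c - o)   # candidates x objects
  cx <- outer(ox, obj$cx, function(o, c) c - o)
  i <- pmin(pmax(round(cy / step_y), 0), n - 1)
  j <- pmin(pmax(round(cx / step_x), 0), n - 1)
  d2 <- (cy - i * step_y)^2 + (cx - j * step_x)^2
  hit <- d2 <= tol_px^2
  # tiny distance penalty breaks ties between placements catching the same
  # objects, preferring the best-centred one
  as.numeric(hit %*% obj$weight) - 1e-6 * as.numeric((d2 * hit) %*% obj$weight)
}

#' Fit the ideal spot grid to one pin block
#'
#' Detects round objects of the expected spot size in the enhanced block
#' subimage (96th-percentile threshold for bright spots, 85th for weak;
#' non-round and wrong-size objects discarded as artifacts) and positions an
#' ideal `block_size` x `block_size` grid by maximizing the summed weight of
#' objects whose centroid lies within 125 um of a grid node, bright spots
#' weighted 3x stronger than weak ones. The search covers translations up to
#' one pitch (0.25 px resolution) and pitch scalings of +/-5%. A block with
#' no detected objects falls back to the nominal grid with a warning.
#'
#' @param block One element of [locate_blocks()].
#' @param layout The [array_layout()].
#' @return A tibble of the block's spot centres: 0-based `row`, `col` within
#'   the block and `x_px`, `y_px` in full-image pixel coordinates.
#' @export
fit_grid <- function(block, layout) {
  bs <- layout$block_size
  pp <- block$pixel_pitch
  tol_px <- (layout$spot_diameter / 2) / pp
  obj <- detect_block_objects(block, layout)
  # nominal node (0,0) in block-local pixels: half a step from the corner
  ox0 <- block$origin[["x"]] - block$crop[["x"]] + 1 + block$col_step / 2
  oy0 <- block$origin[["y"]] - block$crop[["y"]] + 1 + block$row_step / 2
  if (nrow(obj) == 0) {
    warning("no objects detected in block; using nominal grid",
            call. = FALSE)
    best <- list(ox = ox0, oy = oy0, s = 1)
  } else {
    step <- block$col_step
    coarse <- expand.grid(dx = seq(-step, step, by = 0.5),
                          dy = seq(-step, step, by = 0.5))
    sc <- grid_score(obj, ox0 + coarse$dx, oy0 + coarse$dy,
                     block$col_step, block$row_step, bs, tol_px)
    # whole-pitch translations tie in hit weight (same nodes hit,
    # re-indexed); among placements within the centring-penalty scale of the
    # optimum, prefer the one closest to the nominal grid
    b <- which(sc >= max(sc) - 0.01)
    b <- b[order(coarse$dx[b]^2 + coarse$dy[b]^2, -sc[b])][1]
    # the pitch scale is only identifiable with several anchoring objects
    scales <- if (nrow(obj) >= 4) seq(0.95, 1.05, by = 0.025) else 1
    fine <- expand.grid(
      dx = coarse$dx[b] + seq(-0.5, 0.5, by = 0.25),
      dy = coarse$dy[b] + seq(-0.5, 0.5, by = 0.25),
      s = scales)
    scf <- unlist(lapply(split(fine, fine$s), function(fs)
      grid_score(obj, ox0 + fs$dx, oy0 + fs$dy, fs$s[1] * block$col_step,
                 fs$s[1] * block$row_step, bs, tol_px)))
    fine_o <- fine[order(fine$s), ]
    bf <- which(scf >= max(scf) - 0.01)
    bf <- bf[order(abs(fine_o$s[bf] - 1),
                   fine_o$dx[bf]^2 + fine_o$dy[bf]^2, -scf[bf])][1]
    best <- list(ox = ox0 + fine_o$dx[bf], oy = oy0 + fine_o$dy[bf],
                 s = fine_o$s[bf])
  }
  grid <- tidyr::expand_grid(row = seq_len(bs) - 1L, col = seq_len(bs) - 1L)
  dplyr::mutate(
    grid,
    x_px = best$ox + .data$col * best$s * block$col_step +
      block$crop[["x"]] - 1,
    y_px = best$oy + .data$row * best$s * block$row_step +
      block$crop[["y"]] - 1)
}
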