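#' Replicate deviations within one slide
#'
#' Each log2 net spot intensity is compared with its replicate counterparts on
#' the other sets: `dev1` is the difference against the first other set (by
#' ascending set index), `dev2` against the second, and so on. Deviations are
#' only defined between reliable (unflagged, non-missing) spots; otherwise
#' they are `NA`.
#'
#' @param tab A single-slide spot table.
#' @param layout The slide's [array_layout()].
#' @return A tibble with `set`, `row`, `col`, `substrate_id` and one `dev<k>`
#'   column per replicate counterpart.
#' @export
replicate_deviations <- function(tab, layout) {
  assert_spot_table(tab)
  m <- spot_matrices(tab, layout)
  use <- usable_mask(m)
  ns <- layout$n_sets
  out <- dplyr::arrange(
    dplyr::select(tab, "set", "row", "col", "substrate_id"),
    .data$set, .data$substrate_id)
  if (ns < 2L) return(out)
  devs <- vector("list", ns)
  for (j in seq_len(ns)) {
    others <- setdiff(seq_len(ns), j)
    dj <- sapply(others, function(o) {
      d <- m$vals[, j] - m$vals[, o]
      d[!(use[, j] & use[, o])] <- NA_real_
      d
    })
    devs[[j]] <- dj
  }
  for (k in seq_len(ns - 1L)) {
    out[[paste0("dev", k)]] <-
      unlist(lapply(seq_len(ns), function(j) devs[[j]][, k]))
  }
  out
}

# local gradient medians for every (set, substrate) cell; returns one matrix
# per deviation column, n_substrates x n_sets. Eligible neighbours are
# unflagged spots whose deviation against the same counterpart set is
# defined; the query spot's own deviation is excluded.
local_gradient_matrices <- function(tab, layout, n_neighbors = 20) {
  m <- spot_matrices(tab, layout)
  use <- usable_mask(m)
  ns <- layout$n_sets
  geom <- set_geometry(layout)
  n <- geom$n
  grads <- replicate(ns - 1L, matrix(NA_real_, n, ns), simplify = FALSE)
  starved <- 0L
  for (j in seq_len(ns)) {
    others <- setdiff(seq_len(ns), j)
    for (k in seq_along(others)) {
      o <- others[k]
      dev <- m$vals[, j] - m$vals[, o]
      ok <- use[, j] & use[, o]
      dev[!ok] <- NA_real_
      for (p in seq_len(n)) {
        idx <- nearest_idx(geom, p, ok, n_neighbors, warn = FALSE)
        if (length(idx) == 0L) {
          starved <- starved + 1L
          grads[[k]][p, j] <- 0
        } else {
          grads[[k]][p, j] <- stats::median(dev[idx])
        }
      }
    }
  }
  if (starved > 0L) {
    warning(sprintf(
      "%d spot(s) had no eligible neighbour; their gradient was set to 0",
      starved), call. = FALSE)
  }
  grads
}

#' Local gradient of one spot
#'
#' The gradient against each counterpart set is the median deviation of the
#' nearest unflagged spots (default 20, radius grown in pitch steps; see
#' [nearest_spots()]), the spot's own deviation excluded.
#'
#' @inheritParams replicate_deviations
#' @param set,row,col 0-based address of the query spot.
#' @param n_neighbors Minimum neighbour count used for the local median.
#' @return A named numeric vector `gradient1`, `gradient2`, ... (one entry per
#'   counterpart set).
#' @export
local_gradient <- function(tab, set, row, col, layout, n_neighbors = 20) {
  grads <- local_gradient_matrices(tab, layout, n_neighbors)
  p <- as.integer(row) * layout$set_cols + as.integer(col) + 1L
  out <- vapply(grads, function(g) g[p, set + 1L], numeric(1))
  names(out) <- paste0("gradient", seq_along(grads))
  out
}

#' Correct intraslide intensity gradients using the replicate sets
#'
#' Spatial intensity gradients over a slide (uneven sample loading, peptide
#' deposition) are detected by comparing each spot with its replicate
#' counterparts on the other sets and estimating, per spot, a local gradient
#' as the median replicate deviation over its nearest unflagged neighbours.
#' The applied correction is the mean of the per-counterpart gradients
#' divided by the number of sets (for triplicates:
#' `(gradient1 + gradient2) / 3`), which equalizes a uniform per-set offset
#' exactly. The correction is subtracted from the observed log2 value;
#' flagged spots pass through uncorrected.
#'
#' @inheritParams replicate_deviations
#' @param n_neighbors Minimum neighbour count for the local medians
#'   (default 20).
#' @return The corrected spot table, with `gradient<k>` and `correction`
#'   columns appended (the correction map).
#' @export
#' @examples
#' layout <- array_layout(set_rows = 8, set_cols = 8)
#' tab <- new_spot_table(layout)
#' tab$net_log2 <- 10 + 0.5 * (tab$set == 2)   # set 3 shifted up
#' corr <- gradient_correct(tab, layout)
#' range(corr$net_log2)                        # all sets equalized
gradient_correct <- function(tab, layout, n_neighbors = 20) {
  assert_spot_table(tab)
  ns <- layout$n_sets
  ord <- order(tab$set, tab$substrate_id)
  tab_s <- tab[ord, ]
  if (ns < 2L) {
    tab_s$correction <- 0
    return(tab_s)
  }
  grads <- local_gradient_matrices(tab_s, layout, n_neighbors)
  cell <- cbind(tab_s$substrate_id, tab_s$set + 1L)
  gsum <- 0
  for (k in seq_along(grads)) {
    gk <- grads[[k]][cell]
    tab_s[[paste0("gradient", k)]] <- gk
    gsum <- gsum + gk
  }
  tab_s$correction <- gsum / ns
  apply_to <- tab_s$overall == 0L & !is.na(tab_s$net_log2)
  tab_s$net_log2[apply_to] <-
    tab_s$net_log2[apply_to] - tab_s$correction[apply_to]
  tab_s
}
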