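#' Define a peptide-array layout
#'
#' A slide carries `n_sets` identical replicate sets of `set_rows` x `set_cols`
#' spots, stacked vertically, so the full logical grid is
#' `(n_sets * set_rows) x set_cols`. Each set is printed in square pin blocks
#' of `block_size` x `block_size` spots. The default corresponds to a
#' 1024-substrate chip spotted in triplicate: 3 sets of 32 x 32 spots at a
#' 560 micrometre pitch with 250 micrometre spots.
#'
#' @param n_sets Number of replicate sets (>= 1).
#' @param set_rows,set_cols Rows and columns per set; each must be divisible
#'   by `block_size`.
#' @param block_size Spots per pin-block edge.
#' @param spot_pitch Centre-to-centre spot distance in micrometres.
#' @param spot_diameter Nominal spot diameter in micrometres
#'   (must be smaller than the pitch).
#' @return An object of class `array_layout`.
#' @export
#' @examples
#' layout <- array_layout()
#' layout
array_layout <- function(n_sets = 3L, set_rows = 32L, set_cols = 32L,
                         block_size = 8L, spot_pitch = 560,
                         spot_diameter = 250) {
  n_sets <- as.integer(n_sets)
  set_rows <- as.integer(set_rows)
  set_cols <- as.integer(set_cols)
  block_size <- as.integer(block_size)
  if (n_sets < 1L) stop("`n_sets` must be >= 1", call. = FALSE)
  if (set_rows %% block_size != 0L || set_cols %% block_size != 0L) {
    stop("`set_rows` and `set_cols` must be divisible by `block_size`",
         call. = FALSE)
  }
  if (spot_pitch <= spot_diameter) {
    stop("`spot_pitch` must exceed `spot_diameter`", call. = FALSE)
  }
  structure(
    list(n_sets = n_sets, set_rows = set_rows, set_cols = set_cols,
         block_size = block_size, spot_pitch = spot_pitch,
         spot_diameter = spot_diameter),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf(
    "<array_layout> %d set(s) of %d x %d spots (pin blocks %d x %d)\n",
    x$n_sets, x$set_rows, x$set_cols, x$block_size, x$block_size))
  cat(sprintf("  pitch %g um, spot diameter %g um, full grid %d x %d\n",
              x$spot_pitch, x$spot_diameter,
              x$n_sets * x$set_rows, x$set_cols))
  invisible(x)
}

n_substrates <- function(layout) layout$set_rows * layout$set_cols

#' Enumerate all spot positions of a layout
#'
#' Returns one row per grid position of every set, with 0-based `set`, `row`,
#' `col` indices, the 1-based `substrate_id` shared by the replicate sets, and
#' physical centre coordinates in micrometres. The physical origin is the
#' top-left spot centre; x grows with columns, y with rows (sets stacked in y).
#'
#' @param layout An [array_layout()].
#' @return A tibble with columns `set`, `row`, `col`, `substrate_id`,
#'   `x_um`, `y_um`.
#' @export
spot_positions <- function(layout) {
  stopifnot(inherits(layout, "array_layout"))
  grid <- tidyr::expand_grid(
    set = seq_len(layout$n_sets) - 1L,
    row = seq_len(layout$set_rows) - 1L,
    col = seq_len(layout$set_cols) - 1L
  )
  dplyr::mutate(
    grid,
    substrate_id = .data$row * layout$set_cols + .data$col + 1L,
    x_um = .data$col * layout$spot_pitch,
    y_um = (.data$set * layout$set_rows + .data$row) * layout$spot_pitch
  )
}

#' Replicate counterparts of a spot address
#'
#' Every substrate is spotted once per set at the same within-set (row, col),
#' so a spot has `n_sets - 1` replicate counterparts on the other sets.
#'
#' @param set,row,col 0-based spot address.
#' @param layout An [array_layout()].
#' @return A tibble of the counterpart addresses (possibly zero rows),
#'   ordered by set index.
#' @export
#' @examples
#' replicate_addresses(0, 5, 7, array_layout())
replicate_addresses <- function(set, row, col, layout) {
  stopifnot(inherits(layout, "array_layout"))
  set <- as.integer(set); row <- as.integer(row); col <- as.integer(col)
  if (set < 0L || set >= layout$n_sets ||
      row < 0L || row >= layout$set_rows ||
      col < 0L || col >= layout$set_cols) {
    stop(sprintf("invalid spot address (set %d, row %d, col %d)",
                 set, row, col), call. = FALSE)
  }
  others <- setdiff(seq_len(layout$n_sets) - 1L, set)
  tibble::tibble(
    set = others, row = row, col = col,
    substrate_id = row * layout$set_cols + col + 1L
  )
}

# ---- within-set distance machinery ------------------------------------------
# All sets share one within-set geometry; distances between nominal grid
# centres depend only on (row, col). The sorted-neighbour tables are cached
# per (set_rows, set_cols, spot_pitch).

.kinorm_geom_cache <- new.env(parent = emptyenv())

set_geometry <- function(layout) {
  key <- paste(layout$set_rows, layout$set_cols, layout$spot_pitch, sep = "|")
  g <- .kinorm_geom_cache[[key]]
  if (!is.null(g)) return(g)
  n <- n_substrates(layout)
  idx <- seq_len(n) - 1L
  row <- idx %/% layout$set_cols
  col <- idx %% layout$set_cols
  x <- col * layout$spot_pitch
  y <- row * layout$spot_pitch
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  ord <- apply(d, 2L, order)                   # ord[, p]: indices by distance
  dsort <- matrix(d[cbind(as.vector(ord), rep(seq_len(n), each = n))], n, n)
  g <- list(n = n, row = row, col = col, x = x, y = y,
            ord = ord, dsort = dsort, pitch = layout$spot_pitch)
  .kinorm_geom_cache[[key]] <- g
  g
}

# Indices (1-based substrate position) of the neighbours of position `p`
# selected by stepwise radius expansion: the search radius grows in steps of
# one spot pitch until at least `n` eligible spots are inside, and all
# eligible spots within the final radius are returned, ordered by distance
# (ties at equal distance kept in index order). `include_self` controls
# whether position p itself may be part of the result (it is excluded for
# intra-array gradients, included for interarray local medians).
nearest_idx <- function(geom, p, eligible, n, include_self = FALSE,
                        warn = TRUE) {
  o <- geom$ord[, p]
  ds <- geom$dsort[, p]
  if (!include_self) {
    keep_pos <- o != p
    o <- o[keep_pos]
    ds <- ds[keep_pos]
  }
  el <- eligible[o]
  cum <- cumsum(el)
  total <- cum[length(cum)]
  if (is.na(total)) total <- 0L
  if (total < n) {
    if (warn) {
      warning(sprintf(
        "only %d eligible spot(s) available for a %d-nearest query", total, n),
        call. = FALSE)
    }
    return(o[el])
  }
  i_n <- which(cum >= n)[1L]
  k <- max(1, ceiling(ds[i_n] / geom$pitch - 1e-9))
  r <- k * geom$pitch + 1e-6
  o[el & ds <= r]
}

#' Nearest eligible spots of a query spot
#'
#' Finds neighbouring spots of a query address within its own replicate set,
#' by growing a circle around the query centre in steps of one spot pitch
#' until it holds at least `n` eligible spots; all eligible spots inside the
#' final circle are returned (ties at the boundary included), ordered by
#' distance. The query spot itself is excluded. If the whole set holds fewer
#' than `n` eligible spots, all of them are returned with a warning.
#'
#' @param spots A spot table (see [read_spot_table()]) or any tibble with
#'   `set`, `row`, `col` columns for a single slide.
#' @param set,row,col 0-based address of the query spot.
#' @param layout The [array_layout()] of the slide.
#' @param n Minimum number of neighbours (default 20).
#' @param eligible Optional logical vector along `spots` marking spots usable
#'   as neighbours (default: all). Spots of other sets are never used.
#' @return The eligible neighbouring rows of `spots`, ordered by distance,
#'   with a `distance_um` column appended.
#' @export
nearest_spots <- function(spots, set, row, col, layout, n = 20,
                          eligible = NULL) {
  stopifnot(inherits(layout, "array_layout"), n >= 1)
  geom <- set_geometry(layout)
  if (is.null(eligible)) eligible <- rep(TRUE, nrow(spots))
  stopifnot(length(eligible) == nrow(spots))
  p <- as.integer(row) * layout$set_cols + as.integer(col) + 1L
  if (p < 1L || p > geom$n || set < 0L || set >= layout$n_sets) {
    stop("invalid spot address", call. = FALSE)
  }
  in_set <- spots$set == set
  # map substrate position -> row index of `spots` within this set
  pos <- spots$row[in_set] * layout$set_cols + spots$col[in_set] + 1L
  row_of <- integer(geom$n)
  row_of[pos] <- which(in_set)
  el <- rep(FALSE, geom$n)
  el[pos] <- eligible[in_set]
  idx <- nearest_idx(geom, p, el, n)
  out <- spots[row_of[idx], , drop = FALSE]
  d <- sqrt((geom$x[idx] - geom$x[p])^2 + (geom$y[idx] - geom$y[p])^2)
  out$distance_um <- d
  out
}
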