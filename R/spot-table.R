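#' @importFrom rlang .data
NULL

# the eight per-spot quality flags, in canonical column order
FLAG_COLS <- c("artifact", "overshine", "ks", "no_contrast", "saturated",
               "shape", "position", "overall")

#' Quality-flag column names
#'
#' The eight binary per-spot reliability flags carried by a spot table:
#' `artifact`, `overshine`, `ks`, `no_contrast`, `saturated`, `shape`,
#' `position` and the derived `overall` (1 if any other flag is 1).
#' @return Character vector of flag column names.
#' @export
flag_columns <- function() FLAG_COLS

#' Build an empty (all-reliable) spot table for a layout
#'
#' One record per grid position of every set, with missing intensities and all
#' flags 0. Used as the canvas for simulation and quantification.
#'
#' @param layout An [array_layout()].
#' @param slide_id,condition Identifier columns carried along.
#' @return A spot-table tibble.
#' @export
new_spot_table <- function(layout, slide_id = "slide", condition = NA_character_) {
  tab <- spot_positions(layout)
  tab <- dplyr::mutate(tab,
    slide_id = slide_id, condition = condition, net_log2 = NA_real_,
    .before = 1L)
  for (f in FLAG_COLS) tab[[f]] <- 0L
  tab
}

assert_spot_table <- function(tab) {
  need <- c("slide_id", "condition", "set", "row", "col", "substrate_id",
            "x_um", "y_um", "net_log2", FLAG_COLS)
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("not a spot table; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' Read / write a spot table as TSV
#'
#' The on-disk format has one row per spot and columns `slide_id`,
#' `condition`, `set`, `row`, `col`, `substrate_id`, `x_um`, `y_um`,
#' `net_log2` plus one 0/1 column per quality flag. Missing intensities are
#' written as `NA`.
#'
#' @param path File path.
#' @return `read_spot_table()` returns the spot-table tibble.
#' @export
read_spot_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_spot_table(tab)
  tab$set <- as.integer(tab$set)
  tab$row <- as.integer(tab$row)
  tab$col <- as.integer(tab$col)
  tab$substrate_id <- as.integer(tab$substrate_id)
  for (f in intersect(FLAG_COLS, names(tab))) tab[[f]] <- as.integer(tab[[f]])
  assert_spot_table(tab)
}

#' @param tab A spot-table tibble.
#' @rdname read_spot_table
#' @export
write_spot_table <- function(tab, path) {
  assert_spot_table(tab)
  cols <- c("slide_id", "condition", "set", "row", "col", "substrate_id",
            "x_um", "y_um", "net_log2", FLAG_COLS)
  readr::write_tsv(dplyr::select(tab, dplyr::all_of(cols)), path,
                   progress = FALSE)
  invisible(path)
}

# ---- internal wide helpers ---------------------------------------------------
# Fast paths reshape a single-slide table into substrate x set matrices of
# values and flags; rows indexed by substrate_id 1..n_substrates.

spot_matrices <- function(tab, layout) {
  if (length(unique(tab$slide_id)) > 1L) {
    stop("expected a single-slide spot table; split by `slide_id` first",
         call. = FALSE)
  }
  n <- n_substrates(layout)
  vals <- matrix(NA_real_, n, layout$n_sets)
  flags <- matrix(1L, n, layout$n_sets)
  i <- tab$substrate_id
  j <- tab$set + 1L
  vals[cbind(i, j)] <- tab$net_log2
  flags[cbind(i, j)] <- tab$overall
  list(vals = vals, flags = flags)
}

# usable (unflagged, non-missing) replicate mask
usable_mask <- function(m) m$flags == 0L & !is.na(m$vals)
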