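# Independent brute-force oracles, built straight from the definitions and
# kept free of the package's internal geometry caches.

# nearest-spot search: full distance sort within the query's set, stepwise
# radius growth in pitch units until >= n eligible spots are inside, all
# eligible spots within the final radius returned ordered by distance
bf_nearest <- function(spots, set, row, col, n, layout, eligible = NULL) {
  if (is.null(eligible)) eligible <- rep(TRUE, nrow(spots))
  pitch <- layout$spot_pitch
  same <- spots$set == set & !(spots$row == row & spots$col == col)
  cand <- spots[same & eligible, , drop = FALSE]
  d <- sqrt(((cand$col - col) * pitch)^2 + ((cand$row - row) * pitch)^2)
  o <- order(d)
  cand <- cand[o, , drop = FALSE]
  d <- d[o]
  if (nrow(cand) < n) return(cand)
  k <- ceiling(d[n] / pitch - 1e-9)
  cand[d <= k * pitch + 1e-6, , drop = FALSE]
}

# local median over the brute-force neighbour set
bf_local_median <- function(values, spots, set, row, col, n, layout,
                            eligible, include_self = FALSE) {
  pitch <- layout$spot_pitch
  same <- spots$set == set
  if (!include_self) same <- same & !(spots$row == row & spots$col == col)
  cand <- spots[same & eligible, , drop = FALSE]
  vals <- values[same & eligible]
  d <- sqrt(((cand$col - col) * pitch)^2 + ((cand$row - row) * pitch)^2)
  o <- order(d)
  vals <- vals[o]; d <- d[o]
  if (length(vals) == 0) return(NA_real_)
  if (length(vals) < n) return(median(vals))
  k <- ceiling(d[n] / pitch - 1e-9)
  median(vals[d <= k * pitch + 1e-6])
}

# AUC by exhaustive concordant-pair counting (ties count 1/2)
bf_auc <- function(p, positive) {
  pos <- p[positive]; neg <- p[!positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small spot-table builder with given per-(set, substrate) values
make_table <- function(layout, values = NULL, slide_id = "s",
                       condition = NA_character_) {
  tab <- new_spot_table(layout, slide_id = slide_id, condition = condition)
  if (!is.null(values)) tab$net_log2 <- values
  tab
}

small_layout <- function(n_sets = 3L)
  array_layout(n_sets = n_sets, set_rows = 8L, set_cols = 8L)
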