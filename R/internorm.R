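#' Per-substrate triplicate means of one slide
#'
#' Averages the replicate log2 net intensities of each substrate over its
#' unflagged, non-missing replicates; `NA` when no replicate is usable.
#'
#' @param tab A single-slide spot table.
#' @param layout The slide's [array_layout()].
#' @return A tibble with `substrate_id`, `mean_log2`, `n_usable`.
#' @export
spot_means <- function(tab, layout) {
  assert_spot_table(tab)
  m <- spot_matrices(tab, layout)
  use <- usable_mask(m)
  tibble::tibble(
    substrate_id = seq_len(n_substrates(layout)),
    mean_log2 = row_means_masked(m$vals, use),
    n_usable = as.integer(rowSums(use))
  )
}

# local-median offsets across conditions: for every substrate position p,
# the median of d over the >= n nearest eligible substrates (radius grown in
# pitch steps; the querying substrate itself is included when eligible).
lmc_offsets <- function(d, eligible, geom, n_neighbors) {
  el <- eligible & !is.na(d)
  if (!any(el)) stop("no eligible substrates for local median-centering",
                     call. = FALSE)
  m <- numeric(geom$n)
  for (p in seq_len(geom$n)) {
    idx <- nearest_idx(geom, p, el, n_neighbors, include_self = TRUE,
                       warn = FALSE)
    m[p] <- stats::median(d[idx])
  }
  m
}

#' Local median-centering of a slide pair
#'
#' For each substrate, the between-condition difference of triplicate means
#' `d(s) = mean_B(s) - mean_A(s)` is summarized over the `n_neighbors`
#' nearest eligible substrates (same radius-growth rule as [nearest_spots()],
#' the substrate itself included) by its median `m(s)`, and the pair is
#' shifted symmetrically: slide A gains `+m(s)/2`, slide B `-m(s)/2`, so the
#' local median of `B - A` becomes approximately zero while the pair mean is
#' preserved.
#'
#' @param tab_a,tab_b Spot tables of the two conditions (same layout).
#' @param layout The [array_layout()].
#' @param eligible Logical vector over substrates (length
#'   `set_rows * set_cols`) marking substrates used to estimate the offsets;
#'   default: substrates with a usable mean in both conditions.
#' @param n_neighbors Minimum neighbour count for the local medians.
#' @return A list with the shifted `table_a`, `table_b` and an `offsets`
#'   tibble (`substrate_id`, `offset` = `m(s)`).
#' @export
local_median_center_pair <- function(tab_a, tab_b, layout, eligible = NULL,
                                     n_neighbors = 20) {
  assert_spot_table(tab_a); assert_spot_table(tab_b)
  geom <- set_geometry(layout)
  ma <- spot_means(tab_a, layout)$mean_log2
  mb <- spot_means(tab_b, layout)$mean_log2
  d <- mb - ma
  if (is.null(eligible)) eligible <- !is.na(ma) & !is.na(mb)
  stopifnot(length(eligible) == geom$n)
  m <- lmc_offsets(d, eligible, geom, n_neighbors)
  list(
    table_a = shift_by_substrate(tab_a, m / 2),
    table_b = shift_by_substrate(tab_b, -m / 2),
    offsets = tibble::tibble(substrate_id = seq_len(geom$n), offset = m)
  )
}

shift_by_substrate <- function(tab, shift) {
  ok <- !is.na(tab$net_log2)
  tab$net_log2[ok] <- tab$net_log2[ok] + shift[tab$substrate_id[ok]]
  tab
}

# per-substrate group stats of a pair, used by the t-test battery
pair_stats <- function(tab_a, tab_b, layout) {
  a <- spot_matrices(tab_a, layout); b <- spot_matrices(tab_b, layout)
  ua <- usable_mask(a); ub <- usable_mask(b)
  list(
    mean_a = row_means_masked(a$vals, ua), mean_b = row_means_masked(b$vals, ub),
    var_a = row_vars_masked(a$vals, ua), var_b = row_vars_masked(b$vals, ub),
    n_a = rowSums(ua), n_b = rowSums(ub)
  )
}

#' Substrates significantly affected by the condition
#'
#' Per substrate, a two-sided two-sample Student t-test (pooled variance)
#' compares the unflagged replicate values of the two conditions; substrates
#' with `p < alpha` are reported. Substrates with fewer than two usable
#' replicates in either condition are skipped (treated as unaffected for
#' normalization purposes). The default quasi-stringent `alpha = 0.1`
#' deliberately over-excludes so that the normalization set is enriched for
#' truly unaffected substrates.
#'
#' @inheritParams local_median_center_pair
#' @param alpha Exclusion threshold on the t-test p-value.
#' @return Integer vector of affected `substrate_id`s.
#' @export
detect_affected <- function(tab_a, tab_b, layout, alpha = 0.1) {
  stopifnot(alpha > 0, alpha < 1)
  s <- pair_stats(tab_a, tab_b, layout)
  tt <- pooled_t(s$mean_a, s$mean_b, s$var_a, s$var_b, s$n_a, s$n_b)
  which(!is.na(tt$p.value) & tt$p.value < alpha)
}

#' Repetitive signal enhancement (RSE) interarray normalization
#'
#' Normalizes a control/treatment slide pair by local median-centering on a
#' set of substrates iteratively purged of condition-affected substrates:
#'
#' 1. Local median-centering using all substrates passing QC in both
#'    conditions.
#' 2. Per-substrate quasi-stringent t-testing (default `p < 0.1`) on the
#'    centered replicate values; significant substrates are excluded.
#' 3. Local median-centering on the reduced set.
#'
#' Steps 2 and 3 repeat until the exclusion set stabilizes. At every
#' iteration the centering is rebuilt from the original values with the
#' current set, so substrates excluded early can re-enter later. The
#' converged set is typically enriched for substrates unaffected by the
#' treatment, removing the bias that global median-centering or quantile
#' normalization suffer when intensity distributions differ between
#' conditions.
#'
#' @inheritParams local_median_center_pair
#' @param alpha Exclusion threshold of the per-substrate t-test.
#' @param max_iterations Iteration cap; non-convergence returns the last
#'   state with a warning. A repeating cycle of sets returns the cycle
#'   union's centering with a warning.
#' @return An object of class `rse_result`: normalized `table_a`/`table_b`,
#'   the per-substrate `offsets` tibble, the converged `normalization_set`
#'   and `excluded` substrate ids, `iterations`, per-iteration `set_sizes`
#'   and `converged`. See [tidy.rse_result()] and [glance.rse_result()].
#' @export
rse_normalize <- function(tab_a, tab_b, layout, n_neighbors = 20,
                          alpha = 0.1, max_iterations = 50) {
  assert_spot_table(tab_a); assert_spot_table(tab_b)
  stopifnot(alpha > 0, alpha < 1, n_neighbors >= 1)
  geom <- set_geometry(layout)
  s <- pair_stats(tab_a, tab_b, layout)
  d <- s$mean_b - s$mean_a
  eligible0 <- !is.na(s$mean_a) & !is.na(s$mean_b)
  if (!any(eligible0)) stop("no QC-passing substrates in both conditions",
                            call. = FALSE)
  # within-group variances are invariant under per-substrate centering, so
  # only the mean difference d - m changes across iterations
  se <- sqrt((((s$n_a - 1) * s$var_a + (s$n_b - 1) * s$var_b) /
                (s$n_a + s$n_b - 2)) * (1 / s$n_a + 1 / s$n_b))
  df <- s$n_a + s$n_b - 2
  testable <- eligible0 & s$n_a >= 2 & s$n_b >= 2 & !is.na(se)

  current <- eligible0
  seen <- character()
  sizes <- integer()
  stabilized_by <- "max_iterations"
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    m <- lmc_offsets(d, current, geom, n_neighbors)
    diff_c <- d - m
    p <- rep(NA_real_, geom$n)
    nz <- testable & se > 0
    p[nz] <- 2 * stats::pt(-abs(diff_c[nz] / se[nz]), df[nz])
    z0 <- testable & se == 0
    p[z0] <- ifelse(diff_c[z0] == 0, 1, 0)
    affected <- testable & !is.na(p) & p < alpha
    new_set <- eligible0 & !affected
    sizes <- c(sizes, sum(new_set))
    if (identical(new_set, current)) { stabilized_by <- "fixed_point"; break }
    key <- paste(which(new_set), collapse = ",")
    if (key %in% seen) {
      warning("RSE entered a cycle of normalization sets; ",
              "using the cycle union", call. = FALSE)
      new_set <- new_set | current
      current <- new_set
      stabilized_by <- "cycle"
      break
    }
    seen <- c(seen, key)
    current <- new_set
    if (iterations >= max_iterations) {
      warning(sprintf("RSE did not converge within %d iterations",
                      max_iterations), call. = FALSE)
      break
    }
  }

  m <- lmc_offsets(d, current, geom, n_neighbors)
  out <- list(
    table_a = shift_by_substrate(tab_a, m / 2),
    table_b = shift_by_substrate(tab_b, -m / 2),
    offsets = tibble::tibble(
      substrate_id = seq_len(geom$n), offset = m,
      eligible = eligible0, in_set = current,
      excluded = eligible0 & !current),
    normalization_set = which(current),
    excluded = which(eligible0 & !current),
    n_eligible = sum(eligible0),
    iterations = iterations,
    set_sizes = sizes,
    converged = stabilized_by != "max_iterations",
    stabilized_by = stabilized_by,
    params = list(n_neighbors = n_neighbors, alpha = alpha,
                  max_iterations = max_iterations)
  )
  class(out) <- "rse_result"
  out
}

#' @export
print.rse_result <- function(x, ...) {
  cat(sprintf(
    "<rse_result> %s after %d iteration(s)\n",
    if (x$converged) "converged" else "stopped", x$iterations))
  cat(sprintf("  normalization set: %d substrate(s) (%.1f%% of %d eligible)\n",
              length(x$normalization_set),
              100 * length(x$normalization_set) / x$n_eligible,
              x$n_eligible))
  cat(sprintf("  excluded as affected: %d; median offset %.3f log2\n",
              length(x$excluded),
              stats::median(x$offsets$offset[x$offsets$eligible])))
  invisible(x)
}

#' Global median-centering of slides
#'
#' Baseline normalizer: each slide's median log2 net intensity (over all
#' spots, quality flags ignored) is shifted to the common level (the median
#' of the per-slide medians).
#'
#' @param tables List of spot tables.
#' @return List of centered spot tables.
#' @export
median_center <- function(tables) {
  stopifnot(length(tables) >= 2)
  meds <- vapply(tables, function(t) stats::median(t$net_log2, na.rm = TRUE),
                 numeric(1))
  grand <- stats::median(meds)
  purrr::map2(tables, meds, function(t, m) {
    t$net_log2 <- t$net_log2 - m + grand
    t
  })
}

#' Quantile normalization of slides
#'
#' Baseline normalizer: spot intensities of each slide are replaced by the
#' across-slide mean of the order statistics of their rank, forcing identical
#' intensity distributions. Spots missing in any slide are excluded from the
#' quantile estimation and left unnormalized; ties receive the mean of their
#' tied quantile values.
#'
#' @param tables List of spot tables with identical layouts (same spot count
#'   and order by `set`, `row`, `col`).
#' @return List of normalized spot tables.
#' @export
quantile_normalize <- function(tables) {
  stopifnot(length(tables) >= 2)
  tables <- lapply(tables, function(t) t[order(t$set, t$row, t$col), ])
  x <- vapply(tables, function(t) t$net_log2, numeric(nrow(tables[[1]])))
  complete <- stats::complete.cases(x)
  xs <- x[complete, , drop = FALSE]
  target <- rowMeans(apply(xs, 2L, sort))
  xn <- apply(xs, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    (target[floor(r)] + target[ceiling(r)]) / 2
  })
  for (j in seq_along(tables)) {
    v <- tables[[j]]$net_log2
    v[complete] <- xn[, j]
    tables[[j]]$net_log2 <- v
  }
  tables
}

#' Normalize a slide pair by a named method
#'
#' Convenience dispatcher over [rse_normalize()], [median_center()],
#' [quantile_normalize()] or no normalization (`"raw"`).
#'
#' @inheritParams local_median_center_pair
#' @param method One of `"rse"`, `"median"`, `"quantile"`, `"raw"`.
#' @param ... Passed to [rse_normalize()] for `method = "rse"`.
#' @return A list with `table_a` and `table_b`; for `"rse"`, also the full
#'   `rse` result object.
#' @export
normalize_pair <- function(tab_a, tab_b, layout,
                           method = c("rse", "median", "quantile", "raw"),
                           ...) {
  method <- match.arg(method)
  switch(method,
    rse = {
      r <- rse_normalize(tab_a, tab_b, layout, ...)
      list(table_a = r$table_a, table_b = r$table_b, rse = r)
    },
    median = {
      ts <- median_center(list(tab_a, tab_b))
      list(table_a = ts[[1]], table_b = ts[[2]])
    },
    quantile = {
      ts <- quantile_normalize(list(tab_a, tab_b))
      list(table_a = ts[[1]], table_b = ts[[2]])
    },
    raw = list(table_a = tab_a, table_b = tab_b)
  )
}
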