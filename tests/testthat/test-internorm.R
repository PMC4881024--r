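test_that("spot means average only usable replicates", {
  layout <- small_layout()
  tab <- new_spot_table(layout)
  tab$net_log2[tab$substrate_id == 1] <- c(8, 9, 10)
  tab$net_log2[tab$substrate_id == 2] <- c(8, 5, 10)
  tab$overall[tab$substrate_id == 2 & tab$set == 1] <- 1L
  tab$overall[tab$substrate_id == 3] <- 1L
  tab$net_log2[tab$substrate_id == 3] <- c(1, 2, 3)
  m <- spot_means(tab, layout)
  expect_equal(m$mean_log2[1], 9)
  expect_equal(m$mean_log2[2], 9)       # flagged middle replicate dropped
  expect_true(is.na(m$mean_log2[3]))    # all replicates flagged
  expect_equal(m$n_usable[1:3], c(3L, 2L, 0L))
})

test_that("local median-centering removes a constant shift symmetrically", {
  layout <- small_layout()
  set.seed(5)
  vals <- rnorm(64, 10, 1.5)[new_spot_table(layout)$substrate_id]
  a <- make_table(layout, vals, condition = "control")
  b <- make_table(layout, vals + 1.2, condition = "treatment")
  out <- local_median_center_pair(a, b, layout)
  expect_equal(out$offsets$offset, rep(1.2, 64))
  expect_equal(out$table_a$net_log2, vals + 0.6)
  expect_equal(out$table_b$net_log2, vals + 1.2 - 0.6)

  # identical tables: zero offsets, unchanged
  out2 <- local_median_center_pair(a, a, layout)
  expect_equal(out2$offsets$offset, rep(0, 64))
  expect_equal(out2$table_a$net_log2, vals)
})

test_that("local median-centering offsets match the brute-force oracle", {
  layout <- small_layout()
  set.seed(6)
  base <- new_spot_table(layout)
  a <- make_table(layout, rnorm(nrow(base), 10, 1))
  b <- make_table(layout, rnorm(nrow(base), 10.5, 1))
  b$overall[sample(nrow(base), 15)] <- 1L
  out <- local_median_center_pair(a, b, layout, n_neighbors = 5)
  ma <- spot_means(a, layout)$mean_log2
  mb <- spot_means(b, layout)$mean_log2
  d <- mb - ma
  eligible <- !is.na(ma) & !is.na(mb)
  # substrate locations live on a single 8x8 grid (set 0 as reference)
  pos <- base[base$set == 0, ]
  for (id in sample(64, 12)) {
    want <- bf_local_median(d[pos$substrate_id], pos, 0,
                            pos$row[pos$substrate_id == id],
                            pos$col[pos$substrate_id == id],
                            5, layout, eligible[pos$substrate_id],
                            include_self = TRUE)
    expect_equal(out$offsets$offset[id], want)
  }
})

test_that("detect_affected applies the pooled t-test at the threshold", {
  layout <- small_layout()
  a <- new_spot_table(layout); b <- new_spot_table(layout)
  a$net_log2 <- 10
  b$net_log2 <- 10
  # substrate 5: clearly shifted triplicates
  a$net_log2[a$substrate_id == 5] <- c(10.0, 10.1, 9.9)
  b$net_log2[b$substrate_id == 5] <- c(12.0, 12.1, 11.9)
  aff <- detect_affected(a, b, layout, alpha = 0.1)
  expect_true(5 %in% aff)
  # identical triplicates are never affected
  expect_false(1 %in% aff)

  # agreement with stats::t.test on random data
  set.seed(8)
  a$net_log2 <- rnorm(nrow(a), 10, 0.5)
  b$net_log2 <- rnorm(nrow(b), 10, 0.5)
  aff <- detect_affected(a, b, layout, alpha = 0.1)
  ps <- vapply(seq_len(64), function(id) {
    stats::t.test(b$net_log2[b$substrate_id == id],
                  a$net_log2[a$substrate_id == id],
                  var.equal = TRUE)$p.value
  }, numeric(1))
  expect_setequal(aff, which(ps < 0.1))
})

test_that("spot_tests matches the closed-form t statistic and t.test", {
  layout <- small_layout()
  a <- new_spot_table(layout); b <- new_spot_table(layout)
  set.seed(9)
  a$net_log2 <- rnorm(nrow(a), 10, 0.5)
  b$net_log2 <- rnorm(nrow(b), 10.3, 0.5)
  tests <- spot_tests(a, b, layout)
  for (id in sample(64, 10)) {
    tt <- stats::t.test(b$net_log2[b$substrate_id == id],
                        a$net_log2[a$substrate_id == id], var.equal = TRUE)
    expect_equal(tests$p.value[id], tt$p.value)
    expect_equal(tests$statistic[id], unname(tt$statistic))
  }
  # hand formula on a fixed triplet: mean diff 2.0, pooled sd 0.1
  x <- c(10.0, 10.1, 9.9); y <- c(12.0, 12.1, 11.9)
  tstat <- (mean(y) - mean(x)) / (0.1 * sqrt(2 / 3))
  a$net_log2[a$substrate_id == 1] <- x
  b$net_log2[b$substrate_id == 1] <- y
  tests <- spot_tests(a, b, layout)
  expect_equal(tests$statistic[1], tstat, tolerance = 1e-10)
  # identical triplicates both sides: zero variance, zero diff -> p = 1
  a$net_log2[a$substrate_id == 2] <- c(10, 10, 10)
  b$net_log2[b$substrate_id == 2] <- c(10, 10, 10)
  expect_equal(spot_tests(a, b, layout)$p.value[2], 1)
})

test_that("median centering aligns slide medians at the grand median", {
  layout <- small_layout()
  a <- make_table(layout, rnorm(192, 9, 0.1))
  b <- make_table(layout, rnorm(192, 11, 0.1))
  out <- median_center(list(a, b))
  m1 <- median(out[[1]]$net_log2); m2 <- median(out[[2]]$net_log2)
  expect_equal(m1, m2)
  grand <- median(c(median(a$net_log2), median(b$net_log2)))
  expect_equal(m1, grand)
  # single constant pair is unchanged
  cc <- make_table(layout, rep(7, 192))
  out2 <- median_center(list(cc, cc))
  expect_equal(out2[[1]]$net_log2, cc$net_log2)
})

test_that("quantile normalization equals the order-statistic mean contract", {
  layout <- array_layout(n_sets = 1, set_rows = 8, set_cols = 8)
  # tiny hand case embedded in the first three spots, rest NA
  a <- new_spot_table(layout); b <- new_spot_table(layout)
  a$net_log2[1:3] <- c(1, 2, 3)
  b$net_log2[1:3] <- c(4, 5, 6)
  out <- quantile_normalize(list(a, b))
  expect_equal(out[[1]]$net_log2[1:3], c(2.5, 3.5, 4.5))
  expect_equal(out[[2]]$net_log2[1:3], c(2.5, 3.5, 4.5))

  # identical tables unchanged
  set.seed(10)
  v <- rnorm(64, 10, 1)
  t1 <- make_table(layout, v)
  out2 <- quantile_normalize(list(t1, t1))
  expect_equal(out2[[1]]$net_log2, v)

  # random tables match limma's reference implementation
  x <- matrix(rnorm(64 * 3, 10, 1.5), 64, 3)
  tabs <- lapply(1:3, function(j) make_table(layout, x[, j]))
  out3 <- quantile_normalize(tabs)
  ref <- limma::normalizeQuantiles(x, ties = TRUE)
  for (j in 1:3) expect_equal(out3[[j]]$net_log2, ref[, j])
})

test_that("RSE converges immediately on identical slides", {
  layout <- small_layout()
  set.seed(12)
  vals <- rnorm(64, 10, 1.5)[new_spot_table(layout)$substrate_id] +
    rnorm(192, 0, 0.4)
  a <- make_table(layout, vals)
  r <- rse_normalize(a, a, layout)
  expect_equal(r$iterations, 1L)
  expect_true(r$converged)
  expect_equal(r$normalization_set, 1:64)
  expect_equal(r$offsets$offset, rep(0, 64))
  expect_equal(r$table_a$net_log2, vals)
})

test_that("RSE recovers a pure array effect and respects its exclusion rate", {
  cfg <- sim_config(n_patients = 1, n_induced = 0, use_gradients = FALSE)
  ex <- simulate_experiment(cfg, seed = 21)
  a <- experiment_slide(ex, 1, "control")
  b <- experiment_slide(ex, 1, "treatment")
  truth <- diff(ex$array_effects$array_effect)  # B - A
  r <- rse_normalize(a, b, cfg$layout)
  est <- median(r$offsets$offset)
  expect_equal(est, truth, tolerance = 0.05)
  # ~ alpha of null substrates excluded
  expect_lt(length(r$excluded) / 1024, 0.2)
  # no member of the converged set tests significant in the final iteration
  p_final <- spot_tests(r$table_a, r$table_b, cfg$layout)$p.value
  expect_true(all(p_final[r$normalization_set] >= 0.1))
})

test_that("RSE is symmetric under swapping the two slides", {
  layout <- small_layout()
  cfg <- sim_config(n_patients = 1, n_induced = 6, layout = layout,
                    use_gradients = FALSE)
  ex <- simulate_experiment(cfg, seed = 33)
  a <- experiment_slide(ex, 1, "control")
  b <- experiment_slide(ex, 1, "treatment")
  r1 <- rse_normalize(a, b, layout)
  r2 <- rse_normalize(b, a, layout)
  expect_equal(r1$offsets$offset, -r2$offsets$offset)
  expect_equal(r1$normalization_set, r2$normalization_set)
})

test_that("RSE centering leaves induced effects detectable", {
  # treatment raises 12 of 64 substrates; offsets should track the array
  # effect, not the induction
  layout <- small_layout()
  cfg <- sim_config(n_patients = 1, n_induced = 12, layout = layout,
                    effect_size = 1.5, use_gradients = FALSE)
  ex <- simulate_experiment(cfg, seed = 44)
  a <- experiment_slide(ex, 1, "control")
  b <- experiment_slide(ex, 1, "treatment")
  r <- rse_normalize(a, b, layout)
  truth <- diff(ex$array_effects$array_effect)
  est <- median(r$offsets$offset[!ex$truth$induced])
  expect_equal(est, truth, tolerance = 0.25)
  tests <- spot_tests(r$table_a, r$table_b, layout)
  ev <- classify_and_roc(tests, ex$truth)
  expect_gt(ev$auc, 0.8)
})

test_that("normalize_pair dispatches and rejects unknown methods", {
  layout <- small_layout()
  a <- make_table(layout, rnorm(192, 10, 1))
  b <- make_table(layout, rnorm(192, 10, 1))
  raw <- normalize_pair(a, b, layout, method = "raw")
  expect_equal(raw$table_a$net_log2, a$net_log2)
  rse <- normalize_pair(a, b, layout, method = "rse")
  expect_s3_class(rse$rse, "rse_result")
  expect_error(normalize_pair(a, b, layout, method = "bogus"))
})
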