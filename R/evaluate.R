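#' Per-substrate t-tests between two conditions
#'
#' For every substrate with at least two unflagged replicates in each
#' condition, a two-sided two-sample Student t-test (pooled variance)
#' compares the replicate log2 net intensities of the two slides. Substrates
#' with insufficient replicates are reported with `tested = FALSE` and `NA`
#' p-value.
#'
#' @param tab_a,tab_b Normalized spot tables of the two conditions.
#' @param layout The [array_layout()].
#' @return A tibble with `substrate_id`, `estimate` (mean B - mean A),
#'   `statistic`, `p.value`, `n_a`, `n_b`, `tested`.
#' @export
spot_tests <- function(tab_a, tab_b, layout) {
  s <- pair_stats(tab_a, tab_b, layout)
  tt <- pooled_t(s$mean_a, s$mean_b, s$var_a, s$var_b, s$n_a, s$n_b)
  tibble::tibble(
    substrate_id = seq_along(tt$p.value),
    estimate = tt$estimate, statistic = tt$statistic, p.value = tt$p.value,
    n_a = as.integer(s$n_a), n_b = as.integer(s$n_b),
    tested = !is.na(tt$p.value)
  )
}

#' Classify substrate calls against ground truth and build the ROC curve
#'
#' Substrates called at `p < alpha` are compared with the true induced labels
#' to give the confusion counts; the ROC curve is obtained by sweeping the
#' decision threshold over all observed p-values (lower p = more positive,
#' ties share averaged ranks), and the AUC is computed by the trapezoid rule,
#' which equals the Mann-Whitney statistic of p-values vs labels.
#'
#' @param tests Result of [spot_tests()] (untested substrates are dropped).
#' @param truth Logical vector of true induced labels along substrate ids, or
#'   the `truth` tibble of a [simulate_experiment()] result.
#' @param alpha Call threshold (default 0.05).
#' @return An object of class `kinome_eval` with elements `calls` (per-substrate
#'   tibble), `confusion` (TP/FP/TN/FN), `roc` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
classify_and_roc <- function(tests, truth, alpha = 0.05) {
  if (is.data.frame(truth)) {
    lab <- truth$induced[match(tests$substrate_id, truth$substrate_id)]
  } else {
    lab <- truth[tests$substrate_id]
  }
  keep <- tests$tested & !is.na(lab)
  p <- tests$p.value[keep]
  lab <- lab[keep]
  if (length(unique(lab)) < 2) {
    stop("truth labels contain a single class; AUC undefined", call. = FALSE)
  }
  call_pos <- p < alpha
  confusion <- c(
    tp = sum(call_pos & lab), fp = sum(call_pos & !lab),
    tn = sum(!call_pos & !lab), fn = sum(!call_pos & lab))
  n_pos <- sum(lab); n_neg <- sum(!lab)
  # Mann-Whitney AUC on score = -p (ties averaged)
  r <- rank(-p, ties.method = "average")
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(-Inf, sort(unique(p)), Inf)
  tpr <- vapply(thr, function(t) sum(lab & p <= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!lab & p <= t) / n_neg, numeric(1))
  out <- list(
    calls = tibble::tibble(substrate_id = tests$substrate_id[keep],
                           p.value = p, called = call_pos, induced = lab),
    confusion = confusion,
    roc = tibble::tibble(threshold = thr, fpr = c(fpr), tpr = c(tpr)),
    auc = auc, alpha = alpha)
  class(out) <- "kinome_eval"
  out
}

#' @export
print.kinome_eval <- function(x, ...) {
  cat(sprintf("<kinome_eval> AUC = %.3f; at p < %g: TP %d, FP %d, TN %d, FN %d\n",
              x$auc, x$alpha, x$confusion["tp"], x$confusion["fp"],
              x$confusion["tn"], x$confusion["fn"]))
  invisible(x)
}

#' Pathway-level paired t-tests
#'
#' Aggregates substrates annotated to one pathway: per substrate the
#' triplicate mean in condition A is paired with its triplicate mean in
#' condition B, and a two-sided paired t-test across the pathway's usable
#' substrates gives the pathway p-value and direction. Pathways with fewer
#' than three usable substrates are skipped.
#'
#' @inheritParams spot_tests
#' @param annotation Tibble mapping `substrate_id` to `kinase` and `pathway`
#'   (see [annotation_fixture()]).
#' @param by Aggregate per `"pathway"` (default) or per `"kinase"`.
#' @return A tibble with one row per (non-skipped) group: `pathway`,
#'   `n_substrates`, `estimate` (mean paired difference B - A), `statistic`,
#'   `p.value`, `direction`.
#' @export
pathway_tests <- function(tab_a, tab_b, layout, annotation,
                          by = c("pathway", "kinase")) {
  by <- match.arg(by)
  ma <- spot_means(tab_a, layout)
  mb <- spot_means(tab_b, layout)
  ann <- dplyr::mutate(annotation, group = .data[[by]])
  groups <- split(ann$substrate_id, ann$group)
  if (length(groups) == 0) {
    warning("empty annotation; no pathways tested", call. = FALSE)
  }
  rows <- purrr::imap(groups, function(ids, g) {
    a <- ma$mean_log2[ids]; b <- mb$mean_log2[ids]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) return(NULL)
    d <- b[ok] - a[ok]
    if (stats::sd(d) < 1e-12) {
      # constant paired differences: degenerate t; p follows the sign
      est <- mean(d)
      stat <- if (est == 0) 0 else sign(est) * Inf
      pv <- if (est == 0) 1 else 0
    } else {
      tt <- stats::t.test(b[ok], a[ok], paired = TRUE)
      est <- unname(tt$estimate); stat <- unname(tt$statistic)
      pv <- tt$p.value
    }
    tibble::tibble(pathway = g, n_substrates = sum(ok),
                   estimate = est, statistic = stat, p.value = pv,
                   direction = ifelse(est >= 0, "up", "down"))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d pathway(s) skipped (fewer than 3 usable substrates)",
                    dropped), call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Benchmark normalization methods on simulated experiments
#'
#' For every row of a parameter grid and every normalizer, simulates a
#' virtual experiment, optionally applies intraslide gradient correction,
#' normalizes each patient's control/treatment pair, runs per-substrate
#' t-tests and summarizes classification of induced substrates by the AUC,
#' averaged over patients (and repeats) with its SEM.
#'
#' @param grid A data frame whose columns override [sim_config()] arguments
#'   (e.g. `effect_size`, `n_induced`, `gradient_strength`, `off_fraction`);
#'   one row per experimental condition.
#' @param normalizers Character vector among `"raw"`, `"median"`,
#'   `"quantile"`, `"rse"`.
#' @param gradient_correction Apply [gradient_correct()] to every slide
#'   before interarray normalization (default TRUE).
#' @param n_repeats Independent simulated experiments per cell (default 1).
#' @param seed Master seed.
#' @param n_neighbors,alpha RSE parameters.
#' @param ... Further fixed [sim_config()] overrides applied to every cell.
#' @return A tidy tibble: one row per (cell, normalizer) with the grid
#'   columns, `normalizer`, `mean_auc`, `sem_auc`, `n_auc`.
#' @export
benchmark_normalizers <- function(grid, normalizers = c("median", "quantile", "rse"),
                                  gradient_correction = TRUE, n_repeats = 1,
                                  seed = 1L, n_neighbors = 20, alpha = 0.1,
                                  ...) {
  grid <- tibble::as_tibble(grid)
  bad <- setdiff(normalizers, c("raw", "median", "quantile", "rse"))
  if (length(bad)) stop("unknown normalizer(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  fixed <- list(...)
  cells <- purrr::map(seq_len(nrow(grid)), function(i) {
    overrides <- c(as.list(grid[i, , drop = FALSE]), fixed)
    cfg <- do.call(sim_config, overrides)
    aucs <- matrix(NA_real_, nrow = cfg$n_patients * n_repeats,
                   ncol = length(normalizers),
                   dimnames = list(NULL, normalizers))
    for (rep_i in seq_len(n_repeats)) {
      cell_seed <- substream_seed(seed, sprintf("cell%d_rep%d", i, rep_i))
      exper <- simulate_experiment(cfg, seed = cell_seed)
      for (pt in seq_len(cfg$n_patients)) {
        a <- experiment_slide(exper, pt, "control")
        b <- experiment_slide(exper, pt, "treatment")
        if (gradient_correction) {
          a <- gradient_correct(a, cfg$layout, n_neighbors)
          b <- gradient_correct(b, cfg$layout, n_neighbors)
        }
        for (nm in normalizers) {
          pair <- normalize_pair(a, b, cfg$layout, method = nm,
                                 n_neighbors = n_neighbors, alpha = alpha)
          tests <- spot_tests(pair$table_a, pair$table_b, cfg$layout)
          ev <- classify_and_roc(tests, exper$truth)
          aucs[(rep_i - 1) * cfg$n_patients + pt, nm] <- ev$auc
        }
      }
    }
    res <- tibble::as_tibble(grid[i, , drop = FALSE])
    res <- res[rep(1, length(normalizers)), , drop = FALSE]
    res$normalizer <- normalizers
    res$mean_auc <- colMeans(aucs)
    res$sem_auc <- apply(aucs, 2, stats::sd) / sqrt(nrow(aucs))
    res$n_auc <- nrow(aucs)
    res
  })
  dplyr::bind_rows(cells)
}
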