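#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an RSE normalization result
#'
#' One row per substrate with its applied offset, eligibility and membership
#' of the converged normalization set.
#'
#' @param x An `rse_result` from [rse_normalize()].
#' @param ... Unused.
#' @return A tibble with `substrate_id`, `offset`, `eligible`, `in_set`,
#'   `excluded`.
#' @method tidy rse_result
#' @export
tidy.rse_result <- function(x, ...) x$offsets

#' One-row summary of an RSE normalization result
#'
#' @inheritParams tidy.rse_result
#' @return A tibble with `iterations`, `converged`, `n_eligible`,
#'   `n_normalization_set`, `pct_of_substrates`, `n_excluded`,
#'   `median_offset`.
#' @method glance rse_result
#' @export
glance.rse_result <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    n_eligible = x$n_eligible,
    n_normalization_set = length(x$normalization_set),
    pct_of_substrates = 100 * length(x$normalization_set) /
      nrow(x$offsets),
    n_excluded = length(x$excluded),
    median_offset = stats::median(x$offsets$offset[x$offsets$eligible]))
}

#' Tidy a classification/ROC evaluation
#'
#' @param x A `kinome_eval` from [classify_and_roc()].
#' @param ... Unused.
#' @return The ROC curve tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy kinome_eval
#' @export
tidy.kinome_eval <- function(x, ...) x$roc

#' One-row summary of a classification/ROC evaluation
#'
#' @inheritParams tidy.kinome_eval
#' @return A tibble with `auc`, `alpha` and the confusion counts.
#' @method glance kinome_eval
#' @export
glance.kinome_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, alpha = x$alpha,
                 tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
                 tn = x$confusion[["tn"]], fn = x$confusion[["fn"]])
}
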