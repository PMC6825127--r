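#' Run the full germline-to-risk pipeline on a cohort
#'
#' Chains every stage end to end: functional germline calling from the
#' paired VAFs, per-sample seed sets, network propagation to the heat
#' matrix, MSS signature discovery on the training split, NOG_CSS cutoff
#' fitting on the testing split, and risk calls for every split. Intended
#' both for synthetic cohorts and for real inputs assembled into the same
#' shape.
#'
#' @param cohort A `synthetic_cohort`, or a list with elements `variants`,
#'   `network`, `hallmark_sets` and `clinical` (clinical needs `sample_id`,
#'   `split`, `label`, and for survival analyses `dfs_months`, `event`).
#' @param filter A [filter_config()].
#' @param prop A [propagation_config()].
#' @param mss An [mss_config()].
#' @param coverage_floor Passed to [fit_css()].
#' @return A `nog_pipeline` list: `calls`, `seeds`, `heat`, `signatures`,
#'   `css`, and `predictions` (tibble over all seedable samples with
#'   `split` and `label` joined in).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(synthetic_config(
#'   n_genes = 150, n_hallmarks = 3, hallmark_size = 35, n_planted = 8,
#'   n_train = 40, n_test = 20, n_valid = 20, p_recur = 0.3
#' ))
#' fit <- run_nog_pipeline(cohort, mss = mss_config(n_rounds = 100))
#' dplyr::count(fit$predictions, split, call)
#' }
#' @export
run_nog_pipeline <- function(cohort,
                             filter = filter_config(),
                             prop = propagation_config(),
                             mss = mss_config(),
                             coverage_floor = 0.5) {
  calls <- call_germline(cohort$variants, filter)
  seeds <- seeds_per_sample(calls)
  heat <- build_heat_matrix(cohort$network, seeds, prop)

  clin <- tibble::as_tibble(cohort$clinical)
  labels <- clin[, intersect(c("sample_id", "label", "split"), names(clin))]
  train_ids <- clin$sample_id[clin$split == "train"]
  test_ids <- clin$sample_id[clin$split == "test"]

  signatures <- discover_all(
    subset_heat(heat, train_ids),
    dplyr::filter(labels, .data$split == "train"),
    cohort$hallmark_sets,
    mss
  )
  css <- fit_css(
    signatures,
    subset_heat(heat, test_ids),
    dplyr::filter(labels, .data$split == "test"),
    coverage_floor = coverage_floor
  )
  predictions <- predict(css, heat) |>
    dplyr::left_join(labels, by = "sample_id")

  structure(
    list(
      calls = calls, seeds = seeds, heat = heat,
      signatures = signatures, css = css, predictions = predictions
    ),
    class = "nog_pipeline"
  )
}

#' @export
print.nog_pipeline <- function(x, ...) {
  cat(sprintf(
    "<nog_pipeline> %d signatures; cutoffs k <= %d (low) / k >= %d (high)\n",
    length(x$signatures), x$css$K_low, x$css$K_high
  ))
  print(dplyr::count(x$predictions, .data$split, .data$call))
  invisible(x)
}
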