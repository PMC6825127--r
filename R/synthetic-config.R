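#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulator: network size and topology, hallmark
#' gene-set layout, how many recurrence-driver genes are planted, cohort split
#' sizes, the germline mutation-rate model, sequencing depth for VAF draws,
#' the expression effect size, and the exponential survival model.
#'
#' The defaults emulate the design of an ER+ breast-cancer exome study:
#' a training set of 200 patients, a testing set of 60, a validation set of
#' 200, ~15% recurrence, disease-free survival measured in months with
#' administrative censoring at 10 years, and recurred patients carrying an
#' enriched load of functional germline variants on the planted driver genes
#' and their first network neighbors.
#'
#' @param n_genes Number of genes (network nodes).
#' @param n_edges_per_node Preferential-attachment parameter `m`: edges added
#'   per new node while growing the network.
#' @param n_hallmarks Number of cancer-hallmark gene sets.
#' @param hallmark_size Genes per hallmark set.
#' @param n_planted Number of planted recurrence-driver genes.
#' @param n_train,n_test,n_valid Sample counts of the three cohort splits.
#' @param p_recur Probability that a sample is labeled recurred, in (0, 1).
#' @param seed_rate_base Expected number of functional germline genes per
#'   non-recurred sample.
#' @param seed_enrichment Multiplier (>= 1) applied to the per-gene mutation
#'   probability of planted genes and their first neighbors in recurred
#'   samples.
#' @param coverage_mean Mean sequencing depth used for binomial VAF draws.
#' @param expr_shift Standardized effect size separating the groups on
#'   signature-adjacent gene expression (and, scaled, on metagenes).
#' @param hazard_low,hazard_high Exponential event rates (1/months) for
#'   non-recurred and recurred samples; `hazard_high > hazard_low`.
#' @param censor_max Administrative censoring horizon in months.
#' @param rng_seed Integer seed; identical configs reproduce identical cohorts.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_genes = 100, n_train = 20, n_test = 10, n_valid = 10)
#' cfg$p_recur
#' @export
synthetic_config <- function(n_genes = 600,
                             n_edges_per_node = 3,
                             n_hallmarks = 10,
                             hallmark_size = 60,
                             n_planted = 45,
                             n_train = 200,
                             n_test = 60,
                             n_valid = 200,
                             p_recur = 0.15,
                             seed_rate_base = 50,
                             seed_enrichment = 3,
                             coverage_mean = 80,
                             expr_shift = 1,
                             hazard_low = 0.005,
                             hazard_high = 0.02,
                             censor_max = 120,
                             rng_seed = 42L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_edges_per_node = as.integer(n_edges_per_node),
    n_hallmarks = as.integer(n_hallmarks),
    hallmark_size = as.integer(hallmark_size),
    n_planted = as.integer(n_planted),
    n_train = as.integer(n_train),
    n_test = as.integer(n_test),
    n_valid = as.integer(n_valid),
    p_recur = p_recur,
    seed_rate_base = seed_rate_base,
    seed_enrichment = seed_enrichment,
    coverage_mean = coverage_mean,
    expr_shift = expr_shift,
    hazard_low = hazard_low,
    hazard_high = hazard_high,
    censor_max = censor_max,
    rng_seed = as.integer(rng_seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c(
    "n_genes", "n_edges_per_node", "n_hallmarks", "hallmark_size",
    "n_planted", "n_train", "n_test", "n_valid"
  )
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      abort(sprintf("`%s` must be a positive count.", nm), class = "nogcss_config_error")
    }
  }
  if (cfg$n_genes < 2L * cfg$n_edges_per_node) {
    abort("`n_genes` must be at least 2 * `n_edges_per_node`.",
      class = "nogcss_config_error"
    )
  }
  if (!(cfg$p_recur > 0 && cfg$p_recur < 1)) {
    abort("`p_recur` must lie strictly in (0, 1).", class = "nogcss_config_error")
  }
  if (cfg$seed_enrichment < 1) {
    abort("`seed_enrichment` must be >= 1.", class = "nogcss_config_error")
  }
  if (cfg$hazard_high <= cfg$hazard_low) {
    abort("`hazard_high` must exceed `hazard_low`.", class = "nogcss_config_error")
  }
  if (cfg$hazard_low <= 0 || cfg$censor_max <= 0 || cfg$coverage_mean <= 0 ||
    cfg$seed_rate_base <= 0 || cfg$expr_shift < 0) {
    abort("rates, depth and effect sizes must be positive (expr_shift >= 0).",
      class = "nogcss_config_error"
    )
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf(
    "  network: %d genes, m = %d; hallmarks: %d x %d; planted drivers: %d\n",
    x$n_genes, x$n_edges_per_node, x$n_hallmarks, x$hallmark_size, x$n_planted
  ))
  cat(sprintf(
    "  cohort: train %d / test %d / valid %d, p_recur = %.2f\n",
    x$n_train, x$n_test, x$n_valid, x$p_recur
  ))
  cat(sprintf(
    "  germline: base rate %.1f genes/sample, enrichment x%.1f, depth %g\n",
    x$seed_rate_base, x$seed_enrichment, x$coverage_mean
  ))
  cat(sprintf(
    "  survival: hazards %.4g / %.4g per month, censored at %g months\n",
    x$hazard_low, x$hazard_high, x$censor_max
  ))
  invisible(x)
}
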