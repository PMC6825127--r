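#' Germline filter configuration
#'
#' Holds the VAF thresholds (on the percent scale, compared inclusively as
#' printed in the source thresholds: homozygous when normal VAF >= 90%,
#' heterozygous when it falls in the closed interval 45-65%) and the
#' functional-annotation rule.
#'
#' The default functional rule is `"any"`: a variant is functional if any
#' annotator calls it damaging — CADD phred >= `cadd_min`, MutationTaster
#' verdict in `taster_damaging`, or CRAVAT p < `cravat_alpha`. Variants with
#' no annotation evidence at all are conservatively dropped.
#'
#' @param hom_threshold Homozygous normal-VAF threshold, percent.
#' @param het_low,het_high Closed heterozygous window, percent.
#' @param functional_rule `"any"` (an annotator calls damaging), `"all"`
#'   (every *available* annotation must be damaging), or `"cadd_only"`.
#' @param cadd_min CADD phred cutoff.
#' @param taster_damaging MutationTaster verdicts counted as damaging.
#' @param cravat_alpha CRAVAT p-value cutoff.
#' @return A `filter_config` list.
#' @export
filter_config <- function(hom_threshold = 90,
                          het_low = 45,
                          het_high = 65,
                          functional_rule = c("any", "all", "cadd_only"),
                          cadd_min = 15,
                          taster_damaging = "disease_causing",
                          cravat_alpha = 0.05) {
  functional_rule <- tryCatch(match.arg(functional_rule),
    error = function(e) {
      abort(sprintf("unknown functional rule '%s'.", functional_rule[1]),
        class = "nogcss_config_error"
      )
    }
  )
  if (!(0 < het_low && het_low < het_high && het_high < hom_threshold &&
    hom_threshold <= 100)) {
    abort("need 0 < het_low < het_high < hom_threshold <= 100.",
      class = "nogcss_config_error"
    )
  }
  structure(
    list(
      hom_threshold = hom_threshold, het_low = het_low, het_high = het_high,
      functional_rule = functional_rule, cadd_min = cadd_min,
      taster_damaging = taster_damaging, cravat_alpha = cravat_alpha
    ),
    class = "filter_config"
  )
}

check_vaf_columns <- function(variants) {
  for (col in c("tumor_vaf", "normal_vaf")) {
    v <- variants[[col]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad)) {
      abort(sprintf("%d %s value(s) outside [0, 1].", sum(bad), col),
        class = "nogcss_validation_error"
      )
    }
  }
  if (any(!is.na(variants$pos) & variants$pos < 1)) {
    abort("positions must be >= 1 (1-based).", class = "nogcss_validation_error")
  }
  invisible(variants)
}

#' Classify germline zygosity from the normal-sample VAF
#'
#' A variant is called homozygous germline when the normal-sample VAF (as a
#' percentage) is at or above `hom_threshold`, heterozygous germline when it
#' lies inside the closed window `[het_low, het_high]`, and `not_germline`
#' otherwise (typically somatic contamination or noise). Variants with a
#' missing normal VAF cannot be classified and are dropped with a warning.
#'
#' @param variants A variant tibble with at least `sample_id`, `gene`, `pos`,
#'   `tumor_vaf`, `normal_vaf` (VAFs as fractions in \[0, 1\]).
#' @param config A [filter_config()].
#' @return The input tibble with a `zygosity` factor column
#'   (`homozygous` / `heterozygous` / `not_germline`), rows with missing
#'   normal VAF removed.
#' @examples
#' v <- tibble::tibble(
#'   sample_id = "S1", gene = "TP53", chrom = "17", pos = 1,
#'   ref = "A", alt = "G", tumor_vaf = 0.5, normal_vaf = c(0.90, 0.50, 0.30)
#' )
#' classify_zygosity(v)$zygosity
#' @export
classify_zygosity <- function(variants, config = filter_config()) {
  variants <- tibble::as_tibble(variants)
  check_vaf_columns(variants)
  n_missing <- sum(is.na(variants$normal_vaf))
  if (n_missing > 0) {
    warn(sprintf("dropped %d variant(s) with missing normal VAF.", n_missing))
    variants <- dplyr::filter(variants, !is.na(.data$normal_vaf))
  }
  pct <- as_percent(variants$normal_vaf)
  zyg <- dplyr::case_when(
    pct >= config$hom_threshold ~ "homozygous",
    pct >= config$het_low & pct <= config$het_high ~ "heterozygous",
    TRUE ~ "not_germline"
  )
  variants$zygosity <- factor(zyg, levels = c("homozygous", "heterozygous", "not_germline"))
  variants
}

functional_flag <- function(variants, config) {
  n <- nrow(variants)
  get <- function(col) if (col %in% names(variants)) variants[[col]] else rep(NA, n)
  cadd <- get("cadd_phred")
  taster <- get("mutation_taster")
  cravat <- get("cravat_p")
  cadd_hit <- !is.na(cadd) & cadd >= config$cadd_min
  taster_hit <- !is.na(taster) & taster %in% config$taster_damaging
  cravat_hit <- !is.na(cravat) & cravat < config$cravat_alpha
  has_any <- (!is.na(cadd)) | (!is.na(taster)) | (!is.na(cravat))
  switch(config$functional_rule,
    any = cadd_hit | taster_hit | cravat_hit,
    cadd_only = cadd_hit,
    all = {
      ok <- rep(TRUE, n)
      ok[!is.na(cadd) & !cadd_hit] <- FALSE
      ok[!is.na(taster) & !taster_hit] <- FALSE
      ok[!is.na(cravat) & !cravat_hit] <- FALSE
      ok & has_any # no evidence at all is never functional
    }
  )
}

#' Retain functional germline variants
#'
#' Applies the zygosity gate (only homozygous/heterozygous germline calls
#' pass) and then the functional-annotation rule of `config`. The zygosity
#' gate precedes the functional gate: a damaging somatic variant is never
#' retained.
#'
#' @param calls Output of [classify_zygosity()] (annotation columns
#'   `cadd_phred`, `mutation_taster`, `cravat_p` optional; absent evidence
#'   means not functional).
#' @param config A [filter_config()].
#' @return The retained rows with a `functional` logical column (all `TRUE`).
#' @export
apply_functional_filter <- function(calls, config = filter_config()) {
  calls <- tibble::as_tibble(calls)
  if (!"zygosity" %in% names(calls)) {
    abort("run `classify_zygosity()` first (no `zygosity` column).",
      class = "nogcss_validation_error"
    )
  }
  calls$functional <- functional_flag(calls, config)
  dplyr::filter(calls, .data$zygosity != "not_germline", .data$functional)
}

#' Call functional germline variants in one step
#'
#' Convenience wrapper: [classify_zygosity()] then
#' [apply_functional_filter()].
#'
#' @inheritParams classify_zygosity
#' @return Filtered calls tibble.
#' @export
call_germline <- function(variants, config = filter_config()) {
  apply_functional_filter(classify_zygosity(variants, config), config)
}

#' Per-sample seed gene sets
#'
#' Collapses filtered germline calls to one row per sample and gene: the
#' genes with at least one retained functional germline variant are that
#' sample's seed set for network propagation.
#'
#' @param calls Filtered calls from [apply_functional_filter()].
#' @return Tibble with columns `sample_id`, `gene`, `n_variants` (variants
#'   supporting the gene in that sample).
#' @export
seeds_per_sample <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(
      sample_id = character(), gene = character(),
      n_variants = integer()
    ))
  }
  calls |>
    dplyr::mutate(gene = toupper(.data$gene)) |>
    dplyr::count(.data$sample_id, .data$gene, name = "n_variants") |>
    dplyr::arrange(.data$sample_id, .data$gene)
}

#' Per-sample germline burden counts
#'
#' Counts, for each sample, the number of retained functional germline
#' variants, the number of distinct genes harboring one, and the number of
#' those variants falling in leukocyte-expressed genes — the three burden
#' features compared between predicted risk groups.
#'
#' @param calls Filtered calls from [apply_functional_filter()].
#' @param leukocyte_genes Character vector of leukocyte-expressed gene
#'   symbols (may be empty).
#' @param all_samples Optional sample ids to report even when a sample has no
#'   retained variant (counts 0).
#' @return Tibble with `sample_id`, `n_variants`, `n_genes`,
#'   `n_leukocyte_variants`.
#' @export
burden_summary <- function(calls, leukocyte_genes = character(), all_samples = NULL) {
  leukocyte_genes <- toupper(leukocyte_genes)
  out <- calls |>
    dplyr::mutate(gene = toupper(.data$gene)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_genes = dplyr::n_distinct(.data$gene),
      n_leukocyte_variants = sum(.data$gene %in% leukocyte_genes),
      .groups = "drop"
    )
  if (!is.null(all_samples)) {
    out <- tibble::tibble(sample_id = as.character(all_samples)) |>
      dplyr::left_join(out, by = "sample_id") |>
      dplyr::mutate(dplyr::across(
        c("n_variants", "n_genes", "n_leukocyte_variants"),
        ~ tidyr::replace_na(.x, 0L)
      ))
  }
  out
}
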