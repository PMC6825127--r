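#' The 21-gene Oncotype DX recurrence-score model
#'
#' Encodes the published 21-gene recurrence-score (RS) formula for ER+
#' breast cancer: 16 cancer genes in four groups (HER2, ER, proliferation,
#' invasion) plus three singleton genes, referenced against 5 housekeeping
#' genes. Group scores are weighted means of reference-normalized
#' expression with the published floors (HER2 group floored at 8,
#' proliferation group at 6.5, on the 0-15 RT-PCR-like scale); the
#' unscaled RS is the coefficient-weighted sum, and
#' `RS = 20 * (RSu - 6.7)` clamped to \[0, 100\]. Every gene, weight,
#' floor, coefficient and bin threshold can be overridden, so a variant of
#' the formula can be dropped in.
#'
#' @param bin_thresholds Numeric `c(low_max, int_max)`: RS strictly below
#'   `low_max` is low risk, below `int_max` intermediate, else high
#'   (classical 18 / 31).
#' @param groups Named list of gene groups; each element needs `genes`,
#'   `weights` (same length), and optional `floor`.
#' @param coefficients Named weights of the group/singleton scores in the
#'   unscaled RS.
#' @param reference_genes The 5 housekeeping genes whose per-sample mean is
#'   subtracted.
#' @param rs_scale,rs_offset The affine map `rs = rs_scale * (RSu - rs_offset)`.
#' @return An `oncotype_model` list.
#' @export
oncotype_model <- function(bin_thresholds = c(18, 31),
                           groups = NULL,
                           coefficients = NULL,
                           reference_genes = c("ACTB", "GAPDH", "RPLP0", "GUSB", "TFRC"),
                           rs_scale = 20,
                           rs_offset = 6.7) {
  if (is.null(groups)) {
    groups <- list(
      her2 = list(genes = c("GRB7", "ERBB2"), weights = c(0.9, 0.1), floor = 8),
      er = list(
        genes = c("ESR1", "PGR", "BCL2", "SCUBE2"),
        weights = c(0.8, 1.2, 1, 1) / 4, floor = NULL
      ),
      proliferation = list(
        genes = c("MKI67", "AURKA", "BIRC5", "CCNB1", "MYBL2"),
        weights = rep(1 / 5, 5), floor = 6.5
      ),
      invasion = list(genes = c("CTSV", "MMP11"), weights = c(0.5, 0.5), floor = NULL),
      cd68 = list(genes = "CD68", weights = 1, floor = NULL),
      gstm1 = list(genes = "GSTM1", weights = 1, floor = NULL),
      bag1 = list(genes = "BAG1", weights = 1, floor = NULL)
    )
  }
  if (is.null(coefficients)) {
    coefficients <- c(
      her2 = 0.47, er = -0.34, proliferation = 1.04, invasion = 0.10,
      cd68 = 0.05, gstm1 = -0.08, bag1 = -0.07
    )
  }
  stopifnot(setequal(names(groups), names(coefficients)))
  all_genes <- unique(c(unlist(purrr::map(groups, "genes")), reference_genes))
  if (length(all_genes) != 21L) {
    warn(sprintf("model lists %d distinct genes (the published panel has 21).", length(all_genes)))
  }
  structure(
    list(
      groups = groups, coefficients = coefficients,
      reference_genes = toupper(reference_genes),
      rs_scale = rs_scale, rs_offset = rs_offset,
      bin_thresholds = bin_thresholds,
      gene_list = toupper(all_genes)
    ),
    class = "oncotype_model"
  )
}

#' @export
print.oncotype_model <- function(x, ...) {
  cat(sprintf(
    "<oncotype_model> %d genes, %d groups; bins: low < %g <= intermediate < %g <= high\n",
    length(x$gene_list), length(x$groups), x$bin_thresholds[1], x$bin_thresholds[2]
  ))
  invisible(x)
}

#' Compute Oncotype DX recurrence scores
#'
#' Reference-normalizes each sample (subtracting the mean of the 5
#' housekeeping genes), computes the weighted group scores with their
#' floors, combines them with the published coefficients into the unscaled
#' RS, rescales and clamps to \[0, 100\], and assigns the low /
#' intermediate / high risk bin. For RNA-seq input, pass
#' `log2(FPKM-UQ + 1)`-transformed values.
#'
#' @param expression Genes-by-samples matrix (or tibble with gene column) of
#'   expression on a log-like scale.
#' @param model An [oncotype_model()].
#' @return Tibble with `sample_id`, `unscaled_rs`, `rs`, `bin`, plus one
#'   column per group score.
#' @examples
#' m <- oncotype_model()
#' expr <- matrix(10, length(m$gene_list), 2,
#'   dimnames = list(m$gene_list, c("S1", "S2"))
#' )
#' compute_rs(expr, m)
#' @export
compute_rs <- function(expression, model = oncotype_model()) {
  m <- as_profile_matrix(expression)
  missing <- setdiff(model$gene_list, rownames(m))
  if (length(missing)) {
    abort(sprintf("expression matrix is missing genes: %s", toString(missing)),
      class = "nogcss_validation_error"
    )
  }
  refs <- colMeans(m[model$reference_genes, , drop = FALSE])
  norm <- sweep(m[model$gene_list, , drop = FALSE], 2, refs, "-")
  group_scores <- purrr::imap(model$groups, function(g, nm) {
    s <- as.numeric(crossprod(g$weights, norm[toupper(g$genes), , drop = FALSE]))
    if (!is.null(g$floor)) s <- pmax(s, g$floor)
    s
  })
  gs <- do.call(cbind, group_scores)
  unscaled <- as.numeric(gs %*% model$coefficients[colnames(gs)])
  rs <- pmin(100, pmax(0, model$rs_scale * (unscaled - model$rs_offset)))
  bin <- dplyr::case_when(
    rs < model$bin_thresholds[1] ~ "low",
    rs < model$bin_thresholds[2] ~ "intermediate",
    TRUE ~ "high"
  )
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = colnames(m), unscaled_rs = unscaled, rs = rs, bin = bin
    ),
    tibble::as_tibble(gs)
  )
}

#' Compare Oncotype RS bins with NOG_CSS calls
#'
#' Computes the accuracy/recall metric report for the RS risk bins and for
#' the NOG_CSS calls on the overlapping samples, side by side.
#' Intermediate-risk RS samples are excluded by default (the published
#' comparison reports only low and high); `intermediate = "high"` merges
#' them into the high-risk bin instead.
#'
#' @param rs_results Output of [compute_rs()].
#' @param css_calls Tibble with `sample_id`, `call` from
#'   [predict.css_model()].
#' @param labels Tibble with `sample_id`, `label`.
#' @param intermediate `"exclude"` or `"high"`.
#' @return Tibble: the two metric reports with a `classifier` column
#'   (`"oncotype_rs"`, `"nog_css"`).
#' @export
compare_with_css <- function(rs_results, css_calls, labels,
                             intermediate = c("exclude", "high")) {
  intermediate <- match.arg(intermediate)
  shared <- intersect(rs_results$sample_id, css_calls$sample_id)
  if (length(shared) == 0L) {
    abort("no overlapping samples between RS results and CSS calls.",
      class = "nogcss_validation_error"
    )
  }
  rs_calls <- rs_results |>
    dplyr::filter(.data$sample_id %in% shared) |>
    dplyr::mutate(call = dplyr::case_when(
      .data$bin == "low" ~ "low",
      .data$bin == "high" ~ "high",
      intermediate == "high" ~ "high",
      TRUE ~ "unpredicted"
    ))
  css <- dplyr::filter(css_calls, .data$sample_id %in% shared)
  dplyr::bind_rows(
    dplyr::mutate(accuracy_recall(rs_calls, labels, quiet = TRUE),
      classifier = "oncotype_rs", .before = 1
    ),
    dplyr::mutate(accuracy_recall(css, labels, quiet = TRUE),
      classifier = "nog_css", .before = 1
    )
  )
}
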