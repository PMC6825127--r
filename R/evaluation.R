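#' Accuracy and recall of predicted risk groups
#'
#' Computes the four headline percentages used to report classifier
#' performance, following the standard footnote definitions:
#' low-risk accuracy = % of non-recurred samples among the predicted
#' low-risk group; low-risk recall = % of the non-recurred samples that were
#' predicted low; and the high-risk analogues with recurred samples.
#' Unpredicted samples are excluded before anything is counted. Empty
#' denominators yield `NA`, never 0.
#'
#' @param calls Tibble with `sample_id` and `call`
#'   (`"low"`/`"high"`/`"unpredicted"`), e.g. from [predict.css_model()].
#' @param labels Tibble with `sample_id` and `label`
#'   (`"recurred"`/`"non_recurred"`).
#' @param quiet Suppress the join-size message.
#' @return A one-row `metric_report` tibble: `n`, `low_accuracy`,
#'   `low_recall`, `high_accuracy`, `high_recall` (percent), with the
#'   underlying 2x2 counts as columns `n_low_nonrec`, `n_low_rec`,
#'   `n_high_nonrec`, `n_high_rec`.
#' @examples
#' calls <- tibble::tibble(
#'   sample_id = as.character(1:12),
#'   call = rep(c("low", "high"), c(10, 2))
#' )
#' labels <- tibble::tibble(
#'   sample_id = as.character(1:12),
#'   label = rep(c("non_recurred", "recurred", "non_recurred", "recurred"), c(9, 1, 1, 1))
#' )
#' accuracy_recall(calls, labels)
#' @export
accuracy_recall <- function(calls, labels, quiet = FALSE) {
  labels <- check_labels(labels)
  d <- dplyr::inner_join(
    calls[, c("sample_id", "call")],
    labels[, c("sample_id", "label")],
    by = "sample_id"
  ) |>
    dplyr::filter(.data$call %in% c("low", "high"))
  if (nrow(d) == 0L) {
    abort("no called samples with labels.", class = "nogcss_validation_error")
  }
  if (!quiet && nrow(d) < nrow(calls)) {
    rlang::inform(sprintf(
      "%d of %d samples evaluated (unpredicted/unlabeled removed).",
      nrow(d), nrow(calls)
    ))
  }
  n_low_nonrec <- sum(d$call == "low" & d$label == "non_recurred")
  n_low_rec <- sum(d$call == "low" & d$label == "recurred")
  n_high_nonrec <- sum(d$call == "high" & d$label == "non_recurred")
  n_high_rec <- sum(d$call == "high" & d$label == "recurred")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- tibble::tibble(
    n = nrow(d),
    low_accuracy = pct(n_low_nonrec, n_low_nonrec + n_low_rec),
    low_recall = pct(n_low_nonrec, n_low_nonrec + n_high_nonrec),
    high_accuracy = pct(n_high_rec, n_high_rec + n_high_nonrec),
    high_recall = pct(n_high_rec, n_high_rec + n_low_rec),
    n_low_nonrec = n_low_nonrec, n_low_rec = n_low_rec,
    n_high_nonrec = n_high_nonrec, n_high_rec = n_high_rec
  )
  class(out) <- c("metric_report", class(out))
  out
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' Fits product-limit survival curves per predicted risk group and tests
#' their difference with the log-rank test, whose statistic is chi-squared
#' distributed on 1 degree of freedom (the "two-sided chi-squared test" of
#' Kaplan-Meier figure captions). Samples without a disease-free-survival
#' time or without a low/high call must be removed upstream.
#'
#' @param records Tibble with `dfs_months`, `event` (logical or 0/1) and
#'   `group` (`"low"`/`"high"`).
#' @return A `km_result`: list with `curves` (tidy step-coordinate tibble),
#'   `chi2`, `p`, `n`, `n_events`, and the underlying `survival::survfit`
#'   object.
#' @export
km_logrank <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("dfs_months", "event", "group") %in% names(records)))
  records <- dplyr::filter(records, !is.na(.data$dfs_months), !is.na(.data$group))
  if (any(records$dfs_months < 0)) {
    abort("dfs_months must be >= 0.", class = "nogcss_validation_error")
  }
  if (length(unique(records$group)) < 2L) {
    abort("both risk groups must be present.", class = "nogcss_validation_error")
  }
  if (sum(records$event) < 1L) {
    abort("at least one event is required.", class = "nogcss_validation_error")
  }
  records$group <- factor(records$group, levels = c("low", "high"))
  fit <- survival::survfit(
    survival::Surv(dfs_months, event) ~ group,
    data = records
  )
  sd_ <- survival::survdiff(
    survival::Surv(dfs_months, event) ~ group,
    data = records
  )
  chi2 <- unname(sd_$chisq)
  p <- pchisq(chi2, df = length(sd_$n) - 1, lower.tail = FALSE)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- tibble::tibble(
    group = sub("^group=", "", strata),
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv
  )
  structure(
    list(
      curves = curves, chi2 = chi2, p = p,
      n = nrow(records), n_events = sum(records$event), fit = fit
    ),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf(
    "<km_result> n = %d (%d events); log-rank chi2 = %.3f, p = %.3g\n",
    x$n, x$n_events, x$chi2, x$p
  ))
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `km_result`.
#' @param ... Unused.
#' @export
tidy.km_result <- function(x, ...) x$curves

#' @rdname km_logrank
#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, chi2 = x$chi2, p = x$p)
}

#' Cox proportional-hazards covariate comparison
#'
#' Fits Cox models for each clinical covariate singly and for all jointly,
#' reports the likelihood-ratio p-value per model, and places them side by
#' side with the log-rank p of the NOG_CSS risk grouping — the comparison
#' used to ask whether clinical factors predict recurrence better than the
#' germline signature ensemble. Covariates without variation are dropped
#' with a warning; a model that fails to converge is reported as `NA`, not
#' fatal.
#'
#' @param records Tibble with `dfs_months`, `event`, optional `group`
#'   (`"low"`/`"high"` risk calls), and covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "stage", "nodal")`; stage/nodal are used as given — encode
#'   them ordinally upstream, dropping X/NA levels).
#' @return Tibble with one row per model: `model`, `n`, `loglik_p`,
#'   `converged`.
#' @export
cox_covariates <- function(records, covariates = c("age", "stage", "nodal")) {
  records <- tibble::as_tibble(records)
  covariates <- intersect(covariates, names(records))
  keep <- purrr::keep(covariates, function(cv) {
    v <- records[[cv]][!is.na(records[[cv]])]
    ok <- length(unique(v)) > 1L
    if (!ok) warn(sprintf("covariate '%s' has no variation; dropped.", cv))
    ok
  })
  if (length(keep) == 0L) {
    abort("no covariate with variation.", class = "nogcss_validation_error")
  }
  fit_one <- function(terms, name) {
    f <- stats::as.formula(paste(
      "survival::Surv(dfs_months, event) ~",
      paste(terms, collapse = " + ")
    ))
    res <- tryCatch(
      {
        fit <- survival::coxph(f, data = records)
        s <- summary(fit)
        tibble::tibble(
          model = name, n = s$n,
          loglik_p = unname(s$logtest["pvalue"]), converged = TRUE
        )
      },
      error = function(e) {
        tibble::tibble(model = name, n = NA_integer_, loglik_p = NA_real_, converged = FALSE)
      }
    )
    res
  }
  out <- purrr::map_dfr(keep, ~ fit_one(.x, .x))
  if (length(keep) > 1L) {
    out <- dplyr::bind_rows(out, fit_one(keep, paste(keep, collapse = "+")))
  }
  if ("group" %in% names(records) &&
    length(unique(stats::na.omit(records$group))) == 2L &&
    sum(records$event[!is.na(records$group)]) >= 1L) {
    km <- km_logrank(records[!is.na(records$group), ])
    out <- dplyr::bind_rows(out, tibble::tibble(
      model = "nog_css_group", n = km$n, loglik_p = km$p, converged = TRUE
    ))
  }
  out
}

#' Feature-wise Welch comparisons between predicted risk groups
#'
#' For every feature (row of the matrix: a leukocyte metagene, a cell
#' fraction, or a burden count), runs a two-sided Welch t-test between the
#' predicted low- and high-risk groups and summarises both group
#' distributions for boxplots. Raw p-values are reported by default;
#' Benjamini-Hochberg q-values can be added with `adjust = TRUE`.
#'
#' @param features Features-by-samples matrix (or tibble whose first column
#'   is the feature name). Z-score rows upstream where appropriate.
#' @param calls Tibble with `sample_id` and `call`; unpredicted samples are
#'   excluded.
#' @param adjust Add a BH-adjusted `q_value` column.
#' @return Tibble with one row per feature: `feature`, `n_low`, `n_high`,
#'   `mean_low`, `mean_high`, `t_statistic`, `df`, `p_value`, quartiles per
#'   group, and optionally `q_value`. Features where a group has fewer than
#'   two values yield `NA` statistics.
#' @export
compare_groups <- function(features, calls, adjust = FALSE) {
  m <- as_profile_matrix(features)
  calls <- dplyr::filter(tibble::as_tibble(calls), .data$call %in% c("low", "high"))
  ids <- intersect(colnames(m), calls$sample_id)
  grp <- calls$call[match(ids, calls$sample_id)]
  low_ids <- ids[grp == "low"]
  high_ids <- ids[grp == "high"]
  out <- purrr::map_dfr(rownames(m), function(f) {
    x <- m[f, low_ids]
    y <- m[f, high_ids]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    base <- tibble::tibble(
      feature = f, n_low = length(x), n_high = length(y),
      mean_low = if (length(x)) mean(x) else NA_real_,
      mean_high = if (length(y)) mean(y) else NA_real_
    )
    if (length(x) < 2L || length(y) < 2L || (sd(x) == 0 && sd(y) == 0)) {
      return(dplyr::mutate(base,
        t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
        q1_low = NA_real_, median_low = NA_real_, q3_low = NA_real_,
        q1_high = NA_real_, median_high = NA_real_, q3_high = NA_real_
      ))
    }
    tt <- t.test(x, y) # Welch by default, two-sided
    qx <- stats::quantile(x, c(0.25, 0.5, 0.75))
    qy <- stats::quantile(y, c(0.25, 0.5, 0.75))
    dplyr::mutate(base,
      t_statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      q1_low = qx[[1]], median_low = qx[[2]], q3_low = qx[[3]],
      q1_high = qy[[1]], median_high = qy[[2]], q3_high = qy[[3]]
    )
  })
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
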