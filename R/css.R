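as_profile_matrix <- function(profiles) {
  if (inherits(profiles, "heat_matrix")) {
    return(profiles$scores)
  }
  if (is.data.frame(profiles)) {
    m <- as.matrix(profiles[, -1, drop = FALSE])
    rownames(m) <- toupper(profiles[[1]])
    return(m)
  }
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  rownames(profiles) <- toupper(rownames(profiles))
  profiles
}

#' Classify one profile against a signature's centroids
#'
#' Computes the Pearson correlation of the sample's profile, restricted to
#' the signature genes, against the low-risk and high-risk centroids, and
#' assigns the group with the larger correlation; an exact tie goes to low
#' risk (fixed, conservative tie rule). When fewer than two signature genes
#' are available, when more than half are missing, or when either
#' correlation is undefined (zero variance), the signature abstains and
#' `NA` is returned.
#'
#' @param profile Named numeric vector of per-gene scores for one sample.
#' @param signature A `nog_signature` with fitted centroids (or see
#'   `centroids`).
#' @param centroids Optional list with elements `low` and `high` (named
#'   numeric vectors) overriding the signature's own centroids — used for
#'   expression-based classification.
#' @return `"low"`, `"high"`, or `NA_character_` (abstention).
#' @export
classify_one <- function(profile, signature, centroids = NULL) {
  lo <- centroids$low %||% signature$centroid_low
  hi <- centroids$high %||% signature$centroid_high
  names(lo) <- toupper(names(lo))
  names(hi) <- toupper(names(hi))
  names(profile) <- toupper(names(profile))
  genes <- intersect(names(lo), names(profile)[!is.na(profile)])
  if (length(genes) < 2L || length(genes) < length(lo) / 2) {
    return(NA_character_)
  }
  p <- profile[genes]
  l <- lo[genes]
  h <- hi[genes]
  if (sd(p) == 0 || sd(l) == 0 || sd(h) == 0) {
    return(NA_character_)
  }
  r_low <- stats::cor(p, l)
  r_high <- stats::cor(p, h)
  if (r_high > r_low) "high" else "low"
}

# per-sample vote counts over a signature set
# centroid_list: optional per-signature centroid overrides (same length)
signature_votes <- function(signatures, profiles, centroid_list = NULL) {
  m <- as_profile_matrix(profiles)
  S <- length(signatures)
  votes <- matrix(NA_character_, ncol(m), S,
    dimnames = list(colnames(m), purrr::map_chr(signatures, "hallmark"))
  )
  for (s in seq_len(S)) {
    cent <- if (is.null(centroid_list)) NULL else centroid_list[[s]]
    for (j in seq_len(ncol(m))) {
      votes[j, s] <- classify_one(m[, j], signatures[[s]], centroids = cent)
    }
  }
  tibble::tibble(
    sample_id = colnames(m),
    k = as.integer(rowSums(votes == "high", na.rm = TRUE)),
    s_effective = as.integer(rowSums(!is.na(votes))),
    votes = lapply(seq_len(nrow(votes)), function(i) votes[i, ])
  )
}

# map votes to calls under cutoffs, rescaling the cutoffs to the number of
# non-abstaining signatures (rounded half down) so missingness cannot force
# a low call
calls_from_votes <- function(votes, K_low, K_high, S) {
  scale <- votes$s_effective / S
  kl <- round_half_down(K_low * scale)
  kh <- pmax(kl + 1, round_half_down(K_high * scale))
  call <- dplyr::case_when(
    votes$s_effective == 0L ~ "unpredicted",
    votes$k <= kl ~ "low",
    votes$k >= kh ~ "high",
    TRUE ~ "unpredicted"
  )
  dplyr::mutate(votes, call = call)
}

#' Fit the NOG_CSS vote cutoffs on the testing split
#'
#' Given the per-signature votes of the testing samples, grid-searches every
#' cutoff pair `0 <= K_low < K_high <= S` (a sample is called low when at
#' most `K_low` signatures vote high, high when at least `K_high` do, and
#' unpredicted in between). Each pair is scored by low-risk accuracy +
#' high-risk accuracy, subject to at least `coverage_floor` of the testing
#' samples receiving a call; ties prefer the widest unpredicted band, then
#' the smallest `K_low`. The testing split must be disjoint from training —
#' if the labels carry a `split` column, anything other than `"test"` is
#' rejected.
#'
#' @param signatures A `nog_signature_set` (centroids fitted on training).
#' @param testing_profiles `heat_matrix` or genes-by-samples matrix of the
#'   testing split.
#' @param testing_labels Tibble with `sample_id`, `label` (and optionally
#'   `split`).
#' @param coverage_floor Minimum fraction of testing samples that must be
#'   called.
#' @return A `css_model`: signatures, `K_low`, `K_high`, and a `fit_report`
#'   tibble holding the full cutoff grid.
#' @export
fit_css <- function(signatures, testing_profiles, testing_labels,
                    coverage_floor = 0.5) {
  testing_labels <- check_labels(testing_labels)
  if ("split" %in% names(testing_labels) &&
    !all(testing_labels$split == "test")) {
    abort("`fit_css()` must only see the testing split (split hygiene).",
      class = "nogcss_validation_error"
    )
  }
  S <- length(signatures)
  votes <- signature_votes(signatures, testing_profiles)
  votes <- dplyr::inner_join(votes, testing_labels[, c("sample_id", "label")],
    by = "sample_id"
  )
  if (length(unique(votes$label)) < 2L) {
    abort("both classes must be present in the testing split.",
      class = "nogcss_validation_error"
    )
  }
  grid <- tidyr::expand_grid(K_low = 0:(S - 1), K_high = 1:S) |>
    dplyr::filter(.data$K_low < .data$K_high)
  report <- purrr::pmap_dfr(grid, function(K_low, K_high) {
    called <- calls_from_votes(votes, K_low, K_high, S)
    mr <- accuracy_recall(called, called[, c("sample_id", "label")], quiet = TRUE)
    coverage <- mean(called$call != "unpredicted")
    tibble::tibble(
      K_low = K_low, K_high = K_high, coverage = coverage,
      low_accuracy = mr$low_accuracy, high_accuracy = mr$high_accuracy,
      low_recall = mr$low_recall, high_recall = mr$high_recall,
      score = ifelse(is.na(mr$low_accuracy), 0, mr$low_accuracy) +
        ifelse(is.na(mr$high_accuracy), 0, mr$high_accuracy),
      eligible = coverage >= coverage_floor
    )
  })
  eligible <- dplyr::filter(report, .data$eligible)
  if (nrow(eligible) == 0L) {
    abort(sprintf(
      "no cutoff pair called at least %.0f%% of testing samples; lower `coverage_floor`.",
      100 * coverage_floor
    ), class = "nogcss_pipeline_error")
  }
  best <- eligible |>
    dplyr::arrange(
      dplyr::desc(.data$score),
      dplyr::desc(.data$K_high - .data$K_low),
      .data$K_low
    ) |>
    dplyr::slice(1)
  structure(
    list(
      signatures = signatures,
      K_low = best$K_low, K_high = best$K_high, S = S,
      coverage_floor = coverage_floor,
      fit_report = report
    ),
    class = "css_model"
  )
}

#' @export
print.css_model <- function(x, ...) {
  cat(sprintf(
    "<css_model> %d signatures; low if k <= %d, high if k >= %d\n",
    x$S, x$K_low, x$K_high
  ))
  invisible(x)
}

#' Predict risk calls with a fitted NOG_CSS
#'
#' Counts, per sample, the signatures voting high (`k`) among the
#' non-abstaining ones (`s_effective`) and calls the sample low when
#' `k <= K_low`, high when `k >= K_high` (cutoffs rescaled to
#' `s_effective`), and unpredicted in between.
#'
#' @param object A `css_model`.
#' @param profiles `heat_matrix` or genes-by-samples matrix.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `k`, `s_effective`, `call` and a
#'   list-column `votes` of per-signature calls.
#' @export
predict.css_model <- function(object, profiles, ...) {
  votes <- signature_votes(object$signatures, profiles)
  calls_from_votes(votes, object$K_low, object$K_high, object$S)
}

#' Classify samples from expression with genomically fitted cutoffs
#'
#' Re-uses the NOG signature gene lists on an expression matrix: expression
#' is z-scored per gene with the *training-split* mean and standard
#' deviation (no leakage), group centroids are recomputed from the training
#' samples' expression, every requested sample is classified by
#' [classify_one()], and the vote cutoffs fitted on genome sequencing are
#' reused unchanged. With `mode = "loo"`, a classified sample that is itself
#' part of the training split is excluded from the centroid computation for
#' its own call (leave-one-out).
#'
#' @param css A fitted `css_model`.
#' @param expression Genes-by-samples matrix (or tibble with a gene column)
#'   of raw expression values.
#' @param train_labels Tibble with `sample_id`, `label` for the training
#'   split (must be columns of `expression`).
#' @param samples Sample ids to classify (default: all columns not in the
#'   training split).
#' @param mode `"holdout"` (centroids from all training samples) or
#'   `"loo"`.
#' @return Tibble as in [predict.css_model()].
#' @export
classify_expression <- function(css, expression, train_labels,
                                samples = NULL, mode = c("holdout", "loo")) {
  mode <- match.arg(mode)
  m <- as_profile_matrix(expression)
  train_labels <- check_labels(train_labels)
  train_ids <- intersect(train_labels$sample_id, colnames(m))
  if (length(train_ids) < 2L) {
    abort("training samples absent from the expression matrix.",
      class = "nogcss_validation_error"
    )
  }
  if (is.null(samples)) samples <- setdiff(colnames(m), train_ids)
  # z-score per gene on training statistics
  mu <- rowMeans(m[, train_ids, drop = FALSE])
  sg <- apply(m[, train_ids, drop = FALSE], 1, sd)
  sg[sg == 0 | is.na(sg)] <- 1
  z <- sweep(sweep(m, 1, mu, "-"), 1, sg, "/")

  lab <- train_labels$label[match(train_ids, train_labels$sample_id)]
  centroids_for <- function(exclude = NULL) {
    use <- setdiff(train_ids, exclude)
    l <- lab[match(use, train_ids)]
    purrr::map(css$signatures, function(sig) {
      genes <- intersect(toupper(sig$genes), rownames(z))
      if (length(genes) < length(sig$genes) / 2) {
        return(list(low = setNames(numeric(0), character(0)), high = setNames(numeric(0), character(0))))
      }
      sub <- z[genes, use, drop = FALSE]
      list(
        low = rowMeans(sub[, l == "non_recurred", drop = FALSE]),
        high = rowMeans(sub[, l == "recurred", drop = FALSE])
      )
    })
  }
  base_cent <- centroids_for()
  out <- purrr::map_dfr(samples, function(id) {
    cent <- if (mode == "loo" && id %in% train_ids) centroids_for(exclude = id) else base_cent
    v <- purrr::map_chr(seq_along(css$signatures), function(s) {
      cl <- classify_one(z[, id], css$signatures[[s]], centroids = cent[[s]])
      cl %||% NA_character_
    })
    tibble::tibble(
      sample_id = id,
      k = sum(v == "high", na.rm = TRUE),
      s_effective = sum(!is.na(v)),
      votes = list(setNames(v, purrr::map_chr(css$signatures, "hallmark")))
    )
  })
  if (all(out$s_effective == 0L)) {
    abort("every signature abstained for every sample (genes missing from the expression matrix?).",
      class = "nogcss_pipeline_error"
    )
  }
  calls_from_votes(out, css$K_low, css$K_high, css$S)
}

#' Tidy the CSS cutoff grid
#'
#' @param x A `css_model`.
#' @param ... Unused.
#' @return The fit-report tibble (one row per candidate cutoff pair).
#' @export
tidy.css_model <- function(x, ...) x$fit_report

#' One-row summary of a fitted CSS model
#'
#' @param x A `css_model`.
#' @param ... Unused.
#' @return Tibble with the selected cutoffs and their testing-split metrics.
#' @export
glance.css_model <- function(x, ...) {
  x$fit_report |>
    dplyr::filter(.data$K_low == x$K_low, .data$K_high == x$K_high) |>
    dplyr::mutate(n_signatures = x$S, .before = 1)
}
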