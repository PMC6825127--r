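#' Configuration for Multiple Survival Screening
#'
#' MSS extracts a fixed-size gene signature per cancer hallmark by repeated
#' randomization of genes and samples: each round draws `signature_size`
#' genes from the hallmark pool and a stratified `sample_fraction` of
#' training samples, and counts as a *hit* when the drawn gene set separates
#' recurred from non-recurred samples (two-sided rank-sum test on the
#' per-sample mean heating score over the drawn genes, p < `hit_alpha`,
#' with recurred samples hotter). Genes are ranked by how often they appear
#' in hit rounds.
#'
#' @param signature_size Genes per emitted signature (30, the published
#'   signature size).
#' @param n_rounds Randomization rounds per hallmark.
#' @param sample_fraction Fraction of training samples drawn per round,
#'   stratified by label.
#' @param hit_alpha Significance level for a round to count as a hit.
#' @param min_hits Minimum number of hit rounds for a hallmark to emit a
#'   signature (0 forces emission, useful for null studies).
#' @param statistic `"ranksum"` (default; heating scores are heavily
#'   right-skewed) or `"ttest"` (Welch).
#' @param rng_seed Integer seed making the screen reproducible.
#' @return An `mss_config` list.
#' @export
mss_config <- function(signature_size = 30L,
                       n_rounds = 1000L,
                       sample_fraction = 0.8,
                       hit_alpha = 0.05,
                       min_hits = 50L,
                       statistic = c("ranksum", "ttest"),
                       rng_seed = 1L) {
  statistic <- match.arg(statistic)
  if (!(sample_fraction > 0 && sample_fraction <= 1)) {
    abort("`sample_fraction` must lie in (0, 1].", class = "nogcss_config_error")
  }
  if (signature_size < 1L) {
    abort("`signature_size` must be >= 1.", class = "nogcss_config_error")
  }
  structure(
    list(
      signature_size = as.integer(signature_size),
      n_rounds = as.integer(n_rounds),
      sample_fraction = sample_fraction,
      hit_alpha = hit_alpha,
      min_hits = as.integer(min_hits),
      statistic = statistic,
      rng_seed = as.integer(rng_seed)
    ),
    class = "mss_config"
  )
}

# Wilcoxon rank-sum, normal approximation with tie correction and continuity
# correction; matches stats::wilcox.test(exact = FALSE, correct = TRUE).
# Returns two-sided p and the location direction (mean rank difference).
ranksum_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nties <- table(r)
  N <- n1 + n2
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(nties^3 - nties) / (N * (N - 1))))
  if (sigma == 0) {
    return(list(p = 1, delta = 0))
  }
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sigma
  list(p = 2 * pnorm(-abs(z)), delta = U - mu)
}

check_labels <- function(labels) {
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("sample_id", "label") %in% names(labels)))
  bad <- setdiff(unique(labels$label), c("recurred", "non_recurred"))
  if (length(bad)) {
    abort(sprintf("labels must be 'recurred'/'non_recurred'; saw %s", toString(bad)),
      class = "nogcss_validation_error"
    )
  }
  labels
}

# align a labels tibble with the heat-matrix columns, requiring both classes
aligned_classes <- function(scores, labels) {
  labels <- check_labels(labels)
  ids <- intersect(colnames(scores), labels$sample_id)
  lab <- labels$label[match(ids, labels$sample_id)]
  rec <- ids[lab == "recurred"]
  non <- ids[lab == "non_recurred"]
  if (length(rec) == 0L || length(non) == 0L) {
    abort("both label classes must be present among the scored samples.",
      class = "nogcss_validation_error"
    )
  }
  list(recurred = rec, non_recurred = non)
}

#' Screen one hallmark gene set for a NOG signature
#'
#' Runs the MSS randomization (see [mss_config()]) over one hallmark's gene
#' pool and emits the `signature_size` most frequent genes among hit rounds,
#' ties broken by gene symbol, provided the total hit count reaches
#' `min_hits`. Returns `NULL` (with a warning for an undersized pool) when no
#' signature can be emitted.
#'
#' @param heat A `heat_matrix` from [build_heat_matrix()] (training columns).
#' @param labels Tibble with `sample_id` and `label`
#'   (`"recurred"`/`"non_recurred"`).
#' @param hallmark_genes Character vector: the hallmark's gene pool.
#' @param config An [mss_config()].
#' @param hallmark Name recorded on the signature.
#' @return A `nog_signature` (with centroids fitted on the training split)
#'   or `NULL`.
#' @export
screen_hallmark <- function(heat, labels, hallmark_genes,
                            config = mss_config(), hallmark = "hallmark") {
  scores <- heat$scores
  pool <- intersect(toupper(hallmark_genes), rownames(scores))
  if (length(pool) < config$signature_size) {
    warn(sprintf(
      "hallmark '%s': pool (%d genes on the network) smaller than signature size %d; skipped.",
      hallmark, length(pool), config$signature_size
    ))
    return(NULL)
  }
  cls <- aligned_classes(scores, labels)
  n_rec <- max(1L, round(config$sample_fraction * length(cls$recurred)))
  n_non <- max(1L, round(config$sample_fraction * length(cls$non_recurred)))

  sub <- scores[pool, c(cls$recurred, cls$non_recurred), drop = FALSE]
  rec_idx <- seq_along(cls$recurred)
  non_idx <- length(cls$recurred) + seq_along(cls$non_recurred)

  withr::local_seed(config$rng_seed)
  hit_count <- setNames(integer(length(pool)), pool)
  n_hits <- 0L
  for (round_i in seq_len(config$n_rounds)) {
    g <- sample.int(length(pool), config$signature_size)
    sr <- rec_idx[sample.int(length(rec_idx), n_rec)]
    sn <- non_idx[sample.int(length(non_idx), n_non)]
    m <- colMeans(sub[g, c(sr, sn), drop = FALSE])
    x <- m[seq_len(n_rec)]
    y <- m[n_rec + seq_len(n_non)]
    if (config$statistic == "ranksum") {
      rs <- ranksum_p(x, y)
      p <- rs$p
      up <- rs$delta > 0
    } else {
      tt <- t.test(x, y)
      p <- tt$p.value
      up <- tt$estimate[1] > tt$estimate[2]
    }
    # a hit must separate in the recurrence direction (recurred hotter):
    # keeps the null hit rate well below hit_alpha
    if (!is.na(p) && p < config$hit_alpha && up) {
      n_hits <- n_hits + 1L
      hit_count[g] <- hit_count[g] + 1L
    }
  }
  if (n_hits < config$min_hits) {
    return(NULL)
  }
  ord <- order(-hit_count, names(hit_count))
  genes <- names(hit_count)[ord][seq_len(config$signature_size)]
  sig <- structure(
    list(
      hallmark = hallmark,
      genes = genes,
      gene_frequencies = hit_count[genes],
      n_hits = n_hits,
      n_rounds = config$n_rounds,
      centroid_low = NULL,
      centroid_high = NULL
    ),
    class = "nog_signature"
  )
  fit_centroids(heat, labels, sig)
}

#' Fit low/high-risk centroids for a signature
#'
#' The centroid of a group is the per-gene arithmetic mean of the profile
#' (heating score or expression) over that group's training samples:
#' `centroid_low` over non-recurred, `centroid_high` over recurred.
#' Identical centroids are flagged with a warning because downstream
#' correlation classification degenerates.
#'
#' @param heat A `heat_matrix` or a plain genes-by-samples matrix.
#' @param labels Tibble with `sample_id`, `label`.
#' @param signature A `nog_signature`.
#' @return The signature with `centroid_low`/`centroid_high` filled in.
#' @export
fit_centroids <- function(heat, labels, signature) {
  scores <- if (inherits(heat, "heat_matrix")) heat$scores else heat
  missing <- setdiff(signature$genes, rownames(scores))
  if (length(missing)) {
    abort(sprintf("signature genes absent from the matrix: %s", toString(missing)),
      class = "nogcss_validation_error"
    )
  }
  cls <- aligned_classes(scores, labels)
  sub <- scores[signature$genes, , drop = FALSE]
  signature$centroid_low <- rowMeans(sub[, cls$non_recurred, drop = FALSE])
  signature$centroid_high <- rowMeans(sub[, cls$recurred, drop = FALSE])
  if (isTRUE(all.equal(signature$centroid_low, signature$centroid_high))) {
    warn(sprintf(
      "hallmark '%s': identical group centroids; correlation calls will degenerate.",
      signature$hallmark
    ))
  }
  signature
}

#' Discover NOG signatures across a hallmark collection
#'
#' Applies [screen_hallmark()] to every gene set in the collection. Each
#' hallmark screen gets its own deterministic seed derived from
#' `config$rng_seed`, so results do not depend on hallmark order.
#'
#' @param heat A `heat_matrix` (training columns).
#' @param labels Tibble with `sample_id`, `label`.
#' @param hallmark_collection Named list of gene-symbol vectors (e.g. read
#'   with [read_gmt()]).
#' @param config An [mss_config()].
#' @return A `nog_signature_set` (list of `nog_signature`s); errors if no
#'   hallmark emits a signature.
#' @export
discover_all <- function(heat, labels, hallmark_collection, config = mss_config()) {
  if (length(hallmark_collection) == 0L) {
    abort("empty hallmark collection.", class = "nogcss_validation_error")
  }
  if (is.null(names(hallmark_collection))) {
    names(hallmark_collection) <- paste0("HALLMARK_", seq_along(hallmark_collection))
  }
  sigs <- purrr::imap(hallmark_collection, function(genes, nm) {
    cfg_i <- config
    # per-hallmark seed: stable under collection reordering
    cfg_i$rng_seed <- (config$rng_seed + sum(utf8ToInt(nm)) * 131L) %% .Machine$integer.max
    screen_hallmark(heat, labels, genes, cfg_i, hallmark = nm)
  })
  sigs <- purrr::compact(sigs)
  if (length(sigs) == 0L) {
    abort(
      paste(
        "no hallmark reached the minimum hit count — the training heat",
        "matrix carries no recurrence signal at this configuration",
        "(check seeds per sample, n_rounds and min_hits)."
      ),
      class = "nogcss_pipeline_error"
    )
  }
  structure(sigs, class = "nog_signature_set")
}

#' @export
print.nog_signature <- function(x, ...) {
  cat(sprintf(
    "<nog_signature> %s: %d genes, %d/%d hit rounds\n",
    x$hallmark, length(x$genes), x$n_hits, x$n_rounds
  ))
  invisible(x)
}

#' @export
print.nog_signature_set <- function(x, ...) {
  cat(sprintf("<nog_signature_set> %d signatures\n", length(x)))
  for (s in x) {
    cat(sprintf(
      "  %s (%d genes, %d hits)\n", s$hallmark, length(s$genes),
      s$n_hits
    ))
  }
  invisible(x)
}

#' Tidy a NOG signature (or set) into a gene-level tibble
#'
#' @param x A `nog_signature` or `nog_signature_set`.
#' @param ... Unused.
#' @return Tibble with `hallmark`, `rank`, `gene`, `hit_count`,
#'   `centroid_low`, `centroid_high`.
#' @export
tidy.nog_signature <- function(x, ...) {
  tibble::tibble(
    hallmark = x$hallmark,
    rank = seq_along(x$genes),
    gene = x$genes,
    hit_count = as.integer(x$gene_frequencies),
    centroid_low = unname(x$centroid_low),
    centroid_high = unname(x$centroid_high)
  )
}

#' @rdname tidy.nog_signature
#' @export
tidy.nog_signature_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' One-row summary per signature
#'
#' @param x A `nog_signature_set`.
#' @param ... Unused.
#' @return Tibble with `hallmark`, `n_genes`, `n_hits`, `n_rounds`,
#'   `hit_rate`.
#' @export
glance.nog_signature_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), function(s) {
    tibble::tibble(
      hallmark = s$hallmark, n_genes = length(s$genes),
      n_hits = s$n_hits, n_rounds = s$n_rounds,
      hit_rate = s$n_hits / s$n_rounds
    )
  })
}
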