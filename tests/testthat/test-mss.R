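test_that("the internal rank-sum test matches wilcox.test to 1e-10", {
  withr::local_seed(11)
  for (i in 1:100) {
    n1 <- sample(3:40, 1)
    n2 <- sample(3:40, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, mean = runif(1, -1, 1))
    if (i %% 3 == 0) { # force heavy ties
      x <- round(x)
      y <- round(y)
    }
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    got <- nogcss:::ranksum_p(x, y)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("a degenerate pool with a forced hit returns the pool in lexicographic order", {
  genes <- sprintf("G%02d", 30:1) # deliberately unsorted
  n <- 20
  ids <- sprintf("S%02d", 1:n)
  lab <- tibble::tibble(
    sample_id = ids,
    label = rep(c("recurred", "non_recurred"), each = n / 2)
  )
  # recurred samples uniformly hotter: every round separates in direction
  scores <- matrix(rep(c(2, 1), each = 30 * n / 2), 30, n,
    dimnames = list(genes, ids)
  )
  scores <- scores + matrix(rnorm(30 * n, sd = 0.01), 30, n)
  hm <- structure(
    list(scores = scores, seed_indicator = scores * 0, excluded = character()),
    class = "heat_matrix"
  )
  sig <- screen_hallmark(hm, lab, genes,
    mss_config(n_rounds = 1, min_hits = 1, sample_fraction = 1),
    hallmark = "DEGENERATE"
  )
  expect_equal(sig$genes, sort(genes))
  expect_equal(length(sig$genes), 30L)
  expect_equal(sig$n_hits, 1L)
})

test_that("pools smaller than the signature size are skipped with a warning", {
  hm <- small_heat()
  lab <- cohort_labels(small_cohort(), "train")
  expect_warning(
    out <- screen_hallmark(hm, lab, sprintf("G%04d", 1:10),
      mss_config(signature_size = 30),
      hallmark = "TINY"
    ),
    "smaller than signature size"
  )
  expect_null(out)
})

test_that("shuffled labels destroy signatures", {
  # within one shuffle every round reuses the same wrong labels, so null
  # screens are all-or-nothing: a few shuffles separate persistently by
  # chance. The destroying property is the contrast against true labels at
  # the full study scale.
  dd <- default_cohort_heat()
  cfg <- function(seed) mss_config(n_rounds = 300, min_hits = 15, rng_seed = seed)
  emit <- function(labels, seed) {
    sum(vapply(names(dd$cohort$hallmark_sets), function(h) {
      !is.null(suppressWarnings(screen_hallmark(
        dd$heat, labels, dd$cohort$hallmark_sets[[h]], cfg(seed), hallmark = h
      )))
    }, logical(1)))
  }
  n_hm <- length(dd$cohort$hallmark_sets)
  true_emitted <- emit(dd$labels, 1)
  withr::local_seed(8)
  null_emitted <- vapply(1:3, function(rep) {
    shuffled <- dd$labels
    shuffled$label <- sample(shuffled$label)
    emit(shuffled, rep * 100)
  }, numeric(1))
  expect_gte(true_emitted, 0.8 * n_hm)
  expect_lte(sum(null_emitted), 0.4 * 3 * n_hm)
})

test_that("screening is deterministic under its seed", {
  co <- small_cohort()
  hm <- subset_heat(small_heat(), cohort_labels(co, "train")$sample_id)
  lab <- cohort_labels(co, "train")
  cfg <- mss_config(n_rounds = 200, min_hits = 0, rng_seed = 5)
  h <- names(co$hallmark_sets)[1]
  a <- screen_hallmark(hm, lab, co$hallmark_sets[[h]], cfg, hallmark = h)
  b <- screen_hallmark(hm, lab, co$hallmark_sets[[h]], cfg, hallmark = h)
  expect_identical(a$genes, b$genes)
  expect_identical(a$gene_frequencies, b$gene_frequencies)
})

test_that("centroids are per-gene class means", {
  genes <- c("A", "B", "C")
  ids <- c("R1", "R2", "N1")
  scores <- matrix(c(
    1, 2, 3, # R1
    3, 4, 5, # R2
    10, 20, 30 # N1
  ), nrow = 3, dimnames = list(genes, ids))
  lab <- tibble::tibble(
    sample_id = ids,
    label = c("recurred", "recurred", "non_recurred")
  )
  sig <- make_signature(genes, rep(0, 3), rep(0, 3))
  fitted <- fit_centroids(scores, lab, sig)
  expect_equal(fitted$centroid_high, c(A = 2, B = 3, C = 4))
  # a single sample per class: the centroid is that column
  expect_equal(fitted$centroid_low, c(A = 10, B = 20, C = 30))
  # identical class distributions degenerate with a warning
  lab2 <- tibble::tibble(sample_id = ids[1:2], label = c("recurred", "non_recurred"))
  same <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 3, dimnames = list(genes, ids[1:2]))
  expect_warning(fit_centroids(same, lab2, sig), "identical group centroids")
})

test_that("discover_all emits one deterministic signature set per informative cohort", {
  co <- small_cohort()
  hm <- subset_heat(small_heat(), cohort_labels(co, "train")$sample_id)
  lab <- cohort_labels(co, "train")
  cfg <- mss_config(n_rounds = 200, min_hits = 0, rng_seed = 1)
  sigs <- discover_all(hm, lab, co$hallmark_sets, cfg)
  expect_s3_class(sigs, "nog_signature_set")
  expect_true(all(vapply(sigs, function(s) length(s$genes), integer(1)) == 30L))
  # order of the collection does not change per-hallmark results
  sigs_rev <- discover_all(hm, lab, rev(co$hallmark_sets), cfg)
  g1 <- lapply(sigs, `[[`, "genes")
  g2 <- lapply(sigs_rev, `[[`, "genes")
  expect_identical(g1, g2[names(g1)])

  expect_error(discover_all(hm, lab, list(), cfg), class = "nogcss_validation_error")
})

test_that("uninformative heat yields a pipeline error at a strict hit floor", {
  co <- small_cohort()
  hm <- subset_heat(small_heat(), cohort_labels(co, "train")$sample_id)
  lab <- cohort_labels(co, "train")
  lab$label <- rep(c("recurred", "non_recurred"), length.out = nrow(lab))[order(runif(nrow(lab)))]
  withr::local_seed(2)
  lab$label <- sample(lab$label)
  expect_error(
    discover_all(hm, lab, co$hallmark_sets,
      mss_config(n_rounds = 100, min_hits = 90, rng_seed = 3)
    ),
    class = "nogcss_pipeline_error"
  )
})

test_that("tidy and glance expose signature tables", {
  co <- small_cohort()
  hm <- subset_heat(small_heat(), cohort_labels(co, "train")$sample_id)
  lab <- cohort_labels(co, "train")
  sigs <- memo("small_sigs", discover_all(hm, lab, co$hallmark_sets,
    mss_config(n_rounds = 200, min_hits = 0, rng_seed = 1)
  ))
  td <- tidy(sigs)
  expect_equal(nrow(td), 30L * length(sigs))
  expect_named(
    td,
    c("hallmark", "rank", "gene", "hit_count", "centroid_low", "centroid_high")
  )
  gl <- glance(sigs)
  expect_equal(nrow(gl), length(sigs))
  expect_true(all(gl$hit_rate >= 0 & gl$hit_rate <= 1))
})
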