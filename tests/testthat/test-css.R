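toy_signature <- function() {
  make_signature(
    genes = c("A", "B", "C", "D"),
    centroid_low = c(1, 2, 3, 4),
    centroid_high = c(4, 3, 2, 1)
  )
}

test_that("nearest-centroid calls follow the Pearson correlations", {
  sig <- toy_signature()
  expect_equal(classify_one(c(A = 4, B = 3, C = 2, D = 1), sig), "high")
  expect_equal(classify_one(c(A = 1, B = 2, C = 3, D = 4), sig), "low")
  # hand-checked toy: r(profile, low) and r(profile, high) computed with the
  # explicit product-moment formula
  p <- c(A = 2, B = 1, C = 4, D = 3)
  r_hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expected <- if (r_hand(p, sig$centroid_high) > r_hand(p, sig$centroid_low)) "high" else "low"
  expect_equal(classify_one(p, sig), expected)
})

test_that("exact correlation ties resolve to low risk", {
  # profile equidistant from two mirrored centroids
  sig <- make_signature(c("A", "B"), centroid_low = c(0, 1), centroid_high = c(1, 0))
  expect_equal(classify_one(c(A = 1, B = 2), sig), "low")
})

test_that("degenerate profiles abstain", {
  sig <- toy_signature()
  expect_true(is.na(classify_one(c(A = 1, B = 1, C = 1, D = 1), sig))) # zero variance
  five <- make_signature(c("A", "B", "C", "D", "E"), 1:5, 5:1)
  expect_true(is.na(classify_one(c(A = 1, B = 2), five))) # >50% genes missing
  flat <- make_signature(c("A", "B"), centroid_low = c(1, 1), centroid_high = c(0, 2))
  expect_true(is.na(classify_one(c(A = 1, B = 2), flat))) # flat centroid
})

test_that("calls are invariant to positive affine rescaling of the profile", {
  sig <- toy_signature()
  withr::local_seed(4)
  for (i in 1:20) {
    p <- setNames(rnorm(4), c("A", "B", "C", "D"))
    a <- runif(1, 0.1, 10)
    b <- rnorm(1)
    expect_identical(classify_one(p, sig), classify_one(a * p + b, sig))
  }
})

# build profiles whose votes are fully determined: samples equal to one of
# the centroids of every signature
separable_fixture <- function(S = 4, n_rec = 6, n_non = 14) {
  genes <- sprintf("g%02d", 1:(4 * S))
  sigs <- lapply(1:S, function(s) {
    gs <- genes[(4 * (s - 1) + 1):(4 * s)]
    make_signature(gs,
      centroid_low = c(1, 2, 3, 4), centroid_high = c(4, 3, 2, 1),
      hallmark = paste0("H", s)
    )
  })
  ids <- sprintf("T%02d", 1:(n_rec + n_non))
  labels <- tibble::tibble(
    sample_id = ids,
    label = rep(c("recurred", "non_recurred"), c(n_rec, n_non))
  )
  profiles <- vapply(seq_along(ids), function(i) {
    unlist(lapply(sigs, function(sg) {
      if (labels$label[i] == "recurred") sg$centroid_high else sg$centroid_low
    }))
  }, numeric(4 * S))
  rownames(profiles) <- genes
  colnames(profiles) <- ids
  list(signatures = do.call(as_signature_set, sigs), profiles = profiles, labels = labels)
}

test_that("perfectly separable votes select the widest full-range cutoffs", {
  fx <- separable_fixture(S = 4)
  css <- fit_css(fx$signatures, fx$profiles, fx$labels)
  expect_equal(css$K_low, 0)
  expect_equal(css$K_high, 4)
  best <- glance(css)
  expect_equal(best$low_accuracy, 100)
  expect_equal(best$high_accuracy, 100)
  expect_equal(best$coverage, 1)
})

test_that("the cutoff grid enumerates all K_low < K_high pairs", {
  fx <- separable_fixture(S = 3)
  css <- fit_css(fx$signatures, fx$profiles, fx$labels)
  expect_equal(nrow(css$fit_report), choose(3 + 1, 2)) # 6 pairs for S = 3
})

test_that("vote-band semantics drive prediction", {
  fx <- separable_fixture(S = 4)
  css <- fit_css(fx$signatures, fx$profiles, fx$labels)
  css$K_low <- 1
  css$K_high <- 3
  pred <- predict(css, fx$profiles)
  expect_true(all(pred$k[pred$call == "low"] <= 1))
  expect_true(all(pred$k[pred$call == "high"] >= 3))
  expect_true(all(pred$k >= 0 & pred$k <= pred$s_effective))
  # mixed profile: 2 of 4 signatures vote high -> inside the band
  mixed <- fx$profiles[, 1]
  mixed[1:8] <- rep(c(1, 2, 3, 4), 2) # first two signatures now look low
  pm <- predict(css, matrix(mixed, ncol = 1, dimnames = list(names(mixed), "MIX")))
  expect_equal(pm$k, 2L)
  expect_equal(pm$call, "unpredicted")
})

test_that("abstaining signatures rescale the cutoffs instead of forcing low", {
  fx <- separable_fixture(S = 4)
  css <- fit_css(fx$signatures, fx$profiles, fx$labels)
  css$K_low <- 1
  css$K_high <- 3
  # a high-risk sample missing one signature's genes entirely:
  # k = 3 of s_effective = 3, scaled cutoffs floor(1*3/4+0.5)=1 /
  # max(2, floor(3*3/4+.5)=2) -> high
  p <- fx$profiles[, 1]
  p[1:4] <- NA
  pred <- predict(css, matrix(p, ncol = 1, dimnames = list(names(p), "AB")))
  expect_equal(pred$s_effective, 3L)
  expect_equal(pred$k, 3L)
  expect_equal(pred$call, "high")
})

test_that("fit_css refuses non-testing splits and degenerate labels", {
  fx <- separable_fixture(S = 3)
  bad <- dplyr::mutate(fx$labels, split = "train")
  expect_error(fit_css(fx$signatures, fx$profiles, bad),
    class = "nogcss_validation_error"
  )
  one_class <- dplyr::mutate(fx$labels, label = "recurred")
  expect_error(fit_css(fx$signatures, fx$profiles, one_class),
    class = "nogcss_validation_error"
  )
})

test_that("expression classification reuses gene lists with expression centroids", {
  fx <- separable_fixture(S = 3, n_rec = 8, n_non = 12)
  css <- fit_css(fx$signatures, fx$profiles, fx$labels)
  # expression matrix: training samples define centroids; two held-out
  # samples equal to the class means must classify accordingly
  train <- fx$profiles + matrix(rnorm(length(fx$profiles), sd = 0.01), nrow(fx$profiles))
  colnames(train) <- fx$labels$sample_id
  hi <- rowMeans(train[, fx$labels$label == "recurred"])
  lo <- rowMeans(train[, fx$labels$label == "non_recurred"])
  expr <- cbind(train, V_HI = hi, V_LO = lo)
  out <- classify_expression(css, expr, fx$labels, samples = c("V_HI", "V_LO"))
  expect_equal(out$call[out$sample_id == "V_HI"], "high")
  expect_equal(out$call[out$sample_id == "V_LO"], "low")
  expect_equal(out$s_effective, c(3L, 3L))
  # leave-one-out over training samples runs and calls every sample
  loo <- classify_expression(css, expr, fx$labels,
    samples = fx$labels$sample_id[1:4], mode = "loo"
  )
  expect_equal(nrow(loo), 4L)
})

test_that("expression matrices missing all signature genes are an error state", {
  fx <- separable_fixture(S = 3)
  css <- fit_css(fx$signatures, fx$profiles, fx$labels)
  other <- matrix(rnorm(5 * nrow(fx$labels) + 5),
    nrow = 5,
    dimnames = list(paste0("x", 1:5), c(fx$labels$sample_id, "V1"))
  )
  expect_error(
    classify_expression(css, other, fx$labels, samples = "V1"),
    class = "nogcss_pipeline_error"
  )
})

test_that("tidy/glance report the grid and chosen cutoffs", {
  fx <- separable_fixture(S = 3)
  css <- fit_css(fx$signatures, fx$profiles, fx$labels)
  expect_identical(tidy(css), css$fit_report)
  gl <- glance(css)
  expect_equal(gl$n_signatures, 3L)
  expect_equal(nrow(gl), 1L)
})
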