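# shared fixtures, built once per session and memoised

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a small cohort with clear planted signal, cheap enough for unit tests
small_config <- function(rng_seed = 7) {
  synthetic_config(
    n_genes = 150, n_hallmarks = 3, hallmark_size = 35, n_planted = 12,
    n_train = 40, n_test = 20, n_valid = 20, p_recur = 0.3,
    rng_seed = rng_seed
  )
}

small_cohort <- function() memo("small_cohort", generate_cohort(small_config()))

small_heat <- function() {
  memo("small_heat", {
    co <- small_cohort()
    build_heat_matrix(co$network, seeds_per_sample(call_germline(co$variants)))
  })
}

# toy variant table builder
make_variants <- function(normal_vaf,
                          gene = paste0("GENE", seq_along(normal_vaf)),
                          sample_id = "S1",
                          tumor_vaf = 0.5,
                          ...) {
  n <- length(normal_vaf)
  tibble::tibble(
    sample_id = rep_len(sample_id, n),
    chrom = "1",
    pos = seq_len(n),
    ref = "A",
    alt = "T",
    gene = rep_len(gene, n),
    tumor_vaf = rep_len(tumor_vaf, n),
    normal_vaf = normal_vaf,
    ...
  )
}

# hand-built signature with explicit centroids
make_signature <- function(genes, centroid_low, centroid_high, hallmark = "TOY") {
  structure(
    list(
      hallmark = hallmark, genes = genes,
      gene_frequencies = setNames(rep(1L, length(genes)), genes),
      n_hits = 1L, n_rounds = 1L,
      centroid_low = setNames(centroid_low, genes),
      centroid_high = setNames(centroid_high, genes)
    ),
    class = "nog_signature"
  )
}

as_signature_set <- function(...) structure(list(...), class = "nog_signature_set")
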