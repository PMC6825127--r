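ONCOTYPE_UP <- c("GRB7", "ERBB2", "MKI67", "AURKA", "BIRC5", "CCNB1", "MYBL2", "CTSV", "MMP11")
ONCOTYPE_DOWN <- c("ESR1", "PGR", "BCL2", "SCUBE2")
ONCOTYPE_NEUTRAL <- c("CD68", "GSTM1", "BAG1", "ACTB", "GAPDH", "RPLP0", "GUSB", "TFRC")

# metagene profiles: the 8 leukocyte profiles reported as group-separated,
# plus null rows. Direction: negative = enriched in predicted low risk
# (non-recurred), as observed for all but memory B cells.
METAGENE_SHIFTS <- c(
  "MDSC" = -1, "E-Memory CD8" = -1, "DC+" = -1, "CD8+" = -1,
  "Tfh" = -1, "Monos" = -1, "Memory B" = 1, "B cell+" = -1,
  "gd T cells" = 0, "NK cells-" = 0, "MCs-" = 0, "Treg" = 0
)

hallmark_names <- function(n) {
  base <- c(
    "HALLMARK_APOPTOSIS", "HALLMARK_PROLIFERATION", "HALLMARK_CELL_CYCLE",
    "HALLMARK_ANGIOGENESIS", "HALLMARK_INVASION", "HALLMARK_IMMUNE_EVASION",
    "HALLMARK_METABOLISM", "HALLMARK_GENOME_INSTABILITY",
    "HALLMARK_GROWTH_SUPPRESSION", "HALLMARK_REPLICATIVE_IMMORTALITY",
    "HALLMARK_INFLAMMATION", "HALLMARK_EMT"
  )
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("HALLMARK_%02d", seq_len(n - length(base))))
}

neighbors_of <- function(network, genes) {
  e <- network$edges
  unique(c(
    e$gene_b[e$gene_a %in% genes],
    e$gene_a[e$gene_b %in% genes]
  ))
}

draw_vaf <- function(n, p, coverage_mean) {
  cov <- pmax(10L, stats::rpois(n, coverage_mean))
  rbinom(n, cov, p) / cov
}

random_variant_sites <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  tibble::tibble(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(5e7, n, replace = TRUE),
    ref = ref, alt = unname(alt)
  )
}

#' Generate a synthetic cohort for the full pipeline
#'
#' Simulates everything the recurrence pipeline consumes, with the
#' statistical structure it assumes:
#'
#' * a scale-free gene network ([generate_network()]) with `n_planted`
#'   recurrence-driver genes; the *informative pool* is the planted genes
#'   plus their first network neighbors, so that network propagation — not a
#'   raw mutation count — is what recovers the signal;
#' * hallmark gene sets that tile the informative pool (each informative
#'   gene is placed in two hallmark sets) and are filled up with
#'   uninformative genes;
#' * per-sample variant tables: functional germline variants hit each gene
#'   with probability `seed_rate_base / n_genes`, multiplied by
#'   `seed_enrichment` on informative genes in recurred samples; normal-VAF
#'   draws are binomial at depth ~`coverage_mean` around 0.5 (het), 1.0
#'   (hom), or 0.25 (somatic contaminants, ~20% of records), and
#'   non-functional germline variants carry benign annotation scores, so
#'   both the zygosity and the functional filter do real work;
#' * expression: standard-normal per gene, with informative genes shifted by
#'   `expr_shift` SD in recurred samples, plus the 21-gene Oncotype panel on
#'   a 0-15-like scale with recurrence-consistent shifts;
#' * clinical data: exponential disease-free survival at the group's hazard,
#'   censored by a uniform follow-up window capped at `censor_max`;
#'   age/stage/nodal covariates independent of the planted signal;
#' * leukocyte metagene profiles (the 8 reported cell types plus null rows)
#'   with group shifts, and a leukocyte gene list overlapping the
#'   informative pool.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort`: list with `network`, `hallmark_sets`,
#'   `planted_genes`, `informative_genes`, `variants` (one tibble, all
#'   samples), `expression`, `clinical`, `metagenes`, `leukocyte_genes`,
#'   and the `config`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   n_genes = 80, n_hallmarks = 2, hallmark_size = 20, n_planted = 5,
#'   n_train = 12, n_test = 6, n_valid = 6
#' ))
#' dplyr::count(cohort$clinical, split, label)
#' @export
generate_cohort <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  net_cfg <- config
  net_cfg$rng_seed <- config$rng_seed + 1L # keep network and cohort streams apart
  network <- generate_network(net_cfg)
  genes <- network$nodes

  withr::local_seed(config$rng_seed)

  # drivers form a connected module (degree-weighted snowball from a
  # well-connected start): recurrence drivers dysregulate a pathway, and a
  # cohesive module is what diffusion can reinforce
  deg <- setNames(network$degree, genes)
  mid <- names(deg)[deg >= stats::quantile(deg, 0.5) & deg <= stats::quantile(deg, 0.9)]
  planted <- sample(mid, 1L)
  while (length(planted) < config$n_planted) {
    nb <- setdiff(neighbors_of(network, planted), planted)
    # grow through low-degree neighbors: keeps the module cohesive without
    # swallowing the hubs' whole neighborhoods
    nb <- nb[deg[nb] <= stats::quantile(deg[nb], 0.75)] %||% nb
    if (length(nb) == 0L) nb <- setdiff(genes, planted)
    pick <- if (length(nb) == 1L) nb else sample(nb, 1L)
    planted <- c(planted, pick)
  }
  planted <- sort(planted)
  informative <- sort(unique(c(planted, neighbors_of(network, planted))))

  ## hallmark sets: each informative gene lands in 2 hallmarks, filled with
  ## uninformative genes (unique within a set; overlap across sets allowed)
  hm_names <- hallmark_names(config$n_hallmarks)
  slots <- sample(rep(seq_len(config$n_hallmarks), length.out = 2L * length(informative)))
  inf_shuffled <- rep(sample(informative), 2L)
  hallmark_sets <- lapply(seq_len(config$n_hallmarks), function(h) {
    unique(inf_shuffled[slots == h])
  })
  # fillers come from outside the two-hop neighborhood of the planted
  # drivers: diffusion leaks signal one hop past the mutation-enriched
  # genes, and filler genes are meant to be null
  near <- unique(c(informative, neighbors_of(network, informative)))
  far <- setdiff(genes, near)
  other <- setdiff(genes, informative)
  hallmark_sets <- lapply(hallmark_sets, function(hs) {
    hs <- utils::head(hs, config$hallmark_size)
    need <- config$hallmark_size - length(hs)
    if (need > 0) {
      pool_fill <- if (length(far) >= need) far else other
      hs <- c(hs, sample(pool_fill, min(need, length(pool_fill))))
    }
    sort(hs)
  })
  names(hallmark_sets) <- hm_names

  ## cohort labels and splits
  n_total <- config$n_train + config$n_test + config$n_valid
  sample_ids <- sprintf("S%04d", seq_len(n_total))
  split <- rep(c("train", "test", "valid"), c(config$n_train, config$n_test, config$n_valid))
  label <- ifelse(runif(n_total) < config$p_recur, "recurred", "non_recurred")
  # guard: every split needs both classes for screening/fitting/evaluation
  for (sp in unique(split)) {
    idx <- which(split == sp)
    for (cl in c("recurred", "non_recurred")) {
      short <- 2L - sum(label[idx] == cl)
      if (short > 0) {
        flip <- sample(idx[label[idx] != cl], short)
        label[flip] <- cl
      }
    }
  }

  ## variant tables
  p_base <- min(1, config$seed_rate_base / config$n_genes)
  p_inf_rec <- min(1, p_base * config$seed_enrichment)
  is_inf <- genes %in% informative
  variants <- purrr::map_dfr(seq_len(n_total), function(i) {
    p_gene <- if (label[i] == "recurred") ifelse(is_inf, p_inf_rec, p_base) else rep(p_base, length(genes))
    hit <- genes[runif(length(genes)) < p_gene]
    n_func <- length(hit)
    func <- if (n_func > 0) {
      zyg_hom <- runif(n_func) < 0.3
      dplyr::bind_cols(
        random_variant_sites(n_func),
        tibble::tibble(
          gene = hit,
          normal_vaf = draw_vaf(n_func, ifelse(zyg_hom, 1.0, 0.5), config$coverage_mean),
          tumor_vaf = draw_vaf(n_func, ifelse(zyg_hom, 1.0, 0.5), config$coverage_mean),
          cadd_phred = runif(n_func, 16, 45),
          mutation_taster = sample(c("disease_causing", "polymorphism"), n_func,
            replace = TRUE, prob = c(0.7, 0.3)
          ),
          cravat_p = runif(n_func, 0, 0.3)
        )
      )
    } else {
      NULL
    }
    # benign germline variants: right zygosity, no damaging evidence
    n_benign <- stats::rpois(1, config$seed_rate_base)
    benign <- if (n_benign > 0) {
      zyg_hom <- runif(n_benign) < 0.3
      dplyr::bind_cols(
        random_variant_sites(n_benign),
        tibble::tibble(
          gene = sample(genes, n_benign, replace = TRUE),
          normal_vaf = draw_vaf(n_benign, ifelse(zyg_hom, 1.0, 0.5), config$coverage_mean),
          tumor_vaf = draw_vaf(n_benign, ifelse(zyg_hom, 1.0, 0.5), config$coverage_mean),
          cadd_phred = runif(n_benign, 0, 12),
          mutation_taster = "polymorphism",
          cravat_p = runif(n_benign, 0.1, 1)
        )
      )
    } else {
      NULL
    }
    # somatic contaminants (~20% of records): subclonal VAF, fail the
    # zygosity gate even when annotated damaging
    n_som <- stats::rpois(1, 0.25 * (n_func + n_benign))
    somatic <- if (n_som > 0) {
      dplyr::bind_cols(
        random_variant_sites(n_som),
        tibble::tibble(
          gene = sample(genes, n_som, replace = TRUE),
          normal_vaf = draw_vaf(n_som, 0.25, config$coverage_mean),
          tumor_vaf = draw_vaf(n_som, 0.35, config$coverage_mean),
          cadd_phred = runif(n_som, 5, 40),
          mutation_taster = sample(c("disease_causing", "polymorphism"), n_som, replace = TRUE),
          cravat_p = runif(n_som, 0, 1)
        )
      )
    } else {
      NULL
    }
    out <- dplyr::bind_rows(func, benign, somatic)
    if (nrow(out) > 0) out$sample_id <- sample_ids[i]
    out
  })
  variants <- dplyr::relocate(variants, "sample_id")

  ## expression: network genes (z-scale) + Oncotype panel (0-15-like scale)
  rec <- label == "recurred"
  expr_net <- matrix(rnorm(length(genes) * n_total), length(genes), n_total,
    dimnames = list(genes, sample_ids)
  )
  expr_net[is_inf, rec] <- expr_net[is_inf, rec] + config$expr_shift
  # cancer genes sit ~8 units above the stable reference genes so the
  # published group floors (6.5 proliferation, 8 HER2) do not pin the score
  onco_genes <- c(ONCOTYPE_UP, ONCOTYPE_DOWN, ONCOTYPE_NEUTRAL)
  onco_mean <- ifelse(onco_genes %in% c("ACTB", "GAPDH", "RPLP0", "GUSB", "TFRC"), 8, 16)
  onco_sd <- ifelse(onco_genes %in% c("ACTB", "GAPDH", "RPLP0", "GUSB", "TFRC"), 0.3, 0.8)
  expr_onco <- matrix(
    rnorm(length(onco_genes) * n_total, mean = onco_mean, sd = onco_sd),
    length(onco_genes), n_total,
    dimnames = list(onco_genes, sample_ids)
  )
  expr_onco[ONCOTYPE_UP, rec] <- expr_onco[ONCOTYPE_UP, rec] + 0.8 * config$expr_shift
  expr_onco[ONCOTYPE_DOWN, rec] <- expr_onco[ONCOTYPE_DOWN, rec] - 0.8 * config$expr_shift
  expression <- rbind(expr_net, expr_onco)

  ## clinical: exponential DFS at the group hazard, uniform follow-up window
  hazard <- ifelse(rec, config$hazard_high, config$hazard_low)
  t_event <- rexp(n_total, hazard)
  t_censor <- pmin(config$censor_max, runif(n_total, 0.25, 1) * config$censor_max)
  clinical <- tibble::tibble(
    sample_id = sample_ids,
    split = split,
    label = label,
    dfs_months = pmin(t_event, t_censor),
    event = t_event <= t_censor,
    age = round(rnorm(n_total, 59, 10)),
    stage = sample(1:4, n_total, replace = TRUE, prob = c(0.20, 0.55, 0.20, 0.05)),
    nodal = sample(0:3, n_total, replace = TRUE, prob = c(0.45, 0.45, 0.07, 0.03))
  )

  ## leukocyte metagenes
  metagenes <- matrix(
    rnorm(length(METAGENE_SHIFTS) * n_total),
    length(METAGENE_SHIFTS), n_total,
    dimnames = list(names(METAGENE_SHIFTS), sample_ids)
  )
  metagenes[, rec] <- metagenes[, rec] + METAGENE_SHIFTS * (config$expr_shift / 2)

  ## leukocyte-expressed genes: half the informative pool + 10% of the rest
  leukocyte_genes <- sort(c(
    sample(informative, ceiling(length(informative) / 2)),
    sample(other, ceiling(length(other) / 10))
  ))

  structure(
    list(
      network = network,
      hallmark_sets = hallmark_sets,
      planted_genes = planted,
      informative_genes = informative,
      variants = variants,
      expression = expression,
      clinical = clinical,
      metagenes = metagenes,
      leukocyte_genes = leukocyte_genes,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d samples (%d recurred), %d genes, %d variants\n",
    nrow(x$clinical), sum(x$clinical$label == "recurred"),
    length(x$network$nodes), nrow(x$variants)
  ))
  cat(sprintf(
    "  planted drivers: %d (+%d neighbors informative); hallmarks: %d\n",
    length(x$planted_genes),
    length(x$informative_genes) - length(x$planted_genes),
    length(x$hallmark_sets)
  ))
  invisible(x)
}

#' Labels of one cohort split
#'
#' @param cohort A `synthetic_cohort`.
#' @param split `"train"`, `"test"` or `"valid"` (or several).
#' @return Tibble with `sample_id`, `label`, `split`.
#' @export
cohort_labels <- function(cohort, split = c("train", "test", "valid")) {
  dplyr::filter(
    cohort$clinical[, c("sample_id", "label", "split")],
    .data$split %in% .env$split
  )
}

#' Restrict a heat matrix to a set of samples
#'
#' @param heat A `heat_matrix`.
#' @param sample_ids Columns to keep (silently dropping absent ones).
#' @return A `heat_matrix` with the matching columns.
#' @export
subset_heat <- function(heat, sample_ids) {
  keep <- intersect(colnames(heat$scores), sample_ids)
  if (length(keep) == 0L) {
    abort("none of the requested samples are in the heat matrix.",
      class = "nogcss_validation_error"
    )
  }
  structure(
    list(
      scores = heat$scores[, keep, drop = FALSE],
      seed_indicator = heat$seed_indicator[, keep, drop = FALSE],
      excluded = heat$excluded
    ),
    class = "heat_matrix"
  )
}

#' Recovery of planted signal by discovered signatures
#'
#' For each emitted signature, the fraction of recoverable informative genes
#' it captured: `|signature ∩ informative| / min(signature_size,
#' |informative ∩ hallmark pool|)`. Informative genes are the planted
#' drivers and their first network neighbors — the genes whose germline
#' mutation probability is enriched in recurred samples.
#'
#' @param signatures A `nog_signature_set`.
#' @param cohort The `synthetic_cohort` the signatures were trained on.
#' @return Tibble with `hallmark`, `n_informative_pool`, `n_captured`,
#'   `recovery`.
#' @export
signature_recovery <- function(signatures, cohort) {
  purrr::map_dfr(unclass(signatures), function(s) {
    pool_inf <- sum(cohort$hallmark_sets[[s$hallmark]] %in% cohort$informative_genes)
    captured <- sum(s$genes %in% cohort$informative_genes)
    tibble::tibble(
      hallmark = s$hallmark,
      n_informative_pool = pool_inf,
      n_captured = captured,
      recovery = captured / min(length(s$genes), pool_inf)
    )
  })
}
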