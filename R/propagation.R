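#' Build a degree-normalized gene network
#'
#' Constructs the symmetric degree-normalized adjacency
#' \eqn{W = D^{-1/2} A D^{-1/2}} used by heat diffusion. Gene symbols are
#' upper-cased and matched exactly; self-loops are rejected; isolated nodes
#' (listed in `nodes` but absent from the edge list) are retained with zero
#' rows so their heating score stays zero unless they are seeds.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b` and optionally
#'   `weight` (default 1; must be positive).
#' @param nodes Optional character vector of gene symbols fixing the node set
#'   and order; defaults to the genes seen in `edges`.
#' @return A `gene_network`: list with `nodes` (gene symbols), `edges`
#'   (tibble), `W` (sparse symmetric normalized adjacency) and `degree`
#'   (weighted degrees).
#' @examples
#' tri <- tibble::tibble(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"))
#' net <- normalize_network(tri)
#' net$W["A", "B"] # 1/2: all degrees are 2
#' @export
normalize_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0L) {
    abort("edge list is empty.", class = "nogcss_validation_error")
  }
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort("`edges` needs columns `gene_a` and `gene_b`.",
      class = "nogcss_validation_error"
    )
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (any(is.na(edges$weight)) || any(edges$weight <= 0)) {
    abort("edge weights must be positive.", class = "nogcss_validation_error")
  }
  edges$gene_a <- toupper(edges$gene_a)
  edges$gene_b <- toupper(edges$gene_b)
  if (any(edges$gene_a == edges$gene_b)) {
    abort("self-loops are not allowed.", class = "nogcss_validation_error")
  }
  nodes <- if (is.null(nodes)) {
    sort(unique(c(edges$gene_a, edges$gene_b)))
  } else {
    toupper(nodes)
  }
  missing <- setdiff(unique(c(edges$gene_a, edges$gene_b)), nodes)
  if (length(missing)) {
    abort(sprintf("edge genes absent from `nodes`: %s", toString(missing[1:min(5, length(missing))])),
      class = "nogcss_validation_error"
    )
  }
  n <- length(nodes)
  i <- match(edges$gene_a, nodes)
  j <- match(edges$gene_b, nodes)
  A <- sparseMatrix(
    i = c(i, j), j = c(j, i), x = rep(edges$weight, 2),
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  D <- Diagonal(n, inv_sqrt)
  W <- D %*% A %*% D
  dimnames(W) <- list(nodes, nodes)
  structure(
    list(nodes = nodes, edges = edges, W = W, degree = as.numeric(d)),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d genes, %d edges (mean degree %.2f)\n",
    length(x$nodes), nrow(x$edges), mean(x$degree)
  ))
  invisible(x)
}

#' Configuration for network propagation
#'
#' Heat diffusion follows the random-walk-with-restart update
#' \eqn{F_{t+1} = \alpha W F_t + (1 - \alpha) F_0} on the symmetric
#' degree-normalized adjacency, iterated to its fixed point
#' \eqn{F = (1-\alpha)(I - \alpha W)^{-1} F_0}.
#'
#' @param alpha Diffusion retention in (0, 1): the fraction of heat passed to
#'   neighbors each step; `1 - alpha` flows back to the seeds.
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter Iteration cap (a guard; the map is a contraction for
#'   `alpha < 1`).
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(alpha = 0.7, tol = 1e-8, max_iter = 1000L) {
  if (!(alpha > 0 && alpha < 1)) {
    abort("`alpha` must lie strictly in (0, 1).", class = "nogcss_config_error")
  }
  if (tol <= 0) abort("`tol` must be positive.", class = "nogcss_config_error")
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
    class = "propagation_config"
  )
}

#' Diffuse seed genes over the network
#'
#' Starts from heat 1/|seeds| on each seed gene and iterates the
#' random-walk-with-restart update until the L1 change drops below `tol`.
#' Seeds absent from the network are dropped with a warning; if none remain
#' the sample is unseedable and an error of class
#' `nogcss_unseedable_error` is raised.
#'
#' @param network A `gene_network` from [normalize_network()].
#' @param seeds Character vector of seed gene symbols.
#' @param config A [propagation_config()].
#' @param renormalize Rescale the fixed point to sum to 1 (the default;
#'   `FALSE` returns the raw resolvent value, useful when studying the
#'   operator itself).
#' @return Named numeric vector of heating scores over `network$nodes`
#'   (renormalized to sum to 1).
#' @examples
#' net <- normalize_network(tibble::tibble(gene_a = "A", gene_b = "B"))
#' propagate(net, "A")
#' @export
propagate <- function(network, seeds, config = propagation_config(),
                      renormalize = TRUE) {
  f <- propagate_matrix(network, list(sample = seeds), config,
    renormalize = renormalize
  )
  drop(f$scores[, 1])
}

# shared worker: seeds_list is a named list of seed character vectors
propagate_matrix <- function(network, seeds_list, config = propagation_config(),
                             renormalize = TRUE) {
  stopifnot(inherits(network, "gene_network"))
  nodes <- network$nodes
  n <- length(nodes)
  keep <- character(0)
  f0_i <- integer(0)
  f0_j <- integer(0)
  f0_x <- numeric(0)
  dropped <- list()
  excluded <- character(0)
  col <- 0L
  for (nm in names(seeds_list)) {
    s <- unique(toupper(seeds_list[[nm]]))
    in_net <- s[s %in% nodes]
    lost <- setdiff(s, in_net)
    if (length(lost)) dropped[[nm]] <- lost
    if (length(in_net) == 0L) {
      excluded <- c(excluded, nm)
      next
    }
    col <- col + 1L
    keep <- c(keep, nm)
    f0_i <- c(f0_i, match(in_net, nodes))
    f0_j <- c(f0_j, rep(col, length(in_net)))
    f0_x <- c(f0_x, rep(1 / length(in_net), length(in_net)))
  }
  if (length(dropped)) {
    warn(sprintf(
      "%d seed gene(s) absent from the network were dropped (e.g. %s).",
      length(unlist(dropped)), toString(utils::head(unique(unlist(dropped)), 3))
    ))
  }
  if (col == 0L) {
    abort("no sample has any seed gene present in the network.",
      class = "nogcss_unseedable_error"
    )
  }
  F0 <- matrix(0, n, col, dimnames = list(nodes, keep))
  F0[cbind(f0_i, f0_j)] <- f0_x

  a <- config$alpha
  W <- network$W
  Fc <- F0
  restart <- (1 - a) * F0
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    Fn <- as.matrix(a * (W %*% Fc)) + restart
    if (max(colSums(abs(Fn - Fc))) < config$tol) {
      Fc <- Fn
      converged <- TRUE
      break
    }
    Fc <- Fn
  }
  if (!converged) {
    abort(sprintf("propagation did not converge within %d iterations.", config$max_iter),
      class = "nogcss_convergence_error"
    )
  }
  # columns of the symmetric-normalized walk are not mass-conserving;
  # renormalize so every sample column sums to 1 (cross-sample comparability)
  if (renormalize) {
    cs <- colSums(Fc)
    Fc <- sweep(Fc, 2, cs, "/")
  }
  list(scores = Fc, seed_indicator = F0, excluded = excluded, iterations = it)
}

#' Aggregate per-sample heating scores into a heat matrix
#'
#' Runs [propagate()] for every sample's seed set and collects the columns
#' into a genes-by-samples matrix. Samples with no seed gene on the network
#' are excluded and recorded (the analogue of patients without enough
#' germline variants to serve as network seeds).
#'
#' @param network A `gene_network`.
#' @param seeds A tibble with columns `sample_id` and `gene` (one row per
#'   seed gene per sample), as returned by [seeds_per_sample()], or a named
#'   list of gene vectors.
#' @param config A [propagation_config()].
#' @return A `heat_matrix`: list with `scores` (genes x samples), dense
#'   `seed_indicator` of the same shape, and `excluded` (unseedable sample
#'   ids).
#' @export
build_heat_matrix <- function(network, seeds, config = propagation_config()) {
  if (is.data.frame(seeds)) {
    stopifnot(all(c("sample_id", "gene") %in% names(seeds)))
    seeds <- split(seeds$gene, seeds$sample_id)
  }
  if (length(seeds) == 0L) {
    abort("no samples supplied.", class = "nogcss_pipeline_error")
  }
  res <- propagate_matrix(network, seeds, config)
  structure(
    list(
      scores = res$scores, seed_indicator = res$seed_indicator,
      excluded = res$excluded
    ),
    class = "heat_matrix"
  )
}

#' @export
print.heat_matrix <- function(x, ...) {
  cat(sprintf(
    "<heat_matrix> %d genes x %d samples (%d excluded as unseedable)\n",
    nrow(x$scores), ncol(x$scores), length(x$excluded)
  ))
  invisible(x)
}

#' Tidy a heat matrix into long form
#'
#' @param x A `heat_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample_id`, `heat`, `is_seed`.
#' @export
tidy.heat_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$scores), times = ncol(x$scores)),
    sample_id = rep(colnames(x$scores), each = nrow(x$scores)),
    heat = as.numeric(x$scores),
    is_seed = as.numeric(x$seed_indicator) > 0
  )
}
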