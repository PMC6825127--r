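#' Grow a scale-free gene network by preferential attachment
#'
#' Builds an undirected, connected, unit-weight network by Barabasi-Albert
#' growth: starting from `m = n_edges_per_node` seed nodes, each new node
#' attaches to `m` distinct existing nodes chosen with probability
#' proportional to their current degree (the first newcomer links to all seed
#' nodes, so the graph is connected). The grown graph has exactly
#' `m * (n_genes - m)` edges. Real recurrence signaling networks are
#' scale-free-like, and degree hubs give heat diffusion something to
#' concentrate on, which is why this topology is used for simulation.
#'
#' @param config A [synthetic_config()].
#' @return A `gene_network` object (see [normalize_network()]) with gene
#'   symbols `G0001`, `G0002`, ... and unit edge weights.
#' @examples
#' net <- generate_network(synthetic_config(n_genes = 50, rng_seed = 1))
#' nrow(net$edges) # 3 * (50 - 3)
#' @export
generate_network <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_genes
  m <- config$n_edges_per_node
  genes <- sprintf("G%04d", seq_len(n))

  withr::local_seed(config$rng_seed)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  # repeated-node urn: each endpoint occurrence = one degree unit
  urn <- integer(0)
  k <- 0L
  for (v in seq.int(m + 1L, n)) {
    if (length(urn) == 0L) {
      targets <- seq_len(m) # first newcomer wires to every seed node
    } else {
      targets <- integer(0)
      while (length(targets) < m) {
        cand <- urn[sample.int(length(urn), 1L)]
        if (!cand %in% targets) targets <- c(targets, cand)
      }
    }
    idx <- k + seq_len(m)
    from[idx] <- v
    to[idx] <- targets
    k <- k + m
    urn <- c(urn, rep(v, m), targets)
  }

  edges <- tibble::tibble(
    gene_a = genes[pmin(from, to)],
    gene_b = genes[pmax(from, to)],
    weight = 1
  )
  normalize_network(edges, nodes = genes)
}
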