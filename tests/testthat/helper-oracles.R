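# Independent oracles and small fixture builders shared across tests.

# Brute-force clustering centrality: enumerate neighbor pairs on a dense
# logical adjacency matrix. Independent of the package's sparse A^3 route.
oracle_centrality <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  nodes <- rownames(A)
  k <- integer(length(nodes)); E <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    nb <- which(A[i, ])
    k[i] <- length(nb)
    E[i] <- if (k[i] >= 2L) sum(A[nb, nb]) / 2L else 0L
  }
  data.frame(node = nodes, k = k, E = as.integer(E),
             C = ifelse(k >= 2L, 2 * E / (k * (k - 1)), 0),
             stringsAsFactors = FALSE)
}

# Two-sided Fisher exact p by direct hypergeometric summation: sum the
# probabilities of all tables no more likely than the observed one.
oracle_fisher_two_sided <- function(obs, K, N, n) {
  x <- max(0L, n - (N - K)):min(K, n)
  d <- dhyper(x, K, N - K, n)
  p_obs <- dhyper(obs, K, N - K, n)
  sum(d[d <= p_obs * (1 + 1e-7)])
}

# Minimal stage experiment from an explicit matrix and stage labels.
make_se <- function(values, stages, stage_order = unique(stages),
                    control_stages = stage_order[1L]) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(
      stage = factor(stages, levels = stage_order),
      is_control = stages %in% control_stages,
      row.names = colnames(values)))
  S4Vectors::metadata(se)$stage_order <- stage_order
  S4Vectors::metadata(se)$control_stages <- control_stages
  se
}

# Random simple graph with named nodes for property-style checks.
random_graph <- function(n, p = 0.05, seed = 1L) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  g
}

graph_from_pairs <- function(a, b) {
  igraph::graph_from_data_frame(data.frame(a = a, b = b),
                                directed = FALSE)
}
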