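# Independent brute-force oracles used to validate the fast implementations.

# Triple-loop topological overlap, straight from the definition.
tom_oracle <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- a[i, j]
      for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
      out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(adjacency)
  out
}

# Exhaustive weighted edge betweenness with fractional tie splitting:
# enumerate every simple path between every pair, find the tied set of
# minimum-weight paths, credit each path's edges 1/ties. Undirected graphs
# count unordered pairs; directed graphs ordered pairs.
betweenness_oracle <- function(graph, weights, tol = 1e-10) {
  directed <- igraph::is_directed(graph)
  n <- igraph::vcount(graph)
  scores <- numeric(igraph::ecount(graph))
  pairs <- if (directed) {
    expand.grid(from = seq_len(n), to = seq_len(n))
  } else {
    t(utils::combn(n, 2)) |> as.data.frame() |> setNames(c("from", "to"))
  }
  mode <- if (directed) "out" else "all"
  for (r in seq_len(nrow(pairs))) {
    from <- pairs$from[r]; to <- pairs$to[r]
    if (from == to) next
    paths <- suppressWarnings(
      igraph::all_simple_paths(graph, from = from, to = to, mode = mode))
    if (length(paths) == 0) next
    path_edges <- lapply(paths, function(p) {
      v <- as.integer(p)
      pairs_v <- rbind(v[-length(v)], v[-1])
      igraph::get_edge_ids(graph, as.vector(pairs_v), directed = directed)
    })
    # directed mode: drop vertex paths that traverse an arc that does not
    # exist in the required direction
    ok <- vapply(path_edges, function(e) all(e > 0), logical(1))
    paths <- paths[ok]; path_edges <- path_edges[ok]
    if (length(paths) == 0) next
    w <- vapply(path_edges, function(e) sum(weights[e]), numeric(1))
    best <- min(w)
    tied <- which(w <= best + tol * max(best, 1))
    for (t_i in tied) {
      scores[path_edges[[t_i]]] <- scores[path_edges[[t_i]]] + 1 / length(tied)
    }
  }
  scores
}

# Hypergeometric upper-tail by explicit summation of choose() products.
hyper_tail_oracle <- function(k, set_size, module_size, universe) {
  j <- k:min(set_size, module_size)
  sum(choose(set_size, j) * choose(universe - set_size, module_size - j)) /
    choose(universe, module_size)
}

# Random connected-ish undirected weighted graph for oracle comparisons.
random_test_graph <- function(n_nodes, p_edge = 0.35) {
  repeat {
    m <- matrix(runif(n_nodes^2) < p_edge, n_nodes, n_nodes)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(m + t(m), mode = "undirected")
    if (igraph::ecount(g) >= n_nodes - 1) return(g)
  }
}

# Benchmark synthetic spec used across tests (the study-scale conditions).
benchmark_spec <- function(seed = 1L) {
  synthetic_spec(seed = seed)
}

# Perturbation benchmark for differential connectivity: pure-noise
# expression so the doubled hub pair is the only condition difference.
perturbation_spec <- function(seed = 1L) {
  synthetic_spec(n_genes = 500, modules = list(), ppi_n_nodes = 200,
                 ppi_attach_m = 2, noise_sd = 0.3, seed = seed)
}

# Choose the perturbed "two hub genes": endpoints of the edge maximizing
# the smaller endpoint degree (ties: larger total degree).
hub_edge_of <- function(network) {
  deg <- igraph::degree(network$graph)
  el <- igraph::as_edgelist(network$graph)
  mins <- pmin(deg[el[, 1]], deg[el[, 2]])
  tot <- deg[el[, 1]] + deg[el[, 2]]
  unname(el[order(-mins, -tot)[1], ])
}

# Population betweenness scores for the perturbation benchmark: noise-free
# node weights are equal (unit) except perturbed nodes multiplied by the
# stated change.
population_betweenness <- function(network, perturbed = character(0),
                                   change = 1) {
  g <- network$graph
  w <- setNames(rep(1, igraph::vcount(g)), igraph::V(g)$name)
  w[perturbed] <- w[perturbed] * change
  ends <- igraph::ends(g, igraph::E(g))
  igraph::edge_betweenness(g, directed = FALSE,
                           weights = 1 / (w[ends[, 1]] * w[ends[, 2]]))
}

# One replicate of the planted differential-connectivity simulation.
# Returns sensitivity on the strongly-changed corridor, empirical FDR on
# clearly-null edges, hub membership and hub ranks of the perturbed pair.
run_perturbation_replicate <- function(seed, alpha = 0.1) {
  spec <- perturbation_spec(seed)
  ds <- generate_expression(spec)
  sim <- generate_ppi(spec, ds)
  hub_edge <- hub_edge_of(sim$network)
  pert <- list(list(edge = hub_edge, condition = "ad", change = 2))
  b0 <- population_betweenness(sim$network)
  b1 <- population_betweenness(sim$network, hub_edge, 2)
  d_pop <- b1 - b0
  thr <- mean(b0)
  corridor <- abs(d_pop) >= 2 * thr
  clear_null <- abs(d_pop) <= thr / 4
  ds_p <- perturb_dataset(ds, pert)
  wppi <- overlay_expression(sim$network, ds_p, mode = "per_sample")
  de <- differential_edges(wppi, "young", "ad", diff_threshold = thr,
                           alpha = alpha)
  sub <- extract_subnetworks(de)
  up_hubs <- sub$hubs$gene[sub$hubs$subnetwork == "up"]
  deg_up <- igraph::degree(sub$up)
  ranks <- rank(-deg_up, ties.method = "min")[hub_edge]
  list(sensitivity = mean(de$passes[corridor]),
       fdr = if (any(de$passes)) mean(clear_null[de$passes]) else 0,
       hubs_recovered = mean(hub_edge %in% up_hubs),
       hub_ranks = unname(ranks),
       n_corridor = sum(corridor))
}
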