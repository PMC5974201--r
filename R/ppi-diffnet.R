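#' Protein-protein interaction network container
#'
#' Stores an edge list (one row per interaction; bidirectional interactions
#' stored once with `directed = FALSE`) and the corresponding igraph graph.
#' Self-loops are removed and duplicate (source, target, directed) triples
#' deduplicated, with counts reported. In a network containing any directed
#' edge the graph is built directed, with each bidirectional interaction
#' expanded into two reciprocal arcs; an all-undirected edge list yields an
#' undirected graph.
#'
#' @param edges Data frame with columns `source`, `target`, `directed`
#'   (logical or 0/1).
#' @return A `ppi_network` object: `edges` (tibble), `graph` (igraph),
#'   `directed` (logical), `arc_map` (integer: graph edge -> edge row).
#' @export
ppi_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  req <- c("source", "target", "directed")
  if (!all(req %in% names(edges))) {
    abort("`edges` must have columns source, target, directed.")
  }
  edges$directed <- as.logical(edges$directed)
  loops <- edges$source == edges$target
  if (any(loops)) {
    inform(paste0("ppi_network: removed ", sum(loops), " self-loop(s)."))
    edges <- edges[!loops, ]
  }
  # canonical key so an undirected edge listed both ways deduplicates
  key <- ifelse(edges$directed,
                paste(edges$source, edges$target, "d"),
                paste(pmin(edges$source, edges$target),
                      pmax(edges$source, edges$target), "u"))
  dup <- duplicated(key)
  if (any(dup)) {
    inform(paste0("ppi_network: deduplicated ", sum(dup),
                  " repeated edge(s)."))
    edges <- edges[!dup, ]
  }
  any_directed <- any(edges$directed)
  if (any_directed) {
    fwd <- edges
    rev <- edges[!edges$directed, c("target", "source", "directed")]
    names(rev) <- c("source", "target", "directed")
    arcs <- dplyr::bind_rows(
      dplyr::mutate(fwd, .edge_row = dplyr::row_number()),
      dplyr::mutate(rev, .edge_row = which(!edges$directed)))
    g <- igraph::graph_from_data_frame(
      arcs[, c("source", "target")], directed = TRUE)
    arc_map <- arcs$.edge_row
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target")], directed = FALSE)
    arc_map <- seq_len(nrow(edges))
  }
  structure(list(edges = edges, graph = g, directed = any_directed,
                 arc_map = arc_map),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", igraph::vcount(x$graph), " nodes, ",
      nrow(x$edges), " edges (",
      if (x$directed) "mixed directed/bidirectional" else "undirected",
      ")\n", sep = "")
  invisible(x)
}

#' Read a PPI network from an edge-list TSV or GraphML file
#'
#' The TSV format is 3 columns: `source`, `target`, `directed` (0/1 or
#' TRUE/FALSE). Unparseable rows are reported with their line numbers.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"graphml"`.
#' @return A [ppi_network()].
#' @export
read_ppi <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g)
    edges <- tibble::tibble(source = el[, 1], target = el[, 2],
                            directed = igraph::is_directed(g))
    return(ppi_network(edges))
  }
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             source = readr::col_character(),
                             target = readr::col_character(),
                             directed = readr::col_logical()))
  probs <- readr::problems(edges)
  bad <- which(is.na(edges$source) | is.na(edges$target) |
                 is.na(edges$directed))
  if (nrow(probs) > 0 || length(bad) > 0) {
    lines <- sort(unique(c(probs$row + 1, bad + 1)))
    abort(paste0("Unparseable edge row(s) at line(s): ",
                 paste(lines, collapse = ", ")))
  }
  ppi_network(edges)
}

#' Write a PPI network to a 3-column edge-list TSV
#'
#' @param network A [ppi_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(network, path) {
  readr::write_tsv(network$edges, path)
  invisible(path)
}

#' Overlay condition-specific expression on a PPI network
#'
#' Intersects the network's nodes with the dataset's genes (nodes without
#' expression are dropped along with their edges, with a message) and
#' attaches positive node weights `N_i`: the normalized linear-scale signal
#' intensity, either averaged per group (`group_mean`) or kept per sample
#' (`per_sample`). Log-scale input is exponentiated (`2^x`) before
#' weighting. The induced edge weight is `W_ij = 1 / (N_i * N_j)`.
#'
#' @param network A [ppi_network()].
#' @param dataset An [expression_dataset()] with a `group` metadata column.
#' @param mode `"group_mean"` (one weight vector per condition) or
#'   `"per_sample"` (one per sample).
#' @param scale `"log2"` (default; exponentiated to linear intensity) or
#'   `"linear"` (used as-is; must be positive).
#' @return A `weighted_ppi` object: `network` (subnetwork over expressed
#'   nodes), `node_weights` (nodes x conditions or nodes x samples matrix),
#'   `mode`, `sample_groups` (per-sample mode), `group_means` (nodes x
#'   conditions, always present for direction calls).
#' @export
overlay_expression <- function(network, dataset,
                               mode = c("group_mean", "per_sample"),
                               scale = c("log2", "linear")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  stopifnot(inherits(network, "ppi_network"),
            inherits(dataset, "expression_dataset"))
  nodes <- igraph::V(network$graph)$name
  common <- intersect(nodes, rownames(dataset$expr))
  if (length(common) == 0) {
    abort("No overlap between network nodes and dataset genes.")
  }
  if (length(common) < length(nodes)) {
    keep <- network$edges$source %in% common &
      network$edges$target %in% common
    inform(paste0("overlay_expression: dropped ",
                  length(nodes) - length(common),
                  " node(s) without expression and ", sum(!keep),
                  " incident edge(s)."))
    network <- ppi_network(network$edges[keep, ])
    common <- intersect(igraph::V(network$graph)$name, common)
  }
  lin <- dataset$expr[common, , drop = FALSE]
  if (scale == "log2") lin <- 2^lin
  if (any(lin <= 0)) abort("Linear-scale intensities must be positive.")
  groups <- dataset$samples$group
  conditions <- unique(groups)
  group_means <- vapply(conditions, function(g) {
    rowMeans(lin[, groups == g, drop = FALSE])
  }, numeric(nrow(lin)))
  rownames(group_means) <- common
  node_weights <- if (mode == "group_mean") group_means else lin
  structure(list(network = network, node_weights = node_weights,
                 mode = mode,
                 sample_groups = if (mode == "per_sample") groups else NULL,
                 group_means = group_means),
            class = "weighted_ppi")
}

#' @export
print.weighted_ppi <- function(x, ...) {
  cat("<weighted_ppi> ", igraph::vcount(x$network$graph), " nodes, ",
      nrow(x$network$edges), " edges; ", x$mode, " weights over ",
      ncol(x$node_weights), " condition(s)/sample(s)\n", sep = "")
  invisible(x)
}

# Edge distances 1/(N_i N_j) for one weight column, aligned to graph arcs.
arc_distances <- function(wppi, column) {
  n <- wppi$node_weights[, column]
  g <- wppi$network$graph
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  1 / (n[ends[, 1]] * n[ends[, 2]])
}

#' Weighted edge-betweenness centrality under one condition
#'
#' Edge weights act as distances (`W_ij = 1/(N_i N_j)`, so highly expressed
#' pairs are cheap to traverse); the score of an edge is the number of
#' weighted shortest paths passing through it, with fractional attribution
#' when several shortest paths tie. Node pairs are ordered for directed
#' networks and unordered for undirected ones; for a mixed network each
#' bidirectional interaction's score is the sum over its two reciprocal
#' arcs.
#'
#' @param wppi A [overlay_expression()] result.
#' @param condition Column of the weight matrix (condition name in
#'   `group_mean` mode, sample id in `per_sample` mode).
#' @return Tibble: `source`, `target`, `directed`, `betweenness`.
#' @export
edge_betweenness_scores <- function(wppi, condition) {
  if (!condition %in% colnames(wppi$node_weights)) {
    abort(paste0("Unknown condition/sample '", condition, "'."))
  }
  b_arc <- igraph::edge_betweenness(
    wppi$network$graph, directed = wppi$network$directed,
    weights = arc_distances(wppi, condition))
  b <- as.numeric(tapply(b_arc, wppi$network$arc_map, sum))
  dplyr::mutate(wppi$network$edges, betweenness = b)
}

#' Detect differentially connected edges between two conditions
#'
#' In `per_sample_test` mode (default; requires `per_sample` overlay
#' weights) each edge's betweenness is computed in every sample's weighted
#' network, and a two-sample Welch t-test compares the per-sample score
#' distributions between the two groups, with Benjamini-Hochberg
#' adjustment across edges. Per-sample betweenness is heavy-tailed
#' (shortest paths reroute between samples), so by default the t-test is
#' applied to `log(1 + score)` (variance stabilization;
#' `log_scores = FALSE` tests the raw scores). The reported score means
#' and `delta` are always on the raw scale, as is the difference
#' threshold. An edge passes when `|delta| >= diff_threshold`
#' (or the top `1 - diff_threshold` quantile of `|delta|` when
#' `threshold_type = "percentile"`) AND the adjusted p is below `alpha`.
#' In `global_paired` mode the two condition-level score vectors (group-mean
#' weights) are compared by a single paired t-test across all edges,
#' reported as a whole-network statistic (attribute `global_test`), and
#' per-edge passing uses the difference threshold alone.
#'
#' Direction: `up` when both endpoints' mean expression increases going
#' a -> b, `down` when both decrease, else `mixed`. The endpoint-product
#' change `delta_product = N_i(b) N_j(b) - N_i(a) N_j(a)` (the quantity the
#' edge-weight inverts) is reported for resolving mixed edges.
#'
#' @param wppi A [overlay_expression()] result.
#' @param condition_a,condition_b Group labels to contrast (delta is b - a).
#' @param diff_threshold Absolute betweenness-difference threshold (the
#'   whole-network convention of the original analysis is an absolute
#'   difference of 2000) or a quantile probability under
#'   `threshold_type = "percentile"`.
#' @param alpha Adjusted-p cutoff.
#' @param mode `"per_sample_test"` or `"global_paired"`.
#' @param threshold_type `"absolute"` or `"percentile"`.
#' @param log_scores Test `log(1 + betweenness)` instead of raw scores in
#'   `per_sample_test` mode (default TRUE).
#' @return Tibble of class `differential_edge_table`: `source`, `target`,
#'   `directed`, `bet_mean_a`, `bet_mean_b`, `delta`, `statistic`,
#'   `p.value`, `adj.p.value`, `passes`, `direction`, `delta_product`.
#'   Attributes record conditions, mode, the pair-counting convention and
#'   the resolved threshold.
#' @export
differential_edges <- function(wppi, condition_a, condition_b,
                               diff_threshold = 2000, alpha = 0.05,
                               mode = c("per_sample_test", "global_paired"),
                               threshold_type = c("absolute", "percentile"),
                               log_scores = TRUE) {
  mode <- match.arg(mode)
  threshold_type <- match.arg(threshold_type)
  edges <- wppi$network$edges
  gm <- wppi$group_means
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% colnames(gm)) {
      abort(paste0("Unknown condition '", cond, "'."))
    }
  }
  global_test <- NULL
  if (mode == "per_sample_test") {
    if (wppi$mode != "per_sample") {
      abort("per_sample_test mode requires overlay_expression(mode = 'per_sample').")
    }
    groups <- wppi$sample_groups
    samples_a <- colnames(wppi$node_weights)[groups == condition_a]
    samples_b <- colnames(wppi$node_weights)[groups == condition_b]
    bet <- vapply(c(samples_a, samples_b), function(s) {
      edge_betweenness_scores(wppi, s)$betweenness
    }, numeric(nrow(edges)))
    ba <- bet[, samples_a, drop = FALSE]
    bb <- bet[, samples_b, drop = FALSE]
    na <- ncol(ba); nb <- ncol(bb)
    ma <- rowMeans(ba); mb <- rowMeans(bb)
    delta <- mb - ma
    ta <- if (log_scores) log1p(ba) else ba
    tb <- if (log_scores) log1p(bb) else bb
    tma <- rowMeans(ta); tmb <- rowMeans(tb)
    va <- apply(ta, 1, var); vb <- apply(tb, 1, var)
    se2 <- va / na + vb / nb
    tdelta <- tmb - tma
    stat <- ifelse(se2 > 0, tdelta / sqrt(se2), ifelse(tdelta == 0, 0, Inf))
    df <- ifelse(se2 > 0,
                 se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
                 na + nb - 2)
    p <- ifelse(is.finite(stat), 2 * pt(-abs(stat), df = df),
                ifelse(stat == 0, 1, 0))
    p[se2 == 0 & tdelta == 0] <- 1
    adj <- p.adjust(p, method = "BH")
  } else {
    if (wppi$mode != "group_mean") {
      abort("global_paired mode requires overlay_expression(mode = 'group_mean').")
    }
    ma <- edge_betweenness_scores(wppi, condition_a)$betweenness
    mb <- edge_betweenness_scores(wppi, condition_b)$betweenness
    delta <- mb - ma
    global_test <- tryCatch(stats::t.test(mb, ma, paired = TRUE),
                            error = function(e) NULL)
    stat <- rep(NA_real_, nrow(edges))
    p <- rep(NA_real_, nrow(edges))
    adj <- rep(NA_real_, nrow(edges))
  }
  thr <- if (threshold_type == "percentile") {
    unname(quantile(abs(delta), diff_threshold))
  } else diff_threshold
  passes <- abs(delta) >= thr & if (mode == "per_sample_test")
    !is.na(adj) & adj < alpha else TRUE
  d_src <- gm[edges$source, condition_b] - gm[edges$source, condition_a]
  d_tgt <- gm[edges$target, condition_b] - gm[edges$target, condition_a]
  direction <- dplyr::case_when(
    d_src > 0 & d_tgt > 0 ~ "up",
    d_src < 0 & d_tgt < 0 ~ "down",
    TRUE ~ "mixed")
  delta_product <- gm[edges$source, condition_b] *
    gm[edges$target, condition_b] -
    gm[edges$source, condition_a] * gm[edges$target, condition_a]
  out <- dplyr::mutate(edges,
    bet_mean_a = unname(ma), bet_mean_b = unname(mb),
    delta = unname(delta), statistic = unname(stat),
    p.value = unname(p), adj.p.value = unname(adj),
    passes = unname(passes), direction = direction,
    delta_product = unname(delta_product))
  class(out) <- c("differential_edge_table", class(out))
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  attr(out, "mode") <- mode
  attr(out, "pair_convention") <-
    if (wppi$network$directed) "ordered" else "unordered"
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  attr(out, "global_test") <- global_test
  out
}

#' @export
glance.differential_edge_table <- function(x, ...) {
  gt <- attr(x, "global_test")
  tibble::tibble(
    condition_a = attr(x, "conditions")[["a"]],
    condition_b = attr(x, "conditions")[["b"]],
    mode = attr(x, "mode"),
    n_edges = nrow(x),
    n_passing = sum(x$passes),
    threshold = attr(x, "threshold"),
    pair_convention = attr(x, "pair_convention"),
    global_statistic = if (is.null(gt)) NA_real_ else unname(gt$statistic),
    global_p = if (is.null(gt)) NA_real_ else gt$p.value)
}

#' Extract up- and downregulated subnetworks with hub genes
#'
#' Passing edges with direction `up` (plus `mixed` edges whose
#' endpoint-product change is positive) form the upregulated subnetwork;
#' the downregulated subnetwork is built analogously. Within each
#' subnetwork, hub genes are the nodes whose degree reaches the 95th
#' percentile of that subnetwork's degree distribution, ranked by
#' decreasing degree with lexicographic tie-breaking.
#'
#' @param table A [differential_edges()] result.
#' @return List: `up` and `down` (igraph graphs, possibly empty) and
#'   `hubs` (tibble: `subnetwork`, `gene`, `degree`, `rank`).
#' @export
extract_subnetworks <- function(table) {
  passing <- table[table$passes, , drop = FALSE]
  pick <- function(side) {
    sel <- passing$direction == side |
      (passing$direction == "mixed" &
         (if (side == "up") passing$delta_product > 0
          else passing$delta_product < 0))
    sub <- passing[sel, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(igraph::make_empty_graph(0, directed = FALSE))
    }
    igraph::graph_from_data_frame(sub[, c("source", "target")],
                                  directed = FALSE)
  }
  up <- pick("up")
  down <- pick("down")
  hub_tab <- function(g, name) {
    if (igraph::vcount(g) == 0) {
      return(tibble::tibble(subnetwork = character(), gene = character(),
                            degree = numeric(), rank = integer()))
    }
    deg <- igraph::degree(g)
    # empirical (type-1) quantile: degree distributions are discrete and
    # interpolated cutoffs can exclude genuinely top-ranked nodes
    cut <- quantile(deg, 0.95, type = 1)
    hubs <- deg[deg >= cut]
    ord <- order(-hubs, names(hubs))
    tibble::tibble(subnetwork = name, gene = names(hubs)[ord],
                   degree = unname(hubs)[ord],
                   rank = seq_along(hubs))
  }
  list(up = up, down = down,
       hubs = dplyr::bind_rows(hub_tab(up, "up"), hub_tab(down, "down")))
}
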