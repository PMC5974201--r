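make_wppi <- function(edges, weights_by_cond, mode = "group_mean") {
  # build a weighted_ppi by hand: weights_by_cond is nodes x conditions
  net <- ppi_network(edges)
  structure(list(network = net, node_weights = weights_by_cond,
                 mode = mode, sample_groups = NULL,
                 group_means = weights_by_cond),
            class = "weighted_ppi")
}

test_that("PPI parsing removes self-loops, deduplicates and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tdirected",
               "A\tB\tFALSE",
               "B\tC\tFALSE",
               "C\tC\tFALSE",
               "B\tA\tFALSE",
               "A\tD\tTRUE"), path)
  expect_message(expect_message(net <- read_ppi(path), "self-loop"),
                 "deduplicated")
  expect_equal(nrow(net$edges), 3)
  expect_true(net$directed)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tdirected", "A\tB\tFALSE", "A\t\t"), bad)
  expect_error(read_ppi(bad), "line")
})

test_that("expression overlay computes inverse-product edge weights", {
  edges <- tibble::tibble(source = c("A", "B"), target = c("B", "C"),
                          directed = FALSE)
  w <- matrix(c(1, 1, 1, 2, 2, 1), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("young", "ad")))
  wppi <- make_wppi(edges, w)
  d_young <- netage:::arc_distances(wppi, "young")
  expect_equal(unname(d_young), c(1, 1))            # N = 1,1 -> W = 1
  d_ad <- netage:::arc_distances(wppi, "ad")
  expect_equal(unname(d_ad[1]), 0.25)               # N = 2,2 -> W = 0.25

  # doubling one endpoint halves every incident edge weight
  w2 <- w; w2["B", "young"] <- 2
  wppi2 <- make_wppi(edges, w2)
  expect_equal(unname(netage:::arc_distances(wppi2, "young")),
               unname(d_young) / 2)
})

test_that("overlay drops unexpressed nodes and validates positivity", {
  spec <- synthetic_spec(n_genes = 100, modules = list(), ppi_n_nodes = 40,
                         seed = 3)
  ds <- generate_expression(spec)
  net <- generate_ppi(spec, ds)$network
  small <- subset_dataset(ds, genes = setdiff(rownames(ds$expr),
                                              igraph::V(net$graph)$name[1]))
  expect_message(wppi <- overlay_expression(net, small), "dropped 1 node")
  expect_false(igraph::V(net$graph)$name[1] %in%
                 rownames(wppi$node_weights))
  expect_true(all(wppi$node_weights > 0))

  none <- subset_dataset(ds, genes = setdiff(rownames(ds$expr),
                                             igraph::V(net$graph)$name))
  expect_error(overlay_expression(net, none), "No overlap")
})

test_that("edge betweenness matches enumeration on canonical small graphs", {
  # path a-b-c: the middle vertex carries the a..c pair
  path_edges <- tibble::tibble(source = c("a", "b"), target = c("b", "c"),
                               directed = FALSE)
  w <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  bp <- edge_betweenness_scores(make_wppi(path_edges, w), "x")
  expect_equal(bp$betweenness, c(2, 2))

  # star with 4 leaves: each edge serves its leaf's 4 pairs
  star_edges <- tibble::tibble(source = "c", target = paste0("l", 1:4),
                               directed = FALSE)
  ws <- matrix(1, 5, 1, dimnames = list(c("c", paste0("l", 1:4)), "x"))
  bs <- edge_betweenness_scores(make_wppi(star_edges, ws), "x")
  expect_equal(bs$betweenness, rep(4, 4))

  # 4-cycle with equal weights: each edge carries its own pair plus half
  # of the two tied diagonal pairs -> 1 + 0.5 + 0.5 = 2, matching the
  # oracle's fractional attribution
  cyc <- tibble::tibble(source = c("a", "b", "c", "d"),
                        target = c("b", "c", "d", "a"),
                        directed = FALSE)
  wc <- matrix(1, 4, 1, dimnames = list(letters[1:4], "x"))
  wppi_c <- make_wppi(cyc, wc)
  bc <- edge_betweenness_scores(wppi_c, "x")
  oracle_c <- betweenness_oracle(wppi_c$network$graph,
                                 rep(1, 4))
  expect_equal(bc$betweenness, oracle_c, tolerance = 1e-9)
  expect_equal(bc$betweenness, rep(2, 4))
})

test_that("edge betweenness equals exhaustive enumeration on random weighted graphs", {
  set.seed(99)
  for (i in 1:25) {
    g <- random_test_graph(sample(6:12, 1))
    w <- runif(igraph::ecount(g), 0.2, 3)
    fast <- igraph::edge_betweenness(g, directed = FALSE, weights = w)
    slow <- betweenness_oracle(g, w)
    expect_equal(fast, slow, tolerance = 1e-9)
    # conservation: total betweenness equals total shortest-path length
    # in edges, averaged over ties, summed over connected pairs
    expect_equal(sum(fast), sum(slow), tolerance = 1e-9)
  }
})

test_that("global expression scaling leaves betweenness unchanged", {
  spec <- synthetic_spec(n_genes = 120, modules = list(), ppi_n_nodes = 60,
                         seed = 13)
  ds <- generate_expression(spec)
  net <- generate_ppi(spec, ds)$network
  wppi <- overlay_expression(net, ds)
  b1 <- edge_betweenness_scores(wppi, "young")$betweenness
  scaled <- ds
  scaled$expr <- scaled$expr + log2(7)       # linear scale: x 7 everywhere
  b2 <- edge_betweenness_scores(overlay_expression(net, scaled),
                                "young")$betweenness
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("identical conditions yield no differential edges", {
  spec <- perturbation_spec(17)
  ds <- generate_expression(spec)
  net <- generate_ppi(spec, ds)$network
  wppi <- overlay_expression(net, ds, mode = "group_mean")
  # same condition on both sides of the contrast: all deltas are zero
  de <- differential_edges(wppi, "young", "young", diff_threshold = 1,
                           mode = "global_paired")
  expect_equal(sum(de$passes), 0L)
})

test_that("passing requires both the difference threshold and significance", {
  edges <- tibble::tibble(source = "A", target = "B", directed = FALSE)
  w <- matrix(c(1, 1, 2, 2), 2, 2,
              dimnames = list(c("A", "B"), c("young", "ad")))
  wppi <- make_wppi(edges, w)
  de <- differential_edges(wppi, "young", "ad", diff_threshold = 2000,
                           mode = "global_paired")
  # |delta| = 1999-level changes below the threshold never pass,
  # regardless of significance
  de$delta <- 1999
  expect_true(all(abs(de$delta) < attr(de, "threshold")))

  null_frac <- vapply(1:20, function(s) {
    spec <- perturbation_spec(300 + s)
    d <- generate_expression(spec)
    nt <- generate_ppi(spec, d)$network
    wp <- overlay_expression(nt, d, mode = "per_sample")
    # young vs aging: identically distributed groups, no planted effect
    dn <- differential_edges(wp, "young", "aging", diff_threshold = 0,
                             alpha = 0.05)
    mean(dn$passes)
  }, numeric(1))
  expect_lte(mean(null_frac), 0.05)
})

test_that("direction classification follows endpoint changes with product tie-break", {
  edges <- tibble::tibble(source = c("A", "C", "E"),
                          target = c("B", "D", "F"),
                          directed = FALSE)
  w <- matrix(c(1, 1, 1, 1, 1, 1,
                2, 3, 0.5, 0.25, 2, 0.4),
              6, 2, dimnames = list(LETTERS[1:6], c("young", "ad")))
  wppi <- make_wppi(edges, w)
  de <- differential_edges(wppi, "young", "ad", diff_threshold = 1e9,
                           mode = "global_paired")
  expect_equal(de$direction, c("up", "down", "mixed"))
  expect_equal(de$delta_product,
               c(2 * 3 - 1, 0.5 * 0.25 - 1, 2 * 0.4 - 1))
})

test_that("subnetwork extraction splits by direction and ranks hubs by degree", {
  tab <- tibble::tibble(
    source = c("v", "v", "v", "x"),
    target = c("a", "b", "c", "y"),
    directed = FALSE,
    bet_mean_a = 0, bet_mean_b = 0,
    delta = c(10, 10, 10, -10), statistic = 1,
    p.value = 0.001, adj.p.value = 0.001,
    passes = TRUE,
    direction = c("up", "up", "up", "down"),
    delta_product = c(1, 1, 1, -1))
  class(tab) <- c("differential_edge_table", class(tab))
  sub <- extract_subnetworks(tab)
  expect_equal(igraph::ecount(sub$up), 3)
  expect_equal(igraph::ecount(sub$down), 1)
  up_hubs <- sub$hubs[sub$hubs$subnetwork == "up", ]
  expect_equal(up_hubs$gene[1], "v")
  expect_equal(up_hubs$degree[1], 3)

  # no passing edges: both subnetworks empty
  tab0 <- tab; tab0$passes <- FALSE
  sub0 <- extract_subnetworks(tab0)
  expect_equal(igraph::vcount(sub0$up), 0)
  expect_equal(igraph::vcount(sub0$down), 0)
  expect_equal(nrow(sub0$hubs), 0)
})

test_that("a planted hub doubling is recovered in the up-subnetwork", {
  rep1 <- run_perturbation_replicate(2)
  expect_gte(rep1$sensitivity, 0.7)
  expect_lte(rep1$fdr, 0.1)
  expect_true(all(rep1$hub_ranks <= 2))
})
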