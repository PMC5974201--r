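test_that("signed similarity maps correlation endpoints per the linear transform", {
  x <- seq_len(8)
  mat <- rbind(a = x, b = 2 * x + 3, c = -x, d = rep(c(1, 2), 4))
  colnames(mat) <- paste0("s", 1:8)
  ds <- expression_dataset(mat + 0, data.frame(sample_id = colnames(mat)))
  s <- signed_similarity(ds)
  expect_equal(s["a", "b"], 1)            # cor = +1
  expect_equal(s["a", "c"], 0)            # cor = -1
  expect_equal(unname(diag(s)), rep(1, 4))
  expect_true(all(s >= 0 & s <= 1))

  # uncorrelated pair sits at the 0.5 midpoint (construct exactly)
  m2 <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  colnames(m2) <- paste0("s", 1:4)
  ds2 <- expression_dataset(m2, data.frame(sample_id = colnames(m2)))
  expect_equal(signed_similarity(ds2)["a", "b"], 0.5)

  const <- rbind(a = rep(1, 5), b = rnorm(5))
  colnames(const) <- paste0("s", 1:5)
  ds3 <- expression_dataset(const, data.frame(sample_id = colnames(const)))
  expect_error(signed_similarity(ds3), "a")
})

test_that("scale-free index scores an exact power law high and a regular graph undefined", {
  # connectivities drawn from a truncated Pareto law p(k) ~ k^-2.5 on
  # [1, 30], dense enough that every bin is populated
  set.seed(123)
  u <- runif(20000)
  a <- 2.5; kmin <- 1; kmax <- 30
  k <- (kmin^(1 - a) + u * (kmax^(1 - a) - kmin^(1 - a)))^(1 / (1 - a))
  sf <- scale_free_index(k, n_bins = 10)
  expect_false(sf$flagged)
  expect_gte(sf$r_squared, 0.9)
  expect_lt(sf$slope, 0)

  reg <- scale_free_index(rep(7, 100), n_bins = 10)
  expect_true(reg$flagged)
  expect_true(is.na(reg$r_squared))

  # increasing degree law gets a negative signed score
  inc <- scale_free_index(rep(seq(1, 10), times = seq(1, 10)), n_bins = 5)
  expect_lt(inc$r_squared, 0)
})

test_that("mean connectivity strictly decreases with the soft-threshold power", {
  set.seed(1)
  m <- matrix(runif(30 * 8), 30, 8,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:8)))
  s <- signed_similarity(expression_dataset(m, data.frame(sample_id = colnames(m))))
  fit <- scale_free_fit(s, powers = 1:12)
  expect_true(all(diff(fit$mean_k) < 0))
})

test_that("power selection takes the lowest passing power or the saturation knee", {
  rec <- function(power, r2) tibble::tibble(power = power, r_squared = r2,
                                            slope = -1, mean_k = 1,
                                            median_k = 1, max_k = 1,
                                            flagged = FALSE)
  fit <- rbind(rec(6, 0.5), rec(12, 0.82), rec(18, 0.85))
  p <- select_power(fit, r2_threshold = 0.8)
  expect_equal(as.integer(p), 12L)
  expect_false(attr(p, "fallback"))

  # plateau below threshold: knee where later gains stay under 0.01
  fit2 <- rbind(rec(6, 0.3), rec(12, 0.6), rec(18, 0.7), rec(24, 0.705),
                rec(30, 0.702))
  expect_message(p2 <- select_power(fit2, r2_threshold = 0.8), "knee")
  expect_equal(as.integer(p2), 18L)
  expect_true(attr(p2, "fallback"))

  expect_equal(as.integer(select_power(rec(9, 0.9))), 9L)
  expect_error(select_power(rec(9, NA)[0, ]), "No valid")
})

test_that("topological overlap matches hand arithmetic and the triple-loop oracle", {
  # empty network: no overlap anywhere
  a0 <- diag(3)
  expect_equal(topological_overlap(a0), diag(3))

  # full triangle: TOM_12 = (1 + 1) / (2 + 1 - 1) = 1
  a1 <- matrix(1, 3, 3)
  expect_equal(topological_overlap(a1), matrix(1, 3, 3))

  set.seed(42)
  for (i in 1:20) {
    n <- 15
    s <- matrix(runif(n * n), n, n)
    a <- (s + t(s)) / 2
    diag(a) <- 1
    expect_equal(topological_overlap(a), tom_oracle(a), tolerance = 1e-12)
  }
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("two well-separated planted blocks are recovered almost perfectly", {
  spec <- synthetic_spec(n_genes = 400,
                         modules = list(module_spec(200, 0.8, c(0, 1, 2)),
                                        module_spec(200, 0.8, c(0, -1, -2))),
                         seed = 4)
  ds <- generate_expression(spec)
  s <- signed_similarity(ds)
  mods <- cluster_modules(topological_overlap(adjacency_matrix(s, 6)),
                          power = 6)
  expect_equal(sum(mods$sizes$module > 0), 2L)
  truth <- attr(ds, "truth")$module_labels[names(mods$labels)]
  expect_gte(mclust::adjustedRandIndex(mods$labels, truth), 0.95)
})

test_that("pure noise leaves at least 90% of genes unassigned", {
  spec <- synthetic_spec(n_genes = 600, modules = list(), seed = 5)
  ds <- generate_expression(spec)
  s <- signed_similarity(ds)
  mods <- cluster_modules(topological_overlap(adjacency_matrix(s, 12)),
                          power = 12)
  expect_gte(mean(mods$labels == 0), 0.9)
})

test_that("a block below the minimum module size yields no modules", {
  spec <- synthetic_spec(n_genes = 300,
                         modules = list(module_spec(100, 0.8)), seed = 6)
  ds <- generate_expression(spec)
  s <- signed_similarity(ds)
  mods <- cluster_modules(topological_overlap(adjacency_matrix(s, 8)),
                          min_module_size = 150, power = 8)
  expect_equal(sum(mods$sizes$module > 0), 0L)

  tiny <- topological_overlap(adjacency_matrix(s[1:20, 1:20], 8))
  expect_warning(m2 <- cluster_modules(tiny, min_module_size = 150),
                 "Fewer genes")
  expect_true(all(m2$labels == 0))
})

test_that("module eigengenes recover planted latents up to sign and unit variance", {
  spec <- synthetic_spec(n_genes = 200,
                         modules = list(module_spec(80, 0.8, c(0, 1, 2))),
                         seed = 7)
  ds <- generate_expression(spec)
  truth <- attr(ds, "truth")
  me <- module_eigengenes(ds, truth$module_labels)
  expect_equal(rownames(me), "M1")
  expect_equal(sd(me["M1", ]), 1)
  expect_gte(abs(cor(me["M1", ], truth$latents[1, ])), 0.95)

  # flipping all genes leaves the recovery unchanged in magnitude
  flipped <- ds
  labels <- truth$module_labels
  flipped$expr[labels == 1, ] <- -flipped$expr[labels == 1, ]
  me_f <- module_eigengenes(flipped, labels)
  expect_equal(abs(cor(me_f["M1", ], truth$latents[1, ])),
               abs(cor(me["M1", ], truth$latents[1, ])), tolerance = 1e-10)

  # identical profiles: ME equals the common standardized profile
  prof <- rnorm(10)
  m <- matrix(rep(prof, each = 4), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  ds_r1 <- expression_dataset(m, data.frame(sample_id = colnames(m)))
  me1 <- module_eigengenes(ds_r1, setNames(rep(1L, 4), rownames(m)))
  expect_equal(unname(me1[1, ]), as.numeric(scale(prof)), tolerance = 1e-8)
})

test_that("module-trait correlation handles exact, orthogonal and planted cases", {
  stage <- rep(c(0, 1, 2), times = c(17, 21, 18))
  ids <- sprintf("s%02d", seq_along(stage))
  traits <- tibble::tibble(sample_id = ids, stage = stage)
  me <- rbind(M1 = stage / sd(stage))
  colnames(me) <- ids
  res <- module_trait_correlation(me, traits)
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_lt(res$p.value, 1e-10)

  # orthogonal eigengene: zero correlation
  orth <- rep(c(1, -1), length.out = length(stage))
  orth <- residuals(lm(orth ~ stage))
  me2 <- rbind(M1 = orth / sd(orth))
  colnames(me2) <- ids
  expect_equal(module_trait_correlation(me2, traits)$estimate, 0,
               tolerance = 1e-10)

  expect_error(module_trait_correlation(
    me, tibble::tibble(sample_id = ids, flat = rep(1, length(ids)))),
    "zero variance")
})

test_that("a planted monotone stage shift is detected with high power", {
  hits <- vapply(1:100, function(s) {
    spec <- synthetic_spec(n_genes = 60,
                           modules = list(module_spec(50, 0.7, c(0, 1, 2))),
                           seed = 500 + s)
    ds <- generate_expression(spec)
    me <- module_eigengenes(ds, attr(ds, "truth")$module_labels)
    res <- module_trait_correlation(me, encode_traits(ds))
    row <- res[res$trait == "stage", ]
    row$estimate > 0 && row$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("intramodular connectivity ranks the hub of a star module first", {
  set.seed(8)
  n <- 21
  center <- rnorm(20)
  leaves <- vapply(1:20, function(i) center + rnorm(20, sd = 2),
                   numeric(20))
  mat <- rbind(hub = center, t(leaves))
  rownames(mat) <- c("hub", sprintf("leaf%02d", 1:20))
  colnames(mat) <- paste0("s", 1:20)
  ds <- expression_dataset(mat, data.frame(sample_id = colnames(mat)))
  a <- adjacency_matrix(signed_similarity(ds), 6)
  labels <- setNames(rep(1L, n), rownames(mat))
  hubs <- intramodular_hubs(a, labels)
  expect_equal(hubs$gene[1], "hub")
  expect_true(all(hubs$kim <= n - 1))     # kim bounded by module size - 1

  # two-gene module: both members share the same kim
  two <- intramodular_hubs(a[1:2, 1:2], setNames(c(1L, 1L), rownames(a)[1:2]))
  expect_equal(two$kim[1], two$kim[2])
})

test_that("tidy and glance summarize a module set", {
  spec <- synthetic_spec(n_genes = 300,
                         modules = list(module_spec(150, 0.85, c(0, 1, 2))),
                         seed = 9)
  ds <- generate_expression(spec)
  s <- signed_similarity(ds)
  mods <- cluster_modules(topological_overlap(adjacency_matrix(s, 8)),
                          power = 8)
  td <- tidy(mods)
  expect_named(td, c("gene", "module"))
  expect_equal(nrow(td), 300)
  gl <- glance(mods)
  expect_equal(gl$n_genes, 300)
  expect_true(gl$prop_unassigned >= 0 && gl$prop_unassigned <= 1)
})
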