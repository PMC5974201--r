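#' Empirical-Bayes moderated t-test between two groups
#'
#' Per gene, the pooled two-group residual variance `s_g^2` (with
#' `d_g = n_a + n_b - 2` df) is shrunk toward a prior: the prior degrees of
#' freedom `d_0` and prior variance `s_0^2` are estimated by
#' moment-matching the scaled-F distribution of the `s_g^2` on the log
#' scale, the posterior variance is
#' `(d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)`, and the moderated t statistic
#' `(mean_b - mean_a) / (s_post sqrt(1/n_a + 1/n_b))` is referred to a t
#' distribution on `d_0 + d_g` df. Benjamini-Hochberg adjustment is applied
#' across genes.
#'
#' @param dataset An [expression_dataset()] (log2 scale) with a `group`
#'   metadata column.
#' @param group_a,group_b Group labels to contrast; the log2 fold change is
#'   `mean(group_b) - mean(group_a)` (the change going a -> b).
#' @param prior_df,prior_var Optional overrides of the estimated prior
#'   (e.g. `prior_df = Inf` forces the fully moderated limit where every
#'   gene uses the prior variance).
#' @return Tibble of class `deg_table`: `gene`, `contrast`, `log2_fc`,
#'   `statistic`, `df`, `p.value`, `adj.p.value`; attributes `prior_df`,
#'   `prior_var`.
#' @export
moderated_ttest <- function(dataset, group_a, group_b, prior_df = NULL,
                            prior_var = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  groups <- dataset$samples$group
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    abort("Need at least 2 samples per group.")
  }
  na <- length(ia); nb <- length(ib)
  dg <- na + nb - 2
  if (dg < 1) abort("Zero residual degrees of freedom.")
  xa <- dataset$expr[, ia, drop = FALSE]
  xb <- dataset$expr[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  s2 <- (ssa + ssb) / dg
  if (any(s2 == 0)) {
    warn("Genes with zero residual variance; offsetting to smallest positive value.")
    s2[s2 == 0] <- min(s2[s2 > 0]) / 2
  }
  prior <- fit_variance_prior(s2, dg)
  d0 <- prior_df %||% prior$df
  s02 <- prior_var %||% prior$var
  post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(post * (1 / na + 1 / nb))
  tstat <- (mb - ma) / se
  df_total <- min(d0 + dg, 1e6)
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- tibble::tibble(
    gene = rownames(dataset$expr),
    contrast = paste0(group_a, "_vs_", group_b),
    log2_fc = unname(mb - ma),
    statistic = unname(tstat),
    df = df_total,
    p.value = unname(p),
    adj.p.value = p.adjust(unname(p), method = "BH"))
  class(out) <- c("deg_table", class(out))
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

# Moment-matching estimate of the variance prior (d0, s0^2) from the
# marginal scaled-F distribution of the sample variances, on the log scale.
fit_variance_prior <- function(s2, dg) {
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(dg / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(df = Inf, var = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  list(df = d0, var = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

# Newton solve of trigamma(y) = x (x > 0), decreasing convex function.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' @export
glance.deg_table <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast[1],
    n_genes = nrow(x),
    n_significant = sum(x$adj.p.value < 0.05),
    prior_df = attr(x, "prior_df"),
    prior_var = attr(x, "prior_var"))
}

#' Call differentially expressed genes from a moderated-t table
#'
#' Up = linear fold change `2^log2_fc >= fc_threshold` with BH-adjusted
#' p below `fdr`; down = fold change `<= 1/fc_threshold` with the same
#' significance. The two lists are disjoint by construction.
#'
#' @param table A `deg_table` from [moderated_ttest()].
#' @param fc_threshold Linear fold-change cutoff (default 1.5).
#' @param fdr Adjusted-p cutoff (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
deg_filter <- function(table, fc_threshold = 1.5, fdr = 0.05) {
  fc <- 2^table$log2_fc
  sig <- table$adj.p.value < fdr
  list(up = table$gene[sig & fc >= fc_threshold],
       down = table$gene[sig & fc <= 1 / fc_threshold])
}

#' One-sided Fisher exact enrichment of a gene set in a module
#'
#' Tests over-representation of `set_genes` among `module_genes` within
#' `universe` via the hypergeometric upper tail (equivalent to the
#' one-sided Fisher exact test on the 2x2 table).
#'
#' @param module_genes,set_genes Character vectors, both subsets of
#'   `universe`.
#' @param universe Character vector of all considered genes.
#' @return One-row tibble: `intersection`, `module_size`, `set_size`,
#'   `universe_size`, `odds_ratio`, `p.value`.
#' @export
fisher_overlap <- function(module_genes, set_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  module_genes <- unique(intersect(module_genes, universe))
  set_genes <- unique(intersect(set_genes, universe))
  n_u <- length(universe)
  k <- length(intersect(module_genes, set_genes))
  m <- length(module_genes)
  s <- length(set_genes)
  p <- phyper(k - 1, s, n_u - s, m, lower.tail = FALSE)
  a <- k; b <- m - k; c <- s - k; d <- n_u - m - s + k
  or <- (a * d) / max(b * c, .Machine$double.eps)
  tibble::tibble(intersection = k, module_size = m, set_size = s,
                 universe_size = n_u, odds_ratio = or, p.value = p)
}

#' Module x gene-set overlap table
#'
#' Applies [fisher_overlap()] to every module / marker-set pair,
#' mirroring a module-by-cell-type enrichment grid.
#'
#' @param modules A `module_set` or named integer label vector.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Gene universe; defaults to all labeled genes (the genes
#'   that entered network construction).
#' @return Tibble with `module`, `set` and the [fisher_overlap()] columns.
#' @export
overlap_table <- function(modules, sets, universe = NULL) {
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  universe <- universe %||% names(labels)
  ids <- sort(unique(labels[labels > 0]))
  grid <- tidyr::expand_grid(id = ids, set = names(sets))
  purrr::pmap_dfr(grid, function(id, set) {
    res <- fisher_overlap(names(labels)[labels == id], sets[[set]], universe)
    dplyr::bind_cols(tibble::tibble(module = paste0("M", id), set = set), res)
  })
}

#' Permutation Z-summary module preservation
#'
#' For each reference module, measures in the test dataset (i) the module
#' density (mean off-diagonal signed adjacency at the same soft-threshold
#' power) and (ii) the connectivity pattern (Pearson correlation between
#' the genes' intramodular connectivity in the reference and in the test
#' data). A permutation null re-computes both statistics — including the
#' reference-side connectivity — on `n_perm` random gene sets of equal
#' size drawn from the genes shared by both datasets;
#' `Z = (obs - mean_null) / sd_null` for each statistic and
#' `Z_summary = (Z_density + Z_connectivity) / 2`. Classification uses the
#' conventional thresholds: `< 2` no evidence, 2-10 weak-to-moderate,
#' `> 10` strong preservation.
#'
#' @param reference An [expression_dataset()] the modules were found in.
#' @param modules A `module_set` or named integer label vector.
#' @param test An [expression_dataset()] to test preservation in.
#' @param power Soft-threshold power (same as used for the reference
#'   network).
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for the permutation draw.
#' @param min_genes Minimum module size after intersecting with the test
#'   dataset's genes (default 10).
#' @return Tibble of class `preservation_result`: `module`, `n_genes`,
#'   `z_density`, `z_connectivity`, `z_summary`, `preservation`,
#'   `n_permutations`.
#' @export
module_preservation <- function(reference, modules, test, power,
                                n_perm = 100, seed = 1L, min_genes = 10) {
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  set.seed(as.integer(seed))
  test_genes <- rownames(test$expr)
  null_pool <- intersect(test_genes, rownames(reference$expr))
  ids <- sort(unique(labels[labels > 0]))
  rows <- purrr::map_dfr(ids, function(id) {
    genes <- names(labels)[labels == id]
    present <- intersect(genes, test_genes)
    if (length(present) < length(genes)) {
      if (length(present) / length(genes) < 0.5) {
        warn(paste0("Module M", id, ": fewer than half of its genes are in",
                    " the test dataset."))
      }
    }
    if (length(present) < min_genes) {
      abort(paste0("Module M", id, " has fewer than ", min_genes,
                   " genes after intersection with the test dataset."))
    }
    m <- length(present)
    adj_mod <- function(expr_rows) {
      s <- (1 + cor(t(expr_rows))) / 2
      a <- s^power
      diag(a) <- 0
      a
    }
    a_ref <- adj_mod(reference$expr[present, , drop = FALSE])
    kim_ref <- rowSums(a_ref)
    a_obs <- adj_mod(test$expr[present, , drop = FALSE])
    obs_density <- sum(a_obs) / (m * (m - 1))
    obs_conn <- cor(kim_ref, rowSums(a_obs))
    null_density <- numeric(n_perm)
    null_conn <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      rnd <- sample(null_pool, m)
      a_null <- adj_mod(test$expr[rnd, , drop = FALSE])
      null_density[b] <- sum(a_null) / (m * (m - 1))
      # random gene set standing in for the module: gene identity is lost,
      # so the reference connectivity pattern is paired with unrelated
      # test-side connectivities
      null_conn[b] <- cor(kim_ref, rowSums(a_null))
    }
    zd <- (obs_density - mean(null_density)) / sd(null_density)
    zc <- (obs_conn - mean(null_conn)) / sd(null_conn)
    tibble::tibble(module = paste0("M", id), n_genes = m,
                   z_density = zd, z_connectivity = zc,
                   z_summary = (zd + zc) / 2,
                   n_permutations = n_perm)
  })
  rows$preservation <- cut(rows$z_summary, c(-Inf, 2, 10, Inf),
                           labels = c("none", "weak_to_moderate", "strong"))
  class(rows) <- c("preservation_result", class(rows))
  rows
}

#' @export
autoplot.preservation_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_genes,
                                       y = .data$z_summary,
                                       label = .data$module)) +
    ggplot2::geom_hline(yintercept = c(2, 10), linetype = "dashed",
                        colour = c("orange", "darkgreen")) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "module size (genes)", y = expression(Z[summary])) +
    ggplot2::theme_minimal()
}
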