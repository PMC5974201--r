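#' Signed co-expression similarity
#'
#' Linear transform of the gene-gene Pearson correlation that keeps the sign
#' information: `S_ij = (1 + cor(x_i, x_j)) / 2`, so perfect anti-correlation
#' maps to 0, independence to 0.5 and perfect correlation to 1.
#'
#' @param dataset An [expression_dataset()] with >= 3 samples and no
#'   constant-expression genes (IQR-filter first).
#' @return Symmetric genes x genes matrix in \[0, 1\] with unit diagonal.
#' @export
signed_similarity <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (ncol(dataset$expr) < 3) abort("Need at least 3 samples.")
  sds <- apply(dataset$expr, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant-expression gene(s) make correlation undefined: ",
                 paste(head(rownames(dataset$expr)[sds == 0], 5),
                       collapse = ", ")))
  }
  s <- (1 + cor(t(dataset$expr))) / 2
  s[s < 0] <- 0
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Soft-threshold a similarity matrix into an adjacency matrix
#'
#' @param similarity Symmetric similarity in \[0, 1\].
#' @param power Positive soft-threshold exponent (applied elementwise).
#' @return Adjacency matrix, unit diagonal.
#' @export
adjacency_matrix <- function(similarity, power) {
  if (power < 1) abort("`power` must be >= 1.")
  a <- similarity^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit index for a connectivity vector
#'
#' Bins the connectivities into `n_bins` equal-width bins over the observed
#' range, regresses `log10` of the per-bin frequency on `log10` of the bin
#' center, and returns the squared correlation signed by the negated slope
#' sign, so only decreasing degree distributions score positively. Empty
#' bins are dropped; with fewer than 3 non-empty bins (e.g. a regular graph
#' where all connectivities coincide) the fit is undefined and flagged.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of equal-width bins (>= 4).
#' @return List: `r_squared` (signed, `NA` if undefined), `slope`,
#'   `flagged` (TRUE when undefined).
#' @export
scale_free_index <- function(k, n_bins = 10) {
  if (n_bins < 4) abort("`n_bins` must be >= 4.")
  k <- k[k > 0]
  if (length(unique(k)) < 2) {
    return(list(r_squared = NA_real_, slope = NA_real_, flagged = TRUE))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  keep <- !is.na(freq) & freq > 0 & centers > 0
  if (sum(keep) < 3) {
    return(list(r_squared = NA_real_, slope = NA_real_, flagged = TRUE))
  }
  x <- log10(centers[keep])
  y <- log10(as.numeric(freq[keep]))
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  r2 <- cor(x, y)^2
  list(r_squared = -sign(slope) * r2, slope = slope, flagged = FALSE)
}

#' Evaluate candidate soft-threshold powers
#'
#' For each power, raises the similarity elementwise, computes per-gene
#' connectivity (row sums excluding self) and scores the scale-free fit via
#' [scale_free_index()].
#'
#' @param similarity Signed similarity matrix.
#' @param powers Integer vector of candidate powers (default 1-10 then
#'   12, 14, ..., 20, the customary candidate grid).
#' @param n_bins Bins for the degree-distribution fit.
#' @return A tibble of class `scale_free_fit`: `power`, `r_squared`,
#'   `slope`, `mean_k`, `median_k`, `max_k`, `flagged`.
#' @export
scale_free_fit <- function(similarity, powers = c(1:10, seq(12, 20, 2)), n_bins = 10) {
  if (any(powers < 1)) abort("`powers` must all be >= 1.")
  rows <- purrr::map(powers, function(p) {
    a <- similarity^p
    k <- rowSums(a) - diag(a)
    sf <- scale_free_index(k, n_bins = n_bins)
    tibble::tibble(power = p, r_squared = sf$r_squared, slope = sf$slope,
                   mean_k = mean(k), median_k = median(k), max_k = max(k),
                   flagged = sf$flagged)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scale_free_fit", class(out))
  out
}

#' Select the soft-threshold power
#'
#' Returns the lowest power whose signed fit index reaches `r2_threshold`.
#' If no power reaches it, falls back to the saturation knee: the first
#' power after which no later candidate improves the fit index by 0.01 or
#' more (where the saturation curve levels off), computed on a 3-point
#' running median of the fit curve so an isolated noise spike does not
#' masquerade as saturation. The fallback is flagged via the `fallback`
#' attribute and a message.
#'
#' @param fit A [scale_free_fit()] table.
#' @param r2_threshold Fit-index threshold (default 0.8).
#' @return Integer power with attribute `fallback` (logical).
#' @export
select_power <- function(fit, r2_threshold = 0.8) {
  valid <- fit[!fit$flagged & !is.na(fit$r_squared), ]
  if (nrow(valid) == 0) abort("No valid scale-free fit records.")
  ok <- valid$power[valid$r_squared >= r2_threshold]
  if (length(ok) > 0) {
    p <- min(ok)
    return(structure(as.integer(p), fallback = FALSE))
  }
  r2 <- valid$r_squared
  n <- length(r2)
  if (n >= 3) {
    sm <- r2
    for (i in 2:(n - 1)) sm[i] <- median(r2[(i - 1):(i + 1)])
    r2 <- sm
  }
  saturated <- vapply(seq_len(n), function(i) {
    i == n || max(r2[(i + 1):n]) < r2[i] + 0.01
  }, logical(1))
  p <- valid$power[which(saturated)[1]]
  inform(paste0("select_power: no power reached R^2 >= ", r2_threshold,
                "; using saturation knee at power ", p, "."))
  structure(as.integer(p), fallback = TRUE)
}

#' @export
autoplot.scale_free_fit <- function(object, r2_threshold = 0.8, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$power,
                                       y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = r2_threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "soft-threshold power",
                  y = expression(signed ~ scale-free ~ R^2)) +
    ggplot2::theme_minimal()
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with the diagonal set to 1 by convention. The adjacency
#' diagonal is zeroed internally; connectivities `k` exclude self.
#'
#' @param adjacency Symmetric adjacency with entries in \[0, 1\].
#' @return Symmetric TOM matrix in \[0, 1\], unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    abort("`adjacency` must be symmetric.")
  }
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  min_k <- outer(k, k, pmin)
  denom <- min_k + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adjacency)
  (tom + t(tom)) / 2
}

#' Cut the co-expression dendrogram into modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, decomposed into
#' modules by a deterministic recursive branch walk. A branch of the
#' dendrogram is provisionally accepted as a module when (i) it has at
#' least 80% of `min_module_size` members (a few genuine members can
#' attach above the clean branch at high powers and are recovered later),
#' (ii) it is coherent — its median internal off-diagonal TOM is at least
#' `coherence` times the background TOM level (the median off-diagonal
#' TOM of the whole matrix, which is dominated by unrelated gene pairs;
#' medians on both sides keep the gate robust to the heavy right tail of
#' TOM values) — and (iii) no sufficiently large descendant branch is
#' markedly tighter (mean internal TOM at least `split_gain` times the
#' parent's), in which case the walk descends and the children are
#' assessed instead. Accepted branches are pruned of loosely attached
#' members, unassigned genes whose connection to a module clears the same
#' per-gene gate are rescued into it, and only modules with at least
#' `min_module_size` final members are kept. Genes in no module get label
#' 0 (unassigned, "grey"). Modules are numbered M1, M2, ... by decreasing
#' size.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size Minimum branch size to call a module (default
#'   150, the whole-transcriptome setting; reduce for small gene sets).
#' @param coherence Multiple of the background TOM level a branch's mean
#'   internal TOM must reach to be module-coherent (default 3).
#' @param split_gain Tightness ratio of child over parent above which the
#'   walk prefers splitting a coherent branch (default 1.5).
#' @param power The soft-threshold power the TOM was built with, used to
#'   scale the member-pruning threshold (TOM contrast between genuine and
#'   incidentally attached members grows geometrically with the power);
#'   `NULL` uses a power-free middle-ground fraction.
#' @return A `module_set` object: `labels` (named integer, 0 = unassigned),
#'   `dendrogram` (hclust), `cut_height` (background TOM level used),
#'   `sizes` (tibble).
#' @export
cluster_modules <- function(tom, min_module_size = 150, coherence = 3,
                            split_gain = 1.5, power = NULL) {
  if (min_module_size < 2) abort("`min_module_size` must be >= 2.")
  genes <- rownames(tom)
  n <- nrow(tom)
  dend <- hclust(as.dist(1 - tom), method = "average")
  labels <- setNames(integer(n), genes)
  if (n < min_module_size) {
    warn("Fewer genes than `min_module_size`; all genes left unassigned.")
    return(new_module_set(labels, dend, NA_real_))
  }
  off <- tom[lower.tri(tom)]
  background <- median(off)
  min_provisional <- max(2L, ceiling(0.8 * min_module_size))

  # Bottom-up pass over the merge tree: membership, total TOM mass (the
  # cross terms cost sum |left||right| = n(n-1)/2 entries in total), mean
  # internal TOM per branch, and the tightest sufficiently large branch
  # strictly below each node.
  memb <- vector("list", n - 1)
  tom_sum <- numeric(n - 1)   # includes the unit diagonal
  mean_int <- numeric(n - 1)
  best_below <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    l <- dend$merge[i, 1]; r <- dend$merge[i, 2]
    il <- if (l < 0) -l else memb[[l]]
    ir <- if (r < 0) -r else memb[[r]]
    sl <- if (l < 0) 1 else tom_sum[l]
    sr <- if (r < 0) 1 else tom_sum[r]
    memb[[i]] <- c(il, ir)
    tom_sum[i] <- sl + sr + 2 * sum(tom[il, ir])
    m <- length(memb[[i]])
    mean_int[i] <- (tom_sum[i] - m) / (m * (m - 1))
    bb <- max(if (l > 0) best_below[l] else -Inf,
              if (r > 0) best_below[r] else -Inf)
    if (l > 0 && length(memb[[l]]) >= min_provisional) {
      bb <- max(bb, mean_int[l])
    }
    if (r > 0 && length(memb[[r]]) >= min_provisional) {
      bb <- max(bb, mean_int[r])
    }
    best_below[i] <- bb
  }
  median_int <- function(idx) {
    sub <- tom[idx, idx]
    median(sub[lower.tri(sub)])
  }
  accepted <- list()
  stack <- n - 1L
  while (length(stack) > 0) {
    node <- stack[[1]]
    stack <- stack[-1]
    if (node < 0) next
    idx <- memb[[node]]
    if (length(idx) < min_provisional) next
    md <- median_int(idx)
    coherent <- md > 0 && md >= coherence * background
    if (coherent && best_below[node] < split_gain * mean_int[node]) {
      accepted[[length(accepted) + 1]] <- idx
    } else {
      stack <- c(stack, dend$merge[node, 1], dend$merge[node, 2])
    }
  }
  # prune loosely attached members: a gene stays only if its mean TOM to
  # the rest of the branch is a substantial fraction of the branch mean
  # (and clears the background coherence gate)
  prune_frac <- if (is.null(power)) 0.3 else 0.90^power
  accepted <- lapply(accepted, function(idx) {
    for (pass in 1:4) {
      m <- length(idx)
      if (m < 2) break
      per_gene <- (rowSums(tom[idx, idx]) - 1) / (m - 1)
      anchor <- quantile(per_gene, 0.9, names = FALSE)
      keep <- per_gene >= pmax(prune_frac * anchor, coherence * background)
      if (all(keep)) break
      idx <- idx[keep]
    }
    idx
  })
  # rescue: an unassigned gene whose mean TOM to a module clears the same
  # per-gene gate joins it (ties: the module it is most connected to,
  # relative to that module's anchor)
  if (length(accepted) > 0) {
    assigned <- unlist(accepted)
    free <- setdiff(seq_len(n), assigned)
    if (length(free) > 0) {
      ratio <- vapply(accepted, function(idx) {
        per_gene <- (rowSums(tom[idx, idx]) - 1) / (length(idx) - 1)
        anchor <- quantile(per_gene, 0.9, names = FALSE)
        conn <- rowMeans(tom[free, idx, drop = FALSE])
        out <- conn / anchor
        out[conn < coherence * background] <- 0
        out
      }, numeric(length(free)))
      ratio <- matrix(ratio, nrow = length(free))
      best <- apply(ratio, 1, which.max)
      best_ratio <- ratio[cbind(seq_along(free), best)]
      take <- best_ratio >= prune_frac
      for (j in which(take)) {
        accepted[[best[j]]] <- c(accepted[[best[j]]], free[j])
      }
    }
  }
  accepted <- accepted[vapply(accepted, length, integer(1)) >=
                         min_module_size]
  if (length(accepted) > 0) {
    ord <- order(-vapply(accepted, length, integer(1)))
    for (i in seq_along(ord)) {
      labels[accepted[[ord[i]]]] <- i
    }
  }
  new_module_set(labels, dend, background)
}

new_module_set <- function(labels, dendrogram, cut_height) {
  sizes <- tibble::as_tibble(table(module = labels)) |>
    dplyr::mutate(module = as.integer(.data$module)) |>
    dplyr::rename(size = "n") |>
    dplyr::arrange(.data$module)
  structure(list(labels = labels, dendrogram = dendrogram,
                 cut_height = cut_height, sizes = sizes),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- sum(x$sizes$module > 0)
  cat("<module_set> ", n_mod, " module(s) over ", length(x$labels),
      " genes (", sum(x$labels == 0), " unassigned)\n", sep = "")
  print(x$sizes, n = 20)
  invisible(x)
}

#' @export
tidy.module_set <- function(x, ...) {
  tibble::tibble(gene = names(x$labels), module = unname(x$labels))
}

#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$labels),
    n_modules = sum(x$sizes$module > 0),
    prop_unassigned = mean(x$labels == 0),
    cut_height = x$cut_height)
}

#' Module eigengenes by singular value decomposition
#'
#' Each module's member genes are standardized across samples; the module
#' eigengene is the first right singular vector of the standardized
#' submatrix, scaled to unit variance and sign-oriented so it correlates
#' non-negatively with the module's mean standardized expression. A
#' single-gene module's eigengene is that gene's standardized profile.
#'
#' @param dataset An [expression_dataset()].
#' @param modules A `module_set` (or named integer label vector) covering
#'   the dataset's genes; label 0 is skipped.
#' @return Modules x samples matrix (rownames `M1`, `M2`, ...), each row
#'   unit variance.
#' @export
module_eigengenes <- function(dataset, modules) {
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  labels <- labels[names(labels) %in% rownames(dataset$expr)]
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) abort("No modules (all labels are 0).")
  me <- matrix(NA_real_, nrow = length(ids), ncol = ncol(dataset$expr),
               dimnames = list(paste0("M", ids), colnames(dataset$expr)))
  for (i in seq_along(ids)) {
    genes <- names(labels)[labels == ids[i]]
    x <- dataset$expr[genes, , drop = FALSE]
    xs <- t(scale(t(x)))
    if (nrow(xs) == 1) {
      v <- as.numeric(xs)
    } else {
      sv <- svd(xs, nu = 0, nv = 1)
      v <- sv$v[, 1]
    }
    v <- v / sd(v)
    if (cor(v, colMeans(xs)) < 0) v <- -v
    me[i, ] <- v
  }
  me
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation with two-sided p-values from the t distribution on
#' `n - 2` degrees of freedom, for every module x trait pair. P-values are
#' reported unadjusted.
#'
#' @param me Module x sample eigengene matrix ([module_eigengenes()]).
#' @param traits Tibble from [encode_traits()] (or any tibble with
#'   `sample_id` plus numeric trait columns) covering the eigengene samples.
#' @return Tibble: `module`, `trait`, `estimate`, `statistic`, `p.value`,
#'   `n`.
#' @export
module_trait_correlation <- function(me, traits) {
  traits <- tibble::as_tibble(traits)
  if (!"sample_id" %in% names(traits)) {
    abort("`traits` must have a `sample_id` column.")
  }
  if (!all(colnames(me) %in% traits$sample_id)) {
    abort("`traits` must cover every eigengene sample.")
  }
  if (ncol(me) < 3) abort("Need at least 3 samples.")
  traits <- traits[match(colnames(me), traits$sample_id), ]
  trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  n <- ncol(me)
  grid <- tidyr::expand_grid(module = rownames(me), trait = trait_cols)
  purrr::pmap_dfr(grid, function(module, trait) {
    y <- traits[[trait]]
    if (sd(y) == 0) abort(paste0("Trait '", trait, "' has zero variance."))
    r <- cor(me[module, ], y)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    tibble::tibble(module = module, trait = trait, estimate = r,
                   statistic = tstat,
                   p.value = 2 * pt(-abs(tstat), df = n - 2), n = n)
  })
}

#' Intramodular connectivity and hub genes
#'
#' `kIM_i` is gene i's summed adjacency to the other genes of its own
#' module. Genes are ranked within module by decreasing kIM, ties broken
#' lexicographically by gene id.
#'
#' @param adjacency Adjacency matrix over the labeled genes.
#' @param modules A `module_set` or named integer label vector.
#' @param top_n Ranked genes to keep per module (default all).
#' @return Tibble: `module`, `gene`, `kim`, `rank`.
#' @export
intramodular_hubs <- function(adjacency, modules, top_n = Inf) {
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  labels <- labels[names(labels) %in% rownames(adjacency)]
  ids <- sort(unique(labels[labels > 0]))
  purrr::map_dfr(ids, function(id) {
    genes <- names(labels)[labels == id]
    a <- adjacency[genes, genes, drop = FALSE]
    diag(a) <- 0
    kim <- rowSums(a)
    ord <- order(-kim, genes)
    k <- min(top_n, length(genes))
    tibble::tibble(module = paste0("M", id), gene = genes[ord][seq_len(k)],
                   kim = unname(kim[ord][seq_len(k)]), rank = seq_len(k))
  })
}

#' Build the full co-expression network for a dataset
#'
#' Convenience wrapper chaining [signed_similarity()], [scale_free_fit()],
#' [select_power()] (unless `power` is given), [adjacency_matrix()] and
#' [topological_overlap()].
#'
#' @param dataset An [expression_dataset()].
#' @param power Soft-threshold power; `NULL` to select by scale-free fit.
#' @param powers,n_bins,r2_threshold Passed to the power selection.
#' @return A `coexpression_network` object: `similarity`, `power`,
#'   `adjacency`, `tom`, `connectivity`, `fit` (NULL when `power` given),
#'   `power_fallback`.
#' @export
build_network <- function(dataset, power = NULL, powers = c(1:10, seq(12, 20, 2)), n_bins = 10,
                          r2_threshold = 0.8) {
  s <- signed_similarity(dataset)
  fit <- NULL
  fallback <- FALSE
  if (is.null(power)) {
    fit <- scale_free_fit(s, powers = powers, n_bins = n_bins)
    power <- select_power(fit, r2_threshold = r2_threshold)
    fallback <- attr(power, "fallback")
  }
  a <- adjacency_matrix(s, power)
  tom <- topological_overlap(a)
  k <- rowSums(a) - 1
  structure(list(similarity = s, power = as.integer(power), adjacency = a,
                 tom = tom, connectivity = k, fit = fit,
                 power_fallback = fallback),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("<coexpression_network> ", nrow(x$adjacency), " genes, power = ",
      x$power, if (x$power_fallback) " (knee fallback)" else "", "\n",
      sep = "")
  invisible(x)
}
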