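#' Specify a synthetic benchmark dataset
#'
#' Describes an expression study with planted co-expression modules, marker
#' lists overlapping those modules, and a scale-free protein-interaction
#' network whose node expression can be perturbed in chosen conditions.
#' The defaults emulate the hippocampal study design the pipeline targets:
#' three groups (young 17, aging 21, AD 18 samples; ages 20-50 / 70-99 /
#' 70-99 years), four planted modules of 150-300 genes with within-module
#' correlations 0.6-0.85, two shifted up and two shifted down monotonically
#' across young -> aging -> AD.
#'
#' Each module is a list with fields `size` (gene count),
#' `base_correlation` (target mean pairwise Pearson correlation, in (0,1)),
#' `group_shift` (length-3 numeric: latent mean offset for young/aging/ad,
#' in latent standard-deviation units) and `sign` (+1 or -1, the sign of the
#' gene loadings). See [module_spec()].
#'
#' @param n_genes Total gene count.
#' @param n_samples_per_group Named integer vector `c(young=, aging=, ad=)`.
#' @param modules List of module specifications ([module_spec()]).
#' @param noise_sd Standard deviation of the i.i.d. gaussian noise added to
#'   every gene (and the full signal for background genes). Must be > 0.
#' @param marker_overlap Fraction of each planted module copied into its
#'   marker list, in \[0, 1\].
#' @param marker_length Length of each marker list; default the module size.
#' @param ppi_n_nodes Node count of the synthetic interaction network
#'   (must be <= `n_genes`).
#' @param ppi_attach_m Preferential-attachment edges added per node.
#' @param perturbed_edges List of perturbations, each a list with `edge`
#'   (character vector of the two endpoint genes), `condition` (group name)
#'   and `change` (multiplicative expression change applied to both
#'   endpoints in that condition only).
#' @param seed Integer seed fixing all generated outputs bit-for-bit.
#' @param arch_seed Integer seed for the gene-level architecture (module
#'   loadings). Kept separate from `seed` so that independent replicate
#'   draws (same `arch_seed`, different `seed`) measure the same genes
#'   with the same connectivity pattern, as biological replicates would.
#'
#' @return A `synthetic_spec` object (validated list).
#' @export
#'
#' @examples
#' spec <- synthetic_spec(n_genes = 300,
#'   modules = list(module_spec(50, 0.9, c(0, 1, 2))), seed = 7)
#' ds <- generate_expression(spec)
#' ds
synthetic_spec <- function(n_genes = 2000,
                           n_samples_per_group = c(young = 17, aging = 21,
                                                   ad = 18),
                           modules = list(
                             module_spec(300, 0.85, c(0, 1, 2), +1),
                             module_spec(250, 0.75, c(0, 0.75, 1.5), +1),
                             module_spec(200, 0.70, c(0, -1, -2), +1),
                             module_spec(150, 0.60, c(0, -0.75, -1.5), +1)
                           ),
                           noise_sd = 1,
                           marker_overlap = 0.5,
                           marker_length = NULL,
                           ppi_n_nodes = min(200, n_genes),
                           ppi_attach_m = 2,
                           perturbed_edges = list(),
                           seed = 1L,
                           arch_seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_group = n_samples_per_group,
               modules = modules, noise_sd = noise_sd,
               marker_overlap = marker_overlap,
               marker_length = marker_length,
               ppi_n_nodes = as.integer(ppi_n_nodes),
               ppi_attach_m = as.integer(ppi_attach_m),
               perturbed_edges = perturbed_edges,
               seed = as.integer(seed),
               arch_seed = as.integer(arch_seed))
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

#' Specify one planted module
#'
#' @param size Gene count of the module.
#' @param base_correlation Target mean pairwise correlation, in (0, 1).
#' @param group_shift Numeric length 3: latent mean offset in young, aging,
#'   ad (latent SD units).
#' @param sign +1 or -1; sign applied to all gene loadings of the module.
#' @return A list usable in `synthetic_spec(modules = ...)`.
#' @export
module_spec <- function(size, base_correlation, group_shift = c(0, 0, 0),
                        sign = +1) {
  list(size = as.integer(size), base_correlation = base_correlation,
       group_shift = as.numeric(group_shift), sign = sign)
}

validate_spec <- function(spec) {
  if (spec$n_genes < 1) abort("Invalid `n_genes`: must be >= 1.")
  grp <- names(spec$n_samples_per_group)
  if (is.null(grp) || !setequal(grp, c("young", "aging", "ad"))) {
    abort("Invalid `n_samples_per_group`: must be named young/aging/ad.")
  }
  sizes <- vapply(spec$modules, function(m) m$size, integer(1))
  if (length(sizes) > 0 && sum(sizes) > spec$n_genes) {
    abort("Invalid `modules`: module sizes sum exceeds `n_genes`.")
  }
  for (m in spec$modules) {
    if (m$base_correlation <= 0 || m$base_correlation >= 1) {
      abort("Invalid `modules`: base_correlation must lie in (0, 1).")
    }
    if (length(m$group_shift) != 3) {
      abort("Invalid `modules`: group_shift must have length 3.")
    }
    if (!m$sign %in% c(-1, 1)) {
      abort("Invalid `modules`: sign must be +1 or -1.")
    }
  }
  if (spec$noise_sd <= 0) abort("Invalid `noise_sd`: must be > 0.")
  if (spec$marker_overlap < 0 || spec$marker_overlap > 1) {
    abort("Invalid `marker_overlap`: must lie in [0, 1].")
  }
  if (spec$ppi_n_nodes > spec$n_genes) {
    abort("Invalid `ppi_n_nodes`: must be <= `n_genes`.")
  }
  invisible(spec)
}

# Deterministic per-stage seed derived from the master seed; keeps the three
# generator operations independent of each other's RNG consumption.
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + stage * 104729) %% 2147483647)
}

# mean squared loading for loadings ~ U(0.7, 1): E[l^2]
.mean_sq_loading <- (0.7^2 + 0.7 * 1 + 1^2) / 3

#' Generate a synthetic expression dataset with planted modules
#'
#' Module genes are built as `sign * loading * s_m * latent + noise` with
#' loadings uniform in \[0.7, 1\], so the first singular vector of the module
#' block recovers the latent (matching eigengene-by-SVD summarization). The
#' latent has a per-group mean offset (`group_shift`) plus unit gaussian
#' variation per sample; the amplitude `s_m` is solved so the expected
#' within-module pairwise correlation equals `base_correlation`.
#' Background genes are pure `N(0, noise_sd^2)` noise. Sample ages are drawn
#' uniformly in 20-50 (young) and 70-99 (aging, ad) years; sex alternates
#' F/M within group.
#'
#' @param spec A [synthetic_spec()].
#' @return An [expression_dataset()] with a `truth` attribute (list:
#'   `module_labels` named integer vector, 0 = background; `latents`
#'   module x sample matrix; `spec`).
#' @export
generate_expression <- function(spec) {
  validate_spec(spec)
  # gene architecture (loadings) first, under its own seed, so replicate
  # draws with a different run seed share it
  set.seed(derive_seed(spec$arch_seed %||% 1L, 4L))
  loadings_list <- lapply(spec$modules, function(m) {
    m$sign * runif(m$size, 0.7, 1)
  })
  set.seed(derive_seed(spec$seed, 1L))
  n_per <- spec$n_samples_per_group[c("young", "aging", "ad")]
  groups <- rep(c("young", "aging", "ad"), times = n_per)
  n_samp <- length(groups)
  sample_ids <- sprintf("S%02d_%s", seq_len(n_samp), groups)
  age_rng <- list(young = c(20, 50), aging = c(70, 99), ad = c(70, 99))
  ages <- vapply(groups, function(g) {
    round(runif(1, age_rng[[g]][1], age_rng[[g]][2]))
  }, numeric(1))
  sex <- unlist(lapply(n_per, function(k) {
    rep_len(c("F", "M"), k)
  }), use.names = FALSE)

  gene_ids <- sprintf("gene%05d", seq_len(spec$n_genes))
  expr <- matrix(rnorm(spec$n_genes * n_samp, sd = spec$noise_sd),
                 nrow = spec$n_genes,
                 dimnames = list(gene_ids, sample_ids))
  labels <- setNames(integer(spec$n_genes), gene_ids)
  effect <- setNames(numeric(spec$n_genes), gene_ids)
  n_mod <- length(spec$modules)
  latents <- matrix(NA_real_, nrow = n_mod, ncol = n_samp,
                    dimnames = list(NULL, sample_ids))
  offset <- 0L
  for (mi in seq_along(spec$modules)) {
    m <- spec$modules[[mi]]
    idx <- offset + seq_len(m$size)
    offset <- offset + m$size
    shift <- setNames(m$group_shift, c("young", "aging", "ad"))
    latent <- shift[groups] + rnorm(n_samp)
    latents[mi, ] <- latent
    loadings <- loadings_list[[mi]]
    b <- m$base_correlation
    amp <- sqrt(spec$noise_sd^2 * b / (.mean_sq_loading * (1 - b)))
    expr[idx, ] <- expr[idx, ] + outer(loadings * amp, latent)
    labels[idx] <- mi
    effect[idx] <- loadings * amp * (m$group_shift[3] - m$group_shift[1])
  }
  meta <- tibble::tibble(sample_id = sample_ids, group = groups,
                         age = unname(ages), sex = sex)
  ds <- expression_dataset(expr, meta)
  attr(ds, "truth") <- list(module_labels = labels, latents = latents,
                            effect_young_to_ad = effect, spec = spec)
  ds
}

#' Generate marker gene lists overlapping planted modules
#'
#' One list per planted module: `round(marker_overlap * size)` genes sampled
#' from the module plus background genes (never in any planted module) up to
#' the configured list length. Lists are mutually disjoint.
#'
#' @param spec A [synthetic_spec()].
#' @param dataset The [generate_expression()] output for `spec`.
#' @return Named list of character vectors (`celltype1`, `celltype2`, ...).
#' @export
generate_markers <- function(spec, dataset) {
  validate_spec(spec)
  truth <- attr(dataset, "truth")
  if (is.null(truth)) abort("`dataset` must come from generate_expression().")
  set.seed(derive_seed(spec$seed, 2L))
  labels <- truth$module_labels
  background_pool <- names(labels)[labels == 0L]
  markers <- list()
  for (mi in seq_along(spec$modules)) {
    m <- spec$modules[[mi]]
    len <- spec$marker_length %||% m$size
    n_in <- round(spec$marker_overlap * m$size)
    n_in <- min(n_in, len)
    mod_genes <- names(labels)[labels == mi]
    picked <- sample(mod_genes, n_in)
    n_bg <- len - n_in
    if (n_bg > length(background_pool)) {
      abort("Not enough background genes to fill disjoint marker lists.")
    }
    bg <- if (n_bg > 0) sample(background_pool, n_bg) else character(0)
    background_pool <- setdiff(background_pool, bg)
    markers[[paste0("celltype", mi)]] <- c(picked, bg)
  }
  markers
}

#' Generate a synthetic scale-free interaction network with expression
#'
#' Grows an undirected preferential-attachment graph over a random subset of
#' the dataset's genes and attaches per-condition node expression: the group
#' mean of the gene's linear-scale intensity (`2^x` of the log values), with
#' each perturbed edge's endpoint expression multiplied by its stated change
#' in the stated condition only.
#'
#' @param spec A [synthetic_spec()].
#' @param dataset The [generate_expression()] output for `spec`.
#' @return A list of class `ppi_sim`: `network` (a [ppi_network]),
#'   `node_expr` (nodes x conditions matrix of linear intensities),
#'   `perturbed` (tibble of applied perturbations).
#' @export
generate_ppi <- function(spec, dataset) {
  validate_spec(spec)
  genes <- rownames(dataset$expr)  # force the promise before seeding
  set.seed(derive_seed(spec$seed, 3L))
  nodes <- sample(genes, spec$ppi_n_nodes)
  g <- igraph::sample_pa(spec$ppi_n_nodes, power = 1, m = spec$ppi_attach_m,
                         directed = FALSE)
  igraph::V(g)$name <- nodes
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(source = el[, 1], target = el[, 2],
                          directed = FALSE)
  net <- ppi_network(edges)

  groups <- dataset$samples$group
  conditions <- unique(groups)
  lin <- 2^dataset$expr[nodes, , drop = FALSE]
  node_expr <- vapply(conditions, function(g_) {
    rowMeans(lin[, groups == g_, drop = FALSE])
  }, numeric(length(nodes)))
  rownames(node_expr) <- nodes

  pert <- tibble::tibble(source = character(), target = character(),
                         condition = character(), change = numeric())
  for (p in spec$perturbed_edges) {
    known <- all(p$edge %in% igraph::V(net$graph)$name)
    eid <- if (known) {
      igraph::get_edge_ids(net$graph, p$edge, error = FALSE)
    } else 0
    if (eid == 0) {
      abort(paste0("Perturbed edge (", p$edge[1], ", ", p$edge[2],
                   ") is not present in the generated topology."))
    }
    if (!p$condition %in% conditions) {
      abort(paste0("Unknown perturbation condition '", p$condition, "'."))
    }
    node_expr[p$edge, p$condition] <- node_expr[p$edge, p$condition] * p$change
    pert <- dplyr::bind_rows(pert, tibble::tibble(
      source = p$edge[1], target = p$edge[2],
      condition = p$condition, change = p$change))
  }
  structure(list(network = net, node_expr = node_expr, perturbed = pert),
            class = "ppi_sim")
}

#' Apply a spec's expression perturbations to the dataset itself
#'
#' Multiplies the linear-scale expression of each perturbed edge's endpoint
#' genes by the stated change in all samples of the stated condition (i.e.
#' adds `log2(change)` on the log scale). Used to propagate interaction
#' perturbations into per-sample weighted networks.
#'
#' @param dataset An [expression_dataset()].
#' @param perturbed_edges As in [synthetic_spec()].
#' @return The perturbed [expression_dataset()] (truth attribute preserved).
#' @export
perturb_dataset <- function(dataset, perturbed_edges) {
  expr <- dataset$expr
  groups <- dataset$samples$group
  for (p in perturbed_edges) {
    cols <- groups == p$condition
    genes <- intersect(p$edge, rownames(expr))
    expr[genes, cols] <- expr[genes, cols] + log2(p$change)
  }
  out <- expression_dataset(expr, dataset$samples)
  attr(out, "truth") <- attr(dataset, "truth")
  out
}

#' Write a full synthetic benchmark to disk
#'
#' Emits the canonical file formats consumed by the pipeline: expression and
#' metadata TSVs, marker lists as GMT, the interaction network as a
#' 3-column edge-list TSV, and a JSON ground-truth sidecar (module labels,
#' perturbed edges, seed) for benchmarking.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `paths` (named list of written files)
#'   and the generated objects (`dataset`, `markers`, `ppi`).
#' @export
write_synthetic <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- generate_expression(spec)
  markers <- generate_markers(spec, dataset)
  ppi <- generate_ppi(spec, dataset)
  truth <- attr(dataset, "truth")
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    markers = file.path(dir, "markers.gmt"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression(dataset, paths$expression, paths$metadata)
  write_gmt(markers, paths$markers)
  write_ppi(ppi$network, paths$ppi)
  truth_json <- list(
    module_labels = as.list(truth$module_labels),
    perturbed = ppi$perturbed,
    seed = spec$seed)
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, dataset = dataset, markers = markers,
                 ppi = ppi))
}
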