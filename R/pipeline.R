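#' Configure a full pipeline run
#'
#' Exactly one of a set of real input paths (`expression` + `metadata`,
#' optionally `ppi` and `markers`) or a [synthetic_spec()] must be given.
#'
#' @param expression,metadata,ppi,markers Input file paths (TSV matrix,
#'   metadata TSV, edge-list TSV, GMT).
#' @param synthetic A [synthetic_spec()] describing a generated benchmark.
#' @param out_dir Output directory for all stage artifacts.
#' @param iqr_threshold Gene IQR filter threshold.
#' @param power Soft-threshold power; `NULL` selects by scale-free fit.
#' @param powers,n_bins,r2_threshold Power-selection settings.
#' @param min_module_size,coherence,split_gain Module detection settings
#'   (see [cluster_modules()]).
#' @param fc_threshold,fdr Differential-expression thresholds.
#' @param diff_threshold,threshold_type,alpha,diff_mode Differential-edge
#'   settings (see [differential_edges()]).
#' @param n_perm Permutations for module preservation.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(expression = NULL, metadata = NULL, ppi = NULL,
                       markers = NULL, synthetic = NULL,
                       out_dir = tempfile("netage_run_"),
                       iqr_threshold = 0.2, power = NULL, powers = c(1:10, seq(12, 20, 2)),
                       n_bins = 10, r2_threshold = 0.8,
                       min_module_size = 150, coherence = 3,
                       split_gain = 1.5,
                       fc_threshold = 1.5, fdr = 0.05,
                       diff_threshold = 2000,
                       threshold_type = "absolute", alpha = 0.05,
                       diff_mode = "per_sample_test", n_perm = 100,
                       seed = 1L) {
  real <- !is.null(expression)
  synth <- !is.null(synthetic)
  if (real == synth) {
    abort("Exactly one of real inputs (`expression`) or `synthetic` must be set.")
  }
  if (real && is.null(metadata)) {
    abort("Real inputs require a `metadata` path.")
  }
  if (synth && !inherits(synthetic, "synthetic_spec")) {
    abort("`synthetic` must be a synthetic_spec object.")
  }
  stopifnot(iqr_threshold >= 0, fdr > 0, fdr < 1, alpha > 0, alpha < 1,
            fc_threshold >= 1, min_module_size >= 2,
            coherence > 0, split_gain >= 1, n_perm >= 1)
  cfg <- list(expression = expression, metadata = metadata, ppi = ppi,
              markers = markers, synthetic = synthetic, out_dir = out_dir,
              iqr_threshold = iqr_threshold, power = power, powers = powers,
              n_bins = n_bins, r2_threshold = r2_threshold,
              min_module_size = min_module_size, coherence = coherence,
              split_gain = split_gain, fc_threshold = fc_threshold,
              fdr = fdr, diff_threshold = diff_threshold,
              threshold_type = threshold_type, alpha = alpha,
              diff_mode = diff_mode, n_perm = n_perm,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the four stages in order — expression IO (filtering), signed
#' co-expression network + modules, module statistics (DEGs, marker
#' overlap, preservation against a replicate for synthetic runs), and
#' weighted-PPI differential connectivity — writing every stage's tabular
#' outputs plus a JSON run manifest into `config$out_dir`. Re-running with
#' the identical config and seed reproduces the outputs bit-for-bit.
#'
#' @param config A [run_config()].
#' @return Invisible list with the in-memory results of every stage
#'   (`dataset`, `network`, `modules`, `me`, `trait_cor`, `hubs`, `degs`,
#'   `overlaps`, `preservation`, `diff_edges`, `subnetworks`, `truth`,
#'   `manifest`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "inputs"
  res <- list()
  manifest <- list(package = "netage",
                   version = as.character(utils::packageVersion("netage")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("synthetic"))],
                   stages = list())
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e),
                   "\nCompleted artifacts are under ", config$out_dir))
    })
  }

  # ---- stage 1: inputs + filtering -------------------------------------
  res1 <- run_stage("expression_io", function() {
    if (!is.null(config$synthetic)) {
      spec <- config$synthetic
      dataset <- generate_expression(spec)
      markers <- generate_markers(spec, dataset)
      ppi_sim <- generate_ppi(spec, dataset)
      ppi_dataset <- perturb_dataset(dataset, spec$perturbed_edges)
      truth <- attr(dataset, "truth")
      truth$perturbed <- ppi_sim$perturbed
      list(dataset = dataset, markers = markers, ppi = ppi_sim$network,
           ppi_dataset = ppi_dataset, truth = truth, checksums = list())
    } else {
      raw <- read_expression(config$expression, format = "tsv")
      meta <- readr::read_tsv(config$metadata, show_col_types = FALSE)
      dataset <- expression_dataset(raw$matrix, meta)
      markers <- if (!is.null(config$markers)) read_gmt(config$markers)
      ppi <- if (!is.null(config$ppi)) read_ppi(config$ppi)
      paths <- c(config$expression, config$metadata, config$ppi,
                 config$markers)
      list(dataset = dataset, markers = markers, ppi = ppi,
           ppi_dataset = dataset, truth = NULL,
           checksums = as.list(tools::md5sum(paths)))
    }
  })
  dataset <- iqr_filter(res1$dataset, config$iqr_threshold)
  write_expression(dataset, file.path(config$out_dir, "expression.tsv"),
                   file.path(config$out_dir, "metadata.tsv"))
  manifest$stages$expression_io <- list(
    status = "complete", n_genes = nrow(dataset$expr),
    n_samples = ncol(dataset$expr))

  # ---- stage 2: co-expression network + modules ------------------------
  res2 <- run_stage("coexpression", function() {
    network <- build_network(dataset, power = config$power,
                             powers = config$powers, n_bins = config$n_bins,
                             r2_threshold = config$r2_threshold)
    modules <- cluster_modules(network$tom,
                               min_module_size = config$min_module_size,
                               coherence = config$coherence,
                               split_gain = config$split_gain,
                               power = network$power)
    me <- module_eigengenes(dataset, modules)
    traits <- encode_traits(dataset)
    trait_cor <- module_trait_correlation(me, traits)
    hubs <- intramodular_hubs(network$adjacency, modules)
    list(network = network, modules = modules, me = me,
         trait_cor = trait_cor, hubs = hubs)
  })
  mod_tab <- tidy(res2$modules) |>
    dplyr::left_join(res2$hubs[, c("gene", "kim")], by = "gene")
  readr::write_tsv(mod_tab, file.path(config$out_dir, "modules.tsv"))
  readr::write_tsv(tibble::as_tibble(res2$me, rownames = "module"),
                   file.path(config$out_dir, "eigengenes.tsv"))
  readr::write_tsv(res2$trait_cor,
                   file.path(config$out_dir, "trait_correlation.tsv"))
  ape::write.tree(ape::as.phylo(res2$modules$dendrogram),
                  file.path(config$out_dir, "dendrogram.nwk"))
  manifest$stages$coexpression <- list(
    status = "complete", power = res2$network$power,
    power_fallback = res2$network$power_fallback,
    n_modules = sum(res2$modules$sizes$module > 0))

  # ---- stage 3: module statistics --------------------------------------
  res3 <- run_stage("module_stats", function() {
    contrasts <- list(c("young", "aging"), c("aging", "ad"),
                      c("young", "ad"))
    degs <- purrr::map_dfr(contrasts, function(ct) {
      moderated_ttest(dataset, ct[1], ct[2])
    })
    overlaps <- if (!is.null(res1$markers)) {
      overlap_table(res2$modules, res1$markers)
    }
    preservation <- NULL
    if (!is.null(config$synthetic)) {
      spec2 <- config$synthetic
      spec2$seed <- derive_seed(config$seed, 17L)
      replicate <- iqr_filter(generate_expression(spec2),
                              config$iqr_threshold)
      preservation <- module_preservation(
        dataset, res2$modules, replicate, power = res2$network$power,
        n_perm = config$n_perm, seed = derive_seed(config$seed, 18L))
    }
    list(degs = degs, overlaps = overlaps, preservation = preservation)
  })
  readr::write_tsv(res3$degs, file.path(config$out_dir, "deg_table.tsv"))
  if (!is.null(res3$overlaps)) {
    readr::write_tsv(res3$overlaps,
                     file.path(config$out_dir, "marker_overlap.tsv"))
  }
  if (!is.null(res3$preservation)) {
    readr::write_tsv(res3$preservation,
                     file.path(config$out_dir, "preservation.tsv"))
  }
  manifest$stages$module_stats <- list(
    status = "complete",
    n_deg_young_vs_ad = length(unlist(
      deg_filter(res3$degs[res3$degs$contrast == "young_vs_ad", ],
                 config$fc_threshold, config$fdr))))

  # ---- stage 4: weighted PPI differential connectivity -----------------
  res4 <- run_stage("ppi_diffnet", function() {
    if (is.null(res1$ppi)) {
      return(NULL)
    }
    mode <- if (config$diff_mode == "per_sample_test") "per_sample" else
      "group_mean"
    wppi <- overlay_expression(res1$ppi, res1$ppi_dataset, mode = mode)
    diff_edges <- differential_edges(
      wppi, "young", "ad", diff_threshold = config$diff_threshold,
      alpha = config$alpha, mode = config$diff_mode,
      threshold_type = config$threshold_type)
    subnetworks <- extract_subnetworks(diff_edges)
    list(wppi = wppi, diff_edges = diff_edges, subnetworks = subnetworks)
  })
  if (!is.null(res4)) {
    readr::write_tsv(res4$diff_edges,
                     file.path(config$out_dir, "differential_edges.tsv"))
    readr::write_tsv(res4$subnetworks$hubs,
                     file.path(config$out_dir, "subnetwork_hubs.tsv"))
    for (side in c("up", "down")) {
      g <- res4$subnetworks[[side]]
      if (igraph::vcount(g) > 0) {
        igraph::write_graph(g, file.path(
          config$out_dir, paste0("subnetwork_", side, ".graphml")),
          format = "graphml")
      }
    }
    manifest$stages$ppi_diffnet <- list(
      status = "complete", n_edges = nrow(res4$diff_edges),
      n_passing = sum(res4$diff_edges$passes))
  } else {
    manifest$stages$ppi_diffnet <- list(status = "skipped (no PPI input)")
  }
  manifest$checksums <- res1$checksums
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out <- list(dataset = dataset, markers = res1$markers,
              network = res2$network, modules = res2$modules, me = res2$me,
              trait_cor = res2$trait_cor, hubs = res2$hubs,
              degs = res3$degs, overlaps = res3$overlaps,
              preservation = res3$preservation,
              diff_edges = res4$diff_edges,
              subnetworks = res4$subnetworks, truth = res1$truth,
              manifest = manifest, config = config,
              out_dir = config$out_dir)
  invisible(out)
}

#' Benchmark a synthetic run against its ground truth
#'
#' @param run A [run_pipeline()] result produced from a synthetic config.
#' @return Tibble of metrics: module-recovery adjusted Rand index,
#'   per-module stage-correlation sign accuracy, DEG recall/precision for
#'   young vs AD, preservation classes, differential-edge sensitivity and
#'   empirical FDR (NA when no perturbation was planted).
#' @export
benchmark_report <- function(run) {
  truth <- run$truth
  if (is.null(truth)) abort("Run has no ground-truth sidecar (not synthetic).")
  labels <- run$modules$labels
  truth_labels <- truth$module_labels[names(labels)]
  ari <- mclust::adjustedRandIndex(labels, truth_labels)

  # match each planted module to the recovered module with max overlap and
  # compare the sign of the recovered stage correlation with the planted
  # eigengene trend
  sign_acc <- NA_real_
  planted_ids <- sort(unique(truth_labels[truth_labels > 0]))
  if (length(planted_ids) > 0 && any(labels > 0)) {
    stage_cor <- run$trait_cor[run$trait_cor$trait == "stage", ]
    signs <- vapply(planted_ids, function(pid) {
      genes <- names(truth_labels)[truth_labels == pid]
      rec <- labels[genes]
      rec <- rec[rec > 0]
      if (length(rec) == 0) return(NA)
      matched <- paste0("M", names(sort(table(rec), decreasing = TRUE))[1])
      est <- stage_cor$estimate[stage_cor$module == matched]
      if (length(est) == 0) return(NA)
      planted_trend <- truth$spec$modules[[pid]]$group_shift[3] -
        truth$spec$modules[[pid]]$group_shift[1]
      sign(est) == sign(planted_trend)
    }, logical(1))
    sign_acc <- mean(signs, na.rm = TRUE)
  }

  # planted DEG truth for young vs ad from the planted per-gene effect
  deg_metrics <- c(recall = NA_real_, precision = NA_real_)
  if (!is.null(truth$effect_young_to_ad)) {
    eff <- truth$effect_young_to_ad[names(labels)]
    true_deg <- names(eff)[abs(eff) >= log2(run$config$fc_threshold)]
    called <- unlist(deg_filter(
      run$degs[run$degs$contrast == "young_vs_ad", ],
      run$config$fc_threshold, run$config$fdr), use.names = FALSE)
    if (length(true_deg) > 0) {
      deg_metrics["recall"] <- mean(true_deg %in% called)
    }
    if (length(called) > 0) {
      deg_metrics["precision"] <- mean(called %in% true_deg)
    }
  }

  pres_strong <- if (!is.null(run$preservation)) {
    mean(run$preservation$preservation == "strong")
  } else NA_real_

  sens <- NA_real_; efdr <- NA_real_
  if (!is.null(run$diff_edges) && nrow(truth$perturbed) > 0) {
    pert_nodes <- unique(c(truth$perturbed$source, truth$perturbed$target))
    de <- run$diff_edges
    corridor <- de$source %in% pert_nodes | de$target %in% pert_nodes
    sens <- mean(de$passes[corridor])
    if (any(de$passes)) efdr <- mean(!corridor[de$passes])
  }

  tibble::tibble(
    metric = c("module_recovery_ari", "stage_sign_accuracy",
               "deg_recall", "deg_precision", "preservation_strong_frac",
               "diffedge_sensitivity", "diffedge_fdr"),
    value = unname(c(ari, sign_acc, deg_metrics["recall"],
                     deg_metrics["precision"], pres_strong, sens, efdr)))
}
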