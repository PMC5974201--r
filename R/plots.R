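#' Module-trait correlation heatmap
#'
#' Tile grid of modules x traits colored by the Pearson correlation, with
#' the correlation and its p-value printed in each cell.
#'
#' @param trait_cor Output of [module_trait_correlation()].
#' @return A ggplot object.
#' @export
plot_module_trait <- function(trait_cor) {
  trait_cor |>
    dplyr::mutate(label = sprintf("%.2f\n(%.1e)", .data$estimate,
                                  .data$p.value)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$trait, y = .data$module,
                                 fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.7) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cor") +
    ggplot2::theme_minimal()
}

#' Per-sample module eigengene profiles
#'
#' Eigengene expression per sample, grouped and colored by study group, one
#' panel per module.
#'
#' @param me Module x sample eigengene matrix ([module_eigengenes()]).
#' @param dataset The [expression_dataset()] the eigengenes came from
#'   (supplies the group labels).
#' @return A ggplot object.
#' @export
plot_eigengenes <- function(me, dataset) {
  groups <- dataset$samples
  tibble::as_tibble(me, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "sample_id",
                        values_to = "eigengene") |>
    dplyr::left_join(groups, by = "sample_id") |>
    dplyr::mutate(sample_id = factor(.data$sample_id,
                                     levels = groups$sample_id)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$eigengene,
                                 fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = "sample", y = "module eigengene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
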