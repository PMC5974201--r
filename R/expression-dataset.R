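#' Expression dataset container
#'
#' Bundles a genes x samples matrix of normalized log-scale intensities with
#' per-sample metadata. This is the common currency of the pipeline: the
#' synthetic generator produces it, the readers construct it from files, and
#' every downstream stage consumes it.
#'
#' @param expr Numeric matrix, genes in rows (unique rownames = gene symbols),
#'   samples in columns (unique colnames = sample ids). No missing values.
#' @param samples Data frame of per-sample metadata with at least a
#'   `sample_id` column matching `colnames(expr)`; typically also `group`
#'   (one of `"young"`, `"aging"`, `"ad"` or dataset-specific), `age` (years)
#'   and `sex` (`"F"`/`"M"`).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `expr` (the matrix) and `samples` (a tibble, row order matching the
#'   matrix columns).
#' @export
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    group = c("young", "young", "ad", "ad"))
#' expression_dataset(m, meta)
expression_dataset <- function(expr, samples) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("`expr` must have gene rownames and sample colnames.")
  }
  if (anyNA(expr)) abort("`expr` must not contain missing values.")
  if (anyDuplicated(rownames(expr))) {
    dup <- rownames(expr)[duplicated(rownames(expr))][1]
    abort(paste0("Duplicate gene id in `expr`: '", dup, "'."))
  }
  if (anyDuplicated(colnames(expr))) {
    dup <- colnames(expr)[duplicated(colnames(expr))][1]
    abort(paste0("Duplicate sample id in `expr`: '", dup, "'."))
  }
  samples <- tibble::as_tibble(samples)
  if (!"sample_id" %in% names(samples)) {
    abort("`samples` must have a `sample_id` column.")
  }
  if (!setequal(samples$sample_id, colnames(expr)) ||
      nrow(samples) != ncol(expr)) {
    abort("`samples$sample_id` must match `colnames(expr)` one-to-one.")
  }
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  structure(list(expr = expr, samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$expr), " genes x ",
      ncol(x$expr), " samples\n", sep = "")
  if ("group" %in% names(x$samples)) {
    tab <- table(x$samples$group)
    cat("groups: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$expr)

#' Tidy an expression dataset into long form
#'
#' @param x An [expression_dataset()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample_id`, `value` joined with the
#'   sample metadata.
#' @export
tidy.expression_dataset <- function(x, ...) {
  long <- tibble::as_tibble(x$expr, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Subset an expression dataset
#'
#' @param x An [expression_dataset()].
#' @param genes Optional character vector of genes to keep (order preserved).
#' @param sample_ids Optional character vector of samples to keep.
#' @return An [expression_dataset()].
#' @export
subset_dataset <- function(x, genes = NULL, sample_ids = NULL) {
  stopifnot(inherits(x, "expression_dataset"))
  expr <- x$expr
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing) > 0) {
      abort(paste0("Genes not in dataset: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    expr <- expr[genes, , drop = FALSE]
  }
  if (!is.null(sample_ids)) expr <- expr[, sample_ids, drop = FALSE]
  meta <- x$samples[x$samples$sample_id %in% colnames(expr), ]
  expression_dataset(expr, meta)
}

#' Write an expression dataset to canonical TSV files
#'
#' Expression goes to `<path>` (first column `gene`, then one column per
#' sample); metadata goes to `<meta_path>` (`sample_id`, `group`, `age`,
#' `sex`, plus any extra columns present).
#'
#' @param x An [expression_dataset()].
#' @param path Output TSV path for the matrix.
#' @param meta_path Output TSV path for the sample metadata.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, meta_path) {
  stopifnot(inherits(x, "expression_dataset"))
  tab <- tibble::as_tibble(x$expr, rownames = "gene")
  readr::write_tsv(tab, path)
  readr::write_tsv(x$samples, meta_path)
  invisible(x)
}
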