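#' Read a probe- or gene-level expression matrix
#'
#' Supports plain TSV (first column = probe/gene id, one column per sample)
#' and the GEO series-matrix text format (directive lines prefixed `!`, the
#' data table delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end`). For series matrices the
#' `!Sample_*` directives are parsed into sample metadata;
#' `!Sample_characteristics_ch1` lines of the form `key: value` become one
#' metadata column per key.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"series_matrix"`.
#' @return A list with `matrix` (probes x samples), and `sample_meta`
#'   (tibble, `sample_id` plus any parsed fields).
#' @export
read_expression <- function(path, format = c("tsv", "series_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, name_repair = "minimal")
    ids <- colnames(tab)[-1]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0) {
      abort(paste0("Duplicate sample column id(s): ",
                   paste(dup, collapse = ", ")))
    }
    mat <- as.matrix(tab[, -1])
    if (!is.numeric(mat)) abort("Non-numeric values in expression table.")
    rownames(mat) <- as.character(tab[[1]])
    meta <- tibble::tibble(sample_id = ids)
    return(list(matrix = mat, sample_meta = meta))
  }
  read_series_matrix(path)
}

read_series_matrix <- function(path) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin) {
    abort("Malformed series matrix: missing table begin/end markers.")
  }
  tab_lines <- lines[(begin + 1):(end - 1)]
  tab <- readr::read_tsv(I(tab_lines), show_col_types = FALSE,
                         name_repair = "minimal")
  ids <- gsub('"', "", colnames(tab)[-1])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample column id(s): ",
                 paste(dup, collapse = ", ")))
  }
  mat <- as.matrix(tab[, -1])
  rownames(mat) <- gsub('"', "", as.character(tab[[1]]))
  colnames(mat) <- ids

  meta <- tibble::tibble(sample_id = ids)
  header <- lines[seq_len(begin - 1)]
  parse_fields <- function(line) {
    parts <- strsplit(sub("^![A-Za-z_0-9]+\t", "", line), "\t")[[1]]
    gsub('^"|"$', "", parts)
  }
  titles <- header[startsWith(header, "!Sample_title")]
  if (length(titles) == 1) meta$title <- parse_fields(titles)
  chars <- header[startsWith(header, "!Sample_characteristics_ch1")]
  for (line in chars) {
    vals <- parse_fields(line)
    if (length(vals) != length(ids)) next
    keys <- sub(":.*$", "", vals)
    key <- names(sort(table(keys), decreasing = TRUE))[1]
    key <- gsub("[^A-Za-z0-9]+", "_", tolower(trimws(key)))
    meta[[key]] <- trimws(sub("^[^:]*:", "", vals))
  }
  list(matrix = mat, sample_meta = meta)
}

#' Interquartile range per gene/probe row
#'
#' Q3 - Q1 with linear interpolation of quantiles (R's default type 7).
#'
#' @param mat Numeric matrix, rows = genes/probes.
#' @return Named numeric vector of IQRs.
#' @export
row_iqr <- function(mat) {
  q <- matrixStats_row_quantiles(mat, probs = c(0.25, 0.75))
  setNames(q[, 2] - q[, 1], rownames(mat))
}

# row-wise quantiles without extra dependencies
matrixStats_row_quantiles <- function(mat, probs) {
  t(apply(mat, 1, quantile, probs = probs, names = FALSE, type = 7))
}

#' Collapse probes to genes by maximum IQR
#'
#' Probes with no annotation or with multiple gene annotations are removed;
#' among probes mapping to the same single gene, the probe with the largest
#' IQR across samples is retained. The result is keyed by gene symbol.
#'
#' @param probe_matrix Probes x samples numeric matrix (probe rownames).
#' @param probe_to_gene Data frame with columns `probe_id`, `gene`; a probe
#'   appearing with more than one distinct gene is treated as multiply
#'   annotated and dropped.
#' @param sample_meta Optional per-sample metadata (tibble with `sample_id`).
#' @return An [expression_dataset()] keyed by gene symbol.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene, sample_meta = NULL) {
  map <- tibble::as_tibble(probe_to_gene) |>
    dplyr::distinct(.data$probe_id, .data$gene) |>
    dplyr::filter(!is.na(.data$gene), .data$gene != "")
  multi <- map |>
    dplyr::count(.data$probe_id) |>
    dplyr::filter(.data$n > 1)
  map <- map |>
    dplyr::filter(!.data$probe_id %in% multi$probe_id,
                  .data$probe_id %in% rownames(probe_matrix))
  if (nrow(map) == 0) {
    abort("No annotated probes remain after removing unannotated and multiply annotated probes.")
  }
  iqr <- row_iqr(probe_matrix[map$probe_id, , drop = FALSE])
  chosen <- map |>
    dplyr::mutate(iqr = unname(iqr[.data$probe_id])) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$iqr, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$probe_id, rownames(probe_matrix)))
  mat <- probe_matrix[chosen$probe_id, , drop = FALSE]
  rownames(mat) <- chosen$gene
  if (is.null(sample_meta)) {
    sample_meta <- tibble::tibble(sample_id = colnames(mat))
  }
  expression_dataset(mat, sample_meta)
}

#' Keep genes whose IQR exceeds a threshold
#'
#' Strict inequality (`IQR > threshold`); gene order is preserved. The
#' default 0.2 reproduces the varying-gene filter used before network
#' construction.
#'
#' @param dataset An [expression_dataset()].
#' @param threshold Non-negative IQR cutoff.
#' @return The filtered [expression_dataset()].
#' @export
iqr_filter <- function(dataset, threshold = 0.2) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (threshold < 0) abort("`threshold` must be >= 0.")
  keep <- row_iqr(dataset$expr) > threshold
  if (!any(keep)) {
    abort(paste0("IQR filter at threshold ", threshold,
                 " removed every gene; lower the threshold."))
  }
  out <- expression_dataset(dataset$expr[keep, , drop = FALSE],
                            dataset$samples)
  attr(out, "truth") <- attr(dataset, "truth")
  out
}

#' Assign samples to study groups by metadata predicates
#'
#' Each rule is a one-sided formula evaluated in the sample metadata; a
#' sample matching exactly one rule gets that group, samples matching no
#' rule are excluded (with a message), and a sample matching two rules is an
#' error. The defaults encode the study stratification: young = 20-50 years
#' without AD, aging = 70-99 years without AD, ad = 70-99 years with AD
#' (requires logical/0-1 metadata column `ad` and numeric `age`).
#'
#' @param dataset An [expression_dataset()] whose metadata carries the
#'   fields the rules reference.
#' @param rules Named list of one-sided formulas, names = group labels.
#' @return An [expression_dataset()] restricted to matched samples, with a
#'   `group` metadata column.
#' @export
stratify <- function(dataset,
                     rules = list(
                       young = ~ age >= 20 & age <= 50 & !ad,
                       aging = ~ age >= 70 & age <= 99 & !ad,
                       ad = ~ age >= 70 & age <= 99 & ad)) {
  stopifnot(inherits(dataset, "expression_dataset"))
  meta <- dataset$samples
  hits <- vapply(rules, function(f) {
    v <- rlang::eval_tidy(rlang::f_rhs(f), data = meta)
    as.logical(v)
  }, logical(nrow(meta)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(meta))
  n_match <- rowSums(hits, na.rm = TRUE)
  if (any(n_match > 1)) {
    bad <- meta$sample_id[which(n_match > 1)[1]]
    abort(paste0("Sample '", bad, "' matches more than one group rule."))
  }
  keep <- n_match == 1
  if (sum(!keep) > 0) {
    inform(paste0("stratify: excluded ", sum(!keep),
                  " sample(s) matching no rule."))
  }
  if (!any(keep)) abort("No samples match any stratification rule.")
  group <- rep(NA_character_, nrow(meta))
  for (j in seq_along(rules)) {
    group[hits[, j] & keep] <- names(rules)[j]
  }
  meta$group <- group
  out <- expression_dataset(dataset$expr[, keep, drop = FALSE], meta[keep, ])
  out
}

#' Encode sample traits for module-trait correlation
#'
#' Ordinal stage (young 0, aging 1, AD 2), binary AD indicator (young and
#' aging 0, AD 1), and age in years.
#'
#' @param dataset An [expression_dataset()] with `group` (young/aging/ad)
#'   and `age` metadata.
#' @return Tibble: `sample_id`, `stage`, `ad_indicator`, `age`.
#' @export
encode_traits <- function(dataset) {
  meta <- dataset$samples
  if (!all(c("group", "age") %in% names(meta))) {
    abort("Sample metadata must contain `group` and `age`.")
  }
  bad <- setdiff(unique(meta$group), c("young", "aging", "ad"))
  if (length(bad) > 0) {
    abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  tibble::tibble(
    sample_id = meta$sample_id,
    stage = unname(c(young = 0, aging = 1, ad = 2)[meta$group]),
    ad_indicator = as.numeric(meta$group == "ad"),
    age = meta$age)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tabs).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "",
                        USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
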