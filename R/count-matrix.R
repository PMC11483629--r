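#' Gene-level count matrix with sample annotations
#'
#' The pipeline's raw input: an integer matrix of counts (genes in rows,
#' samples in columns) together with a per-sample annotation table giving
#' tissue, developmental stage, experimental batch and replicate.
#'
#' @param counts Integer matrix, genes x samples, with unique row and column
#'   names. Values must be non-negative and integral.
#' @param sample_meta A data.frame with columns `sample_id`, `tissue`,
#'   `stage`, `batch`, `replicate`, covering every column of `counts`.
#' @param tissue_levels,stage_levels Optional declared factor levels; defaults
#'   to the order of first appearance in `sample_meta`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `meta` (data.frame, one row per column of `counts`,
#'   in column order, with `tissue`/`stage`/`batch` as factors).
#' @export
count_matrix <- function(counts, sample_meta, tissue_levels = NULL,
                         stage_levels = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort_validation("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_validation("`counts` must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    abort_validation("duplicate gene_id in counts: ",
                     paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                           collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    abort_validation("duplicate sample_id in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    abort_validation("counts must be non-negative integers")
  required <- c("sample_id", "tissue", "stage", "batch", "replicate")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols))
    abort_validation("sample_meta lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sample_meta$sample_id))
    abort_validation("duplicate sample_id in metadata")
  uncovered <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(uncovered))
    abort_validation("metadata does not cover samples: ",
                     paste(uncovered, collapse = ", "))
  meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  tl <- tissue_levels %||% unique(as.character(meta$tissue))
  sl <- stage_levels %||% unique(as.character(meta$stage))
  if (!all(as.character(meta$tissue) %in% tl))
    abort_validation("unknown tissue level: ",
                     paste(setdiff(meta$tissue, tl), collapse = ", "))
  if (!all(as.character(meta$stage) %in% sl))
    abort_validation("unknown stage level: ",
                     paste(setdiff(meta$stage, sl), collapse = ", "))
  meta$tissue <- factor(as.character(meta$tissue), levels = tl)
  meta$stage <- factor(as.character(meta$stage), levels = sl)
  meta$batch <- factor(meta$batch)
  storage.mode(counts) <- "double"
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  tissues:", paste(levels(x$meta$tissue), collapse = ", "), "\n")
  cat("  stages: ", paste(levels(x$meta$stage), collapse = ", "), "\n")
  cat("  batches:", nlevels(x$meta$batch), "\n")
  invisible(x)
}

#' Subset a count matrix to one tissue
#'
#' @param x A [count_matrix()].
#' @param tissue A tissue level present in the metadata.
#' @return A `count_matrix` restricted to samples of `tissue`, with unused
#'   batch levels dropped.
#' @export
subset_tissue <- function(x, tissue) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- x$meta$tissue == tissue
  if (!any(keep)) abort_validation("no samples for tissue ", tissue)
  meta <- x$meta[keep, , drop = FALSE]
  meta$batch <- droplevels(meta$batch)
  rownames(meta) <- NULL
  structure(list(counts = x$counts[, keep, drop = FALSE], meta = meta),
            class = "count_matrix")
}

# condition = tissue x stage factor (drops empty combinations)
condition_factor <- function(meta) {
  interaction(meta$tissue, meta$stage, drop = TRUE, lex.order = TRUE)
}
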