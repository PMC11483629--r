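#' Median-of-ratios size factors
#'
#' Per-sample library-size factors estimated with the median-of-ratios
#' method: for each sample, the median over genes expressed in every sample
#' of the ratio between that sample's count and the gene's geometric-mean
#' count. Factors are rescaled to geometric mean 1 so that the scale of the
#' normalized counts is anchored and true factors are identifiable in
#' recovery experiments.
#'
#' @param x A [count_matrix()] or a numeric count matrix.
#' @return Named positive numeric vector of per-sample size factors with
#'   geometric mean 1.
#' @export
estimate_size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    abort_validation("size factors undefined: no gene has positive counts in every sample")
  lc <- log(counts[pos, , drop = FALSE])
  lgeo <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) median(exp(col - lgeo)))
  sf <- sf / geomean(sf)
  names(sf) <- colnames(counts)
  sf
}

#' Variance-stabilizing log transform of normalized counts
#'
#' Transforms counts to `log2(count / size_factor + 1)`: monotone in counts,
#' zero maps to zero, and approximately homoskedastic at moderate-to-high
#' expression. This is a documented surrogate for a dispersion-dependent VST;
#' all downstream operations consume the transformed matrix generically, so
#' the transform is swappable.
#'
#' @param x A [count_matrix()].
#' @param size_factors Optional per-sample factors; estimated with
#'   [estimate_size_factors()] when omitted.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (genes x samples, log2 scale), `size_factors`, and `meta`.
#' @export
transform_counts <- function(x, size_factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  sf <- size_factors %||% estimate_size_factors(x)
  if (length(sf) != ncol(x$counts))
    abort_validation("size_factors length does not match sample count")
  if (any(sf <= 0)) abort_validation("size factors must be positive")
  values <- log2(sweep(x$counts, 2, sf, "/") + 1)
  structure(list(values = values, size_factors = sf, meta = x$meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# linear-scale normalized counts (count / size factor) backing a
# normalized_matrix
linear_normalized <- function(norm) 2^norm$values - 1

#' Expression filter on mean normalized counts
#'
#' Keeps genes whose mean normalized count (linear scale, count/size-factor)
#' reaches `threshold` in at least one group. The default grouping is the
#' condition (tissue x stage); `by = "sample"` reproduces the global
#' every-sample variant of the filter.
#'
#' @param norm A `normalized_matrix`.
#' @param threshold Mean normalized count required in at least one group
#'   (default 50).
#' @param by `"condition"` (tissue x stage means) or `"sample"` (each sample
#'   is its own group).
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(norm, threshold = 50, by = c("condition", "sample")) {
  stopifnot(inherits(norm, "normalized_matrix"))
  by <- match.arg(by)
  lin <- linear_normalized(norm)
  if (by == "condition") {
    grp <- condition_factor(norm$meta)
    if (nlevels(grp) == 0) abort_validation("no condition groups")
    sums <- t(rowsum(t(lin), grp))            # genes x groups
    means <- sweep(sums, 2, as.vector(table(grp)), "/")
  } else {
    means <- lin
  }
  # tolerance absorbs the float round-trip through the log2 representation
  rownames(lin)[apply(means >= threshold - 1e-8 * max(1, threshold), 1, any)]
}

#' Remove batch effects from a transformed matrix
#'
#' Per gene, removes the batch-level mean offsets estimated by ordinary least
#' squares while retaining the condition (tissue x stage) design, then
#' restores each gene's grand mean exactly. With a single batch the input is
#' returned unchanged. The least-squares removal is delegated to
#' \code{limma::removeBatchEffect}.
#'
#' @param norm A `normalized_matrix` whose metadata carries a `batch` factor.
#' @return A `normalized_matrix` with batch offsets removed.
#' @export
remove_batch <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  batch <- droplevels(norm$meta$batch)
  if (nlevels(batch) < 2) return(norm)
  cond <- condition_factor(norm$meta)
  design <- stats::model.matrix(~cond)
  full <- cbind(design, stats::model.matrix(~batch)[, -1, drop = FALSE])
  if (qr(full)$rank < ncol(full))
    abort_validation("batch is confounded with condition; offsets not identifiable")
  adjusted <- limma::removeBatchEffect(norm$values, batch = batch, design = design)
  adjusted <- adjusted + (rowMeans(norm$values) - rowMeans(adjusted))
  structure(list(values = adjusted, size_factors = norm$size_factors,
                 meta = norm$meta), class = "normalized_matrix")
}
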