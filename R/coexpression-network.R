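#' Center and scale expression profiles
#'
#' Standardizes each gene row of a transformed expression matrix to mean 0
#' and SD 1 (the scale on which all downstream network analysis operates).
#' Constant rows carry no profile information and are dropped with a warning.
#'
#' @param norm A `normalized_matrix` or a plain numeric matrix
#'   (genes x samples).
#' @param genes Optional character vector restricting to a gene subset.
#' @return Numeric matrix of standardized rows, with attribute `dropped`
#'   giving the number of constant rows removed.
#' @export
scale_profiles <- function(norm, genes = NULL) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(values))
    if (length(missing))
      abort_validation("genes not in matrix: ", paste(missing, collapse = ", "))
    values <- values[genes, , drop = FALSE]
  }
  n <- ncol(values)
  if (n < 3) abort_validation("profile scaling needs >= 3 samples")
  m <- rowMeans(values)
  centered <- values - m
  s <- sqrt(rowSums(centered^2) / (n - 1))
  constant <- s < 1e-12
  if (any(constant))
    warning(sum(constant), " constant profile(s) dropped")
  out <- centered[!constant, , drop = FALSE] / s[!constant]
  attr(out, "dropped") <- sum(constant)
  out
}

#' Permutation-calibrated correlation threshold
#'
#' Estimates the null edge threshold for a co-expression graph: in each of
#' `replications` rounds, every gene's profile is independently permuted
#' across samples (destroying all between-gene correlation while preserving
#' marginals), Pearson correlations are computed for a random subset of gene
#' pairs, and the configured upper quantile of that round's correlations is
#' recorded. The returned threshold is the median of the per-round quantiles.
#'
#' @param profiles Standardized profile matrix from [scale_profiles()].
#' @param replications Number of permutation rounds (default 1000).
#' @param quantile Upper quantile per round (default 0.99995).
#' @param pairs_per_rep Gene pairs sampled per round; all pairs are used when
#'   the total number of pairs does not exceed this (default 200000).
#' @param seed Integer seed; the result is deterministic given it.
#' @return Single numeric threshold (median of per-round quantiles).
#' @export
permutation_threshold <- function(profiles, replications = 1000,
                                  quantile = 0.99995,
                                  pairs_per_rep = 200000, seed = 1L) {
  ng <- nrow(profiles) ; n <- ncol(profiles)
  if (ng < 2) abort_validation("need >= 2 genes")
  if (pairs_per_rep < 1 / (1 - quantile))
    warning("pairs_per_rep below 1/(1 - quantile); the quantile is poorly resolved")
  n_pairs <- ng * (ng - 1) / 2
  full <- n_pairs <= pairs_per_rep
  with_seed(seed, {
    qs <- numeric(replications)
    for (r in seq_len(replications)) {
      perm <- profiles
      for (g in seq_len(ng)) perm[g, ] <- perm[g, sample.int(n)]
      # rows remain standardized, so r is a scaled dot product
      if (full) {
        cc <- tcrossprod(perm) / (n - 1)
        rv <- cc[upper.tri(cc)]
      } else {
        i <- sample.int(ng, pairs_per_rep, replace = TRUE)
        j <- sample.int(ng - 1L, pairs_per_rep, replace = TRUE)
        j <- ifelse(j >= i, j + 1L, j)        # uniform over off-diagonal pairs
        rv <- rowSums(perm[i, , drop = FALSE] * perm[j, , drop = FALSE]) / (n - 1)
      }
      qs[r] <- stats::quantile(rv, quantile, names = FALSE)
    }
    stats::median(qs)
  })
}

#' Build the thresholded co-expression graph
#'
#' Draws an edge between every gene pair whose Pearson correlation exceeds
#' the threshold (strictly), then applies one minimum-degree removal pass:
#' nodes with fewer edges than `min_degree` are deleted (degrees are taken
#' from the freshly built graph; the pass is not iterated unless requested).
#'
#' @param profiles Standardized profile matrix from [scale_profiles()].
#' @param threshold Edge threshold in (-1, 1].
#' @param min_degree Minimum node degree retained (default 50).
#' @param mode `"signed"` keeps only positive co-regulation (r > threshold);
#'   `"absolute"` thresholds `|r|`.
#' @param iterate Repeat the degree-removal pass to a fixed point.
#' @return Object of class `coexpression_graph`: list with `nodes` (kept gene
#'   ids), `edges` (data.frame gene_a, gene_b, r), `threshold`, `min_degree`,
#'   `removed` (gene ids deleted by the degree filter), `all_nodes`.
#' @export
build_graph <- function(profiles, threshold, min_degree = 50,
                        mode = c("signed", "absolute"), iterate = FALSE) {
  mode <- match.arg(mode)
  if (nrow(profiles) == 0) abort_validation("empty profile set")
  if (threshold <= -1 || threshold > 1)
    abort_validation("threshold must lie in (-1, 1]")
  n <- ncol(profiles)
  cc <- tcrossprod(profiles) / (n - 1)
  cc <- pmin(pmax(cc, -1), 1)    # guard float noise so r > 1 never fires
  w <- if (mode == "absolute") abs(cc) else cc
  sel <- which(upper.tri(w) & w > threshold, arr.ind = TRUE)
  genes <- rownames(profiles)
  edges <- data.frame(gene_a = genes[sel[, 1]], gene_b = genes[sel[, 2]],
                      r = cc[sel], stringsAsFactors = FALSE)
  keep <- rep(TRUE, length(genes)) ; names(keep) <- genes
  repeat {
    deg <- tabulate(factor(c(edges$gene_a, edges$gene_b),
                           levels = genes[keep]), nbins = sum(keep))
    low <- genes[keep][deg < min_degree]
    keep[low] <- FALSE
    edges <- edges[keep[edges$gene_a] & keep[edges$gene_b], , drop = FALSE]
    if (!iterate || length(low) == 0) break
  }
  rownames(edges) <- NULL
  structure(list(nodes = genes[keep], edges = edges, threshold = threshold,
                 min_degree = min_degree, removed = genes[!keep],
                 all_nodes = genes),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf("<coexpression_graph> %d nodes, %d edges (threshold %.4f, min degree %d, %d removed)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$min_degree,
              length(x$removed)))
  invisible(x)
}

#' Node degrees of a co-expression graph
#'
#' @param graph A `coexpression_graph`.
#' @return Named integer vector over `graph$nodes`.
#' @export
graph_degree <- function(graph) {
  d <- tabulate(factor(c(graph$edges$gene_a, graph$edges$gene_b),
                       levels = graph$nodes), nbins = length(graph$nodes))
  names(d) <- graph$nodes
  d
}

# internal: edge list as integer indices into graph$nodes
edge_index <- function(graph) {
  cbind(match(graph$edges$gene_a, graph$nodes),
        match(graph$edges$gene_b, graph$nodes))
}
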