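#' Stage z-score profiles of gene clusters
#'
#' For each gene: the average transformed expression per developmental stage,
#' z-scored across stages (mean 0, SD 1; constant genes map to all zeros).
#' The profile of a cluster is the per-stage mean of its members' z-scores —
#' the statistic displayed in stage-profile heatmaps.
#'
#' @param norm A `normalized_matrix`.
#' @param membership Cluster assignment: vector named by gene id (e.g.
#'   `partition$membership` from [louvain()]).
#' @param tissue Optional tissue to restrict samples to.
#' @return Object of class `cluster_profile`: list with `gene_z` (gene x
#'   stage z-score matrix), `profile` (cluster x stage mean z-scores),
#'   `sizes` (cluster sizes), `stages`.
#' @export
stage_zscore_profiles <- function(norm, membership, tissue = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  genes <- names(membership)
  if (is.null(genes)) abort_validation("membership must be named by gene id")
  missing <- setdiff(genes, rownames(norm$values))
  if (length(missing))
    abort_validation("partition genes absent from matrix: ",
                     paste(utils::head(missing, 5), collapse = ", "))
  keep <- rep(TRUE, nrow(norm$meta))
  if (!is.null(tissue)) keep <- norm$meta$tissue == tissue
  if (!any(keep)) abort_validation("no samples selected")
  stage <- droplevels(norm$meta$stage[keep])
  if (any(table(stage) == 0)) abort_validation("a stage level has no samples")
  v <- norm$values[genes, keep, drop = FALSE]
  sums <- t(rowsum(t(v), stage))
  sm <- sweep(sums, 2, as.vector(table(stage)), "/")   # gene x stage means
  mu <- rowMeans(sm)
  ctr <- sm - mu
  sd <- sqrt(rowSums(ctr^2) / (ncol(sm) - 1))
  z <- ctr / ifelse(sd > 1e-12, sd, Inf)               # constant genes -> 0
  cl <- factor(membership)
  prof <- rowsum(z, cl) / as.vector(table(cl))
  structure(list(gene_z = z, profile = prof,
                 sizes = table(cl), stages = levels(stage)),
            class = "cluster_profile")
}

#' Exclusive cluster-intersection counts (UpSet semantics)
#'
#' Given cluster assignments from several tissues over a shared gene
#' universe, counts genes by their exact membership pattern: each gene is
#' counted in exactly the combination of tissue clusters that contain it, so
#' the disjoint patterns partition the universe. This is the count backing an
#' UpSet plot of the largest intersections.
#'
#' @param assignments Named list (one element per tissue) of cluster
#'   assignments, each a vector named by gene id (cluster labels) or a
#'   data.frame with columns `gene_id` and `cluster`.
#' @param top_k Number of largest patterns to report (default 25).
#' @param universe Optional gene universe; defaults to the union of assigned
#'   genes. Genes in no set are counted under the empty pattern.
#' @return Object of class `intersection_table`: list with `top`
#'   (data.frame pattern/count, the `top_k` largest), `all` (every pattern),
#'   `set_sizes` (per tissue-cluster totals), `n_genes`.
#' @export
cluster_intersections <- function(assignments, top_k = 25, universe = NULL) {
  if (is.null(names(assignments)) || any(names(assignments) == ""))
    abort_validation("assignments must be a named list (one element per tissue)")
  sets <- list()
  for (t in names(assignments)) {
    a <- assignments[[t]]
    if (is.data.frame(a)) {
      genes <- as.character(a$gene_id) ; cl <- as.character(a$cluster)
    } else {
      genes <- names(a) ; cl <- as.character(a)
    }
    if (is.null(genes)) abort_validation("assignment for ", t, " lacks gene ids")
    if (anyDuplicated(genes))
      abort_validation("duplicate gene within tissue ", t, ": ",
                       paste(unique(genes[duplicated(genes)]), collapse = ", "))
    for (lab in unique(cl))
      sets[[paste(t, lab, sep = ":")]] <- genes[cl == lab]
  }
  universe <- universe %||% unique(unlist(sets, use.names = FALSE))
  members <- lapply(sets, intersect, universe)
  hit <- vapply(members, function(g) universe %in% g,
                logical(length(universe)))
  hit <- matrix(hit, nrow = length(universe),
                dimnames = list(universe, names(sets)))
  # canonical pattern key: member set labels, sorted; "(none)" for genes in
  # no set (kept so the patterns partition the universe)
  pattern <- apply(hit, 1, function(h)
    if (any(h)) paste(sort(names(sets)[h], method = "radix"), collapse = "&")
    else "(none)")
  tab <- table(pattern)
  all_df <- data.frame(pattern = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  all_df <- all_df[order(-all_df$count, all_df$pattern, method = "radix"), ,
                   drop = FALSE]
  rownames(all_df) <- NULL
  structure(list(top = utils::head(all_df, top_k), all = all_df,
                 set_sizes = vapply(sets, length, integer(1)),
                 n_genes = length(universe)),
            class = "intersection_table")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same element universe: 1 for identical partitions, approximately 0 for
#' independent ones.
#'
#' @param a,b Partition label vectors named by element (or unnamed and
#'   aligned by position).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    if (is.null(names(a)) || is.null(names(b)) ||
        !setequal(names(a), names(b)))
      abort_validation("partitions cover different element universes")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    abort_validation("partitions cover different element universes")
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(0)   # both trivial partitions
  (sum_ij - expected) / (max_index - expected)
}
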