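# Tabular I/O: one dialect everywhere — tab-delimited, UTF-8, header row,
# no quoting; gene ids are opaque strings.

#' Read a count matrix and its sample metadata from TSV files
#'
#' @param counts_path TSV with first column `gene_id` and one column per
#'   sample (integer counts).
#' @param metadata_path TSV with columns `sample_id`, `tissue`, `stage`,
#'   `batch`, `replicate`.
#' @param tissue_levels,stage_levels Optional declared factor levels.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, metadata_path, tissue_levels = NULL,
                        stage_levels = NULL) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    abort_validation("counts file must start with a gene_id column")
  if (anyDuplicated(tab$gene_id))
    abort_validation("duplicate gene_id in ", counts_path, ": ",
                     paste(unique(tab$gene_id[duplicated(tab$gene_id)]),
                           collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != round(m)) || any(m < 0))
    abort_validation("counts must be non-negative integers in ", counts_path)
  rownames(m) <- tab$gene_id
  meta <- read_metadata(metadata_path)
  count_matrix(m, meta, tissue_levels = tissue_levels,
               stage_levels = stage_levels)
}

#' Read a sample metadata TSV
#'
#' @param path TSV with columns `sample_id`, `tissue`, `stage`, `batch`,
#'   `replicate`.
#' @return A validated data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue", "stage", "batch", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    abort_validation("metadata lacks columns: ",
                     paste(missing_cols, collapse = ", "))
  meta
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a count matrix (and its metadata) to TSV files
#'
#' @param x A [count_matrix()].
#' @param counts_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(x$meta, metadata_path)
  invisible(c(counts_path, metadata_path))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' pipeline's reference parameters: DEG FDR threshold 0.001, expression
#' filter at mean normalized count 50, permutation threshold from the median
#' 99.995% quantile of 1000 replications, minimum node degree 50, Louvain
#' resolution 0.75, the 25 largest intersections, and measurement statistics
#' at alpha 0.05.
#'
#' @param deg_fdr DEG call threshold on the BH-adjusted LRT p-value.
#' @param expr_threshold Expression filter (mean normalized counts).
#' @param apply_expression_filter Apply the filter before network
#'   construction.
#' @param reps,quantile,pairs_per_rep Permutation-threshold settings.
#' @param min_degree Minimum co-expression degree retained.
#' @param resolution Louvain resolution gamma.
#' @param top_k_intersections Number of largest patterns reported.
#' @param stats_alpha Alpha for the measurement statistics.
#' @param include_batch Add the experimental batch as LRT covariate when the
#'   data has more than one batch.
#' @param seed Master seed; per-stage sub-seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(deg_fdr = 0.001, expr_threshold = 50,
                            apply_expression_filter = TRUE,
                            reps = 1000, quantile = 0.99995,
                            pairs_per_rep = 200000, min_degree = 50,
                            resolution = 0.75, top_k_intersections = 25,
                            stats_alpha = 0.05, include_batch = TRUE,
                            seed = 1L) {
  cfg <- list(deg_fdr = deg_fdr, expr_threshold = expr_threshold,
              apply_expression_filter = apply_expression_filter,
              reps = reps, quantile = quantile,
              pairs_per_rep = pairs_per_rep, min_degree = min_degree,
              resolution = resolution,
              top_k_intersections = top_k_intersections,
              stats_alpha = stats_alpha, include_batch = include_batch,
              seed = as.integer(seed))
  stopifnot(cfg$deg_fdr > 0, cfg$deg_fdr < 1, cfg$expr_threshold >= 0,
            cfg$reps >= 1, cfg$quantile > 0, cfg$quantile <= 1,
            cfg$min_degree >= 0, cfg$resolution > 0,
            cfg$top_k_intersections >= 1,
            cfg$stats_alpha > 0, cfg$stats_alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains all stages on a count matrix: normalization (size factors +
#' variance-stabilizing log transform, batch adjustment when the metadata
#' has several batches), per-tissue stage LRT, co-expression network with a
#' permutation-calibrated threshold, Louvain clustering, cluster stage
#' profiles and cross-tissue intersections, and (when measurement tables are
#' supplied) the phenotype and NAF statistics. Every output is written as
#' TSV under `out_dir` and listed with its checksum in a machine-readable
#' manifest (`manifest.json`). The run is deterministic under a fixed seed.
#'
#' Tissues whose DEG set is too small to support the network stage are
#' skipped there with a logged notice.
#'
#' @param x A [count_matrix()].
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param phenotypes Optional phenotype table (see [phenotype_stats()]).
#' @param naf Optional NAF fraction table (see [naf_test()]).
#' @param truth Optional generator ground truth (from [generate_counts()]);
#'   when given, the manifest reports the adjusted Rand index between
#'   recovered clusters and planted modules per tissue.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(x, out_dir, config = pipeline_config(),
                         phenotypes = NULL, naf = NULL, truth = NULL) {
  stopifnot(inherits(x, "count_matrix"), inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  manifest <- list(parameters = unclass(config), seed = config$seed,
                   n_genes = nrow(x$counts), n_samples = ncol(x$counts),
                   stages = list(), notices = character(0))
  files <- character(0)

  ## normalize
  norm <- tryCatch({
    sf <- estimate_size_factors(x)
    n <- transform_counts(x, sf)
    if (nlevels(droplevels(n$meta$batch)) > 1) n <- remove_batch(n)
    n
  }, error = function(e) stage_fail("normalize", e))
  files["size_factors"] <- write_tsv(
    data.frame(sample_id = names(norm$size_factors),
               size_factor = as.numeric(norm$size_factors)),
    file.path(out_dir, "size_factors.tsv"))
  files["normalized"] <- write_tsv(
    data.frame(gene_id = rownames(norm$values), norm$values,
               check.names = FALSE),
    file.path(out_dir, "normalized_vst.tsv"))
  expressed <- if (config$apply_expression_filter)
    expression_filter(norm, threshold = config$expr_threshold) else
      rownames(norm$values)
  manifest$stages$normalize <- list(n_expressed = length(expressed))

  ## per-tissue DEG -> network -> clusters
  tissues <- levels(droplevels(x$meta$tissue))
  assignments <- list()
  ari <- list()
  for (t in tissues) {
    deg <- tryCatch(
      lrt_stage(x, tissue = t, include_batch = config$include_batch,
                fdr_threshold = config$deg_fdr),
      error = function(e) stage_fail(paste0("deg[", t, "]"), e))
    files[paste0("deg_", t)] <- write_tsv(deg, file.path(out_dir, paste0("deg_", t, ".tsv")))
    deg_genes <- intersect(deg$gene_id[deg$is_deg], expressed)
    manifest$stages[[paste0("deg_", t)]] <-
      list(n_deg = sum(deg$is_deg), n_deg_expressed = length(deg_genes))
    if (length(deg_genes) < max(3, config$min_degree + 1)) {
      note <- paste0("tissue ", t, ": DEG set too small (",
                     length(deg_genes), "); network/cluster stages skipped")
      message(note)
      manifest$notices <- c(manifest$notices, note)
      next
    }
    res <- tryCatch({
      keep <- norm$meta$tissue == t
      prof <- scale_profiles(norm$values[deg_genes, keep, drop = FALSE])
      thr <- permutation_threshold(prof, replications = config$reps,
                                   quantile = config$quantile,
                                   pairs_per_rep = config$pairs_per_rep,
                                   seed = derive_seed(config$seed, paste0("perm_", t)))
      g <- build_graph(prof, thr, min_degree = config$min_degree)
      part <- if (length(g$nodes) && nrow(g$edges))
        louvain(g, resolution = config$resolution,
                seed = derive_seed(config$seed, paste0("louvain_", t)))
      else NULL
      list(prof = prof, thr = thr, graph = g, part = part)
    }, error = function(e) stage_fail(paste0("network[", t, "]"), e))
    files[paste0("edges_", t)] <- write_tsv(res$graph$edges,
                                            file.path(out_dir, paste0("edges_", t, ".tsv")))
    net_info <- list(threshold = res$thr, n_nodes = length(res$graph$nodes),
                     n_edges = nrow(res$graph$edges),
                     n_removed = length(res$graph$removed))
    if (is.null(res$part)) {
      note <- paste0("tissue ", t, ": graph empty after degree filter; cluster stage skipped")
      message(note)
      manifest$notices <- c(manifest$notices, note)
      manifest$stages[[paste0("network_", t)]] <- net_info
      next
    }
    part <- res$part
    net_info$modularity <- part$modularity
    net_info$n_clusters <- length(unique(part$membership))
    manifest$stages[[paste0("network_", t)]] <- net_info
    files[paste0("clusters_", t)] <- write_tsv(
      data.frame(gene_id = names(part$membership), tissue = t,
                 cluster = as.integer(part$membership)),
      file.path(out_dir, paste0("clusters_", t, ".tsv")))
    assignments[[t]] <- part$membership
    prof_tab <- stage_zscore_profiles(norm, part$membership, tissue = t)
    files[paste0("profiles_", t)] <- write_tsv(
      data.frame(tissue = t, cluster = rownames(prof_tab$profile),
                 prof_tab$profile, check.names = FALSE),
      file.path(out_dir, paste0("profiles_", t, ".tsv")))
    if (!is.null(truth)) {
      planted <- truth$module_membership[names(part$membership), t]
      ari[[t]] <- adjusted_rand_index(part$membership, planted)
    }
  }

  ## cross-tissue intersections
  if (length(assignments) >= 1) {
    inter <- cluster_intersections(assignments,
                                   top_k = config$top_k_intersections)
    files["intersections"] <- write_tsv(inter$all,
                                        file.path(out_dir, "intersections.tsv"))
    manifest$stages$intersections <- list(n_patterns = nrow(inter$all),
                                          n_genes = inter$n_genes)
  }

  ## measurement statistics
  if (!is.null(phenotypes)) {
    st <- tryCatch(phenotype_stats(phenotypes, alpha = config$stats_alpha),
                   error = function(e) stage_fail("stats", e))
    files["phenotype_models"] <- write_tsv(st$models,
                                           file.path(out_dir, "phenotype_models.tsv"))
    files["phenotype_letters"] <- write_tsv(st$letters,
                                            file.path(out_dir, "phenotype_letters.tsv"))
    manifest$stages$phenotypes <- list(n_models = nrow(st$models),
                                       n_significant = sum(st$models$significant))
  }
  if (!is.null(naf)) {
    nf <- tryCatch(naf_test(naf, alpha = config$stats_alpha),
                   error = function(e) stage_fail("naf", e))
    files["naf_models"] <- write_tsv(nf$models, file.path(out_dir, "naf_models.tsv"))
    files["naf_letters"] <- write_tsv(nf$letters, file.path(out_dir, "naf_letters.tsv"))
    manifest$stages$naf <- list(n_models = nrow(nf$models),
                                n_significant = sum(nf$models$significant))
  }

  if (length(ari)) manifest$ari <- ari
  manifest$files <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
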