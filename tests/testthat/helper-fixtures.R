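# Small fixtures built in code, shared across test files.

# a compact study design: 2 tissues x 3 stages x 3 reps, small gene count
tiny_config <- function(seed = 101, n_genes = 150, module_size = 15,
                        replicates_per_stage = 3, ...) {
  sim_config(n_genes = n_genes, tissues = c("SR", "FR"),
             replicates_per_stage = replicates_per_stage,
             modules_per_tissue = 2, module_size = module_size,
             seed = seed, ...)
}

# count_matrix straight from a matrix with minimal metadata
cm_from_matrix <- function(m, tissue = "SR", stage = NULL, batch = 1) {
  ns <- ncol(m)
  stage <- stage %||% rep(c("PB", "EB", "DB"), length.out = ns)
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ns))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  meta <- data.frame(sample_id = colnames(m),
                     tissue = rep(tissue, length.out = ns),
                     stage = stage, batch = rep(batch, length.out = ns),
                     replicate = seq_len(ns))
  count_matrix(m, meta, stage_levels = unique(stage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# undirected edge data.frame from an index matrix
edges_df <- function(nodes, idx) {
  data.frame(gene_a = nodes[idx[, 1]], gene_b = nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

# Erdos-Renyi graph over n nodes (at least one edge guaranteed)
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n))
  pairs <- t(combn(n, 2))
  repeat {
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) break
  }
  graph_from_edges(nodes, edges_df(nodes, pairs[keep, , drop = FALSE]))
}

# brute-force maximal cliques of the non-significance graph: the reference
# grouping a compact letter display must reproduce
brute_force_letter_groups <- function(sig) {
  lev <- rownames(sig)
  k <- length(lev)
  subsets <- list()
  for (sz in k:1) {
    for (comb in utils::combn(k, sz, simplify = FALSE)) {
      pairs_ok <- TRUE
      if (length(comb) > 1) {
        pr <- utils::combn(comb, 2)
        pairs_ok <- !any(sig[cbind(pr[1, ], pr[2, ])])
      }
      if (pairs_ok) subsets <- c(subsets, list(comb))
    }
  }
  # keep maximal only
  keep <- rep(TRUE, length(subsets))
  for (i in seq_along(subsets)) for (j in seq_along(subsets)) {
    if (i != j && keep[i] && all(subsets[[i]] %in% subsets[[j]]) &&
        length(subsets[[i]]) < length(subsets[[j]]))
      keep[i] <- FALSE
  }
  groups <- unique(lapply(subsets[keep], function(s) sort(lev[s])))
  groups[order(vapply(groups, paste, collapse = ",", FUN.VALUE = ""))]
}

# letter display -> list of level groups (one per distinct letter)
letters_to_groups <- function(lt) {
  chars <- unique(unlist(strsplit(unname(lt), "")))
  groups <- lapply(chars, function(ch) sort(names(lt)[grepl(ch, lt, fixed = TRUE)]))
  groups[order(vapply(groups, paste, collapse = ",", FUN.VALUE = ""))]
}

# hand-coded BH step-up oracle (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
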