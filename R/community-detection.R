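#' Resolution-scaled modularity of a graph partition
#'
#' Computes `Q = sum_c [ e_c / m - gamma * (d_c / 2m)^2 ]` on the unweighted
#' edge set, where `m` is the total number of edges, `e_c` the number of
#' intra-community edges, and `d_c` the total degree of community `c`. The
#' resolution `gamma` scales the degree-based null term; larger values favor
#' smaller communities.
#'
#' @param graph A `coexpression_graph` (see [build_graph()]).
#' @param membership Community labels for every node: a vector named by gene
#'   id, or unnamed in `graph$nodes` order.
#' @param resolution Resolution parameter gamma (default 0.75).
#' @return Modularity Q (numeric scalar).
#' @export
modularity_score <- function(graph, membership, resolution = 0.75) {
  stopifnot(inherits(graph, "coexpression_graph"))
  memb <- align_membership(graph, membership)
  m <- nrow(graph$edges)
  if (m < 1) abort_validation("modularity undefined on a graph with no edges")
  ei <- edge_index(graph)
  same <- memb[ei[, 1]] == memb[ei[, 2]]
  labs <- unique(memb)
  deg <- graph_degree(graph)
  d_c <- vapply(labs, function(l) sum(deg[memb == l]), numeric(1))
  sum(same) / m - resolution * sum((d_c / (2 * m))^2)
}

align_membership <- function(graph, membership) {
  nodes <- graph$nodes
  if (!is.null(names(membership))) {
    missing <- setdiff(nodes, names(membership))
    if (length(missing))
      abort_validation("node missing from partition: ",
                       paste(utils::head(missing, 5), collapse = ", "))
    membership <- membership[nodes]
  } else if (length(membership) != length(nodes)) {
    abort_validation("membership length does not match node count")
  }
  as.integer(factor(membership))
}

# one Louvain level: local moving on a weighted graph with self-loops.
# Returns the community of each node and whether any node moved.
louvain_one_level <- function(n, ei, ej, w, self, gamma, init = NULL) {
  all_i <- c(ei, ej) ; all_j <- c(ej, ei) ; all_w <- c(w, w)
  o <- order(all_i)
  all_j <- all_j[o] ; all_w <- all_w[o]
  cnt <- tabulate(all_i, nbins = n)
  ptr <- c(0L, cumsum(cnt))
  deg <- numeric(n)
  for (e in seq_along(ei)) {
    deg[ei[e]] <- deg[ei[e]] + w[e]
    deg[ej[e]] <- deg[ej[e]] + w[e]
  }
  deg <- deg + 2 * self
  m2 <- sum(deg)
  comm <- init %||% seq_len(n)
  tot <- numeric(max(comm, n))
  for (i in seq_len(n)) tot[comm[i]] <- tot[comm[i]] + deg[i]
  moved_any <- FALSE
  order_nodes <- sample.int(n)   # shuffled once per level
  repeat {
    nmoves <- 0L
    for (i in order_nodes) {
      ci <- comm[i]
      rng <- if (cnt[i] > 0) (ptr[i] + 1L):ptr[i + 1L] else integer(0)
      if (length(rng)) {
        ncomm <- comm[all_j[rng]]
        agg <- rowsum(all_w[rng], ncomm)
        cand <- as.integer(rownames(agg))
        wcand <- agg[, 1]
      } else {
        cand <- integer(0) ; wcand <- numeric(0)
      }
      if (!(ci %in% cand)) { cand <- c(cand, ci) ; wcand <- c(wcand, 0) }
      tot[ci] <- tot[ci] - deg[i]
      score <- wcand - gamma * deg[i] * tot[cand] / m2
      best <- max(score)
      winners <- cand[score >= best - 1e-12]
      target <- min(winners)               # ties toward the lowest community id
      comm[i] <- target
      tot[target] <- tot[target] + deg[i]
      if (target != ci) { nmoves <- nmoves + 1L ; moved_any <- TRUE }
    }
    if (nmoves == 0L) break
  }
  list(comm = comm, moved = moved_any)
}

louvain_core <- function(n, ei, ej, w, gamma) {
  membership <- seq_len(n)
  self <- numeric(n)
  nn <- n
  repeat {
    lev <- louvain_one_level(nn, ei, ej, w, self, gamma)
    if (!lev$moved) break
    relab <- match(lev$comm, sort(unique(lev$comm)))
    membership <- relab[lev$comm][membership]
    k <- max(relab)
    a <- relab[ei] ; b <- relab[ej]
    lo <- pmin(a, b) ; hi <- pmax(a, b)
    intra <- lo == hi
    new_self <- numeric(k)
    if (any(intra)) {
      s <- rowsum(w[intra], lo[intra])
      new_self[as.integer(rownames(s))] <- s[, 1]
    }
    olds <- rowsum(self, relab)
    new_self[as.integer(rownames(olds))] <- new_self[as.integer(rownames(olds))] + olds[, 1]
    if (any(!intra)) {
      key <- (lo[!intra] - 1) * k + hi[!intra]
      agg <- rowsum(w[!intra], key)
      kk <- as.numeric(rownames(agg))
      ei <- as.integer((kk - 1) %/% k + 1)
      ej <- as.integer((kk - 1) %% k + 1)
      w <- agg[, 1]
    } else {
      ei <- integer(0) ; ej <- integer(0) ; w <- numeric(0)
    }
    self <- new_self
    if (k == nn) break
    nn <- k
  }
  membership
}

#' Louvain community detection
#'
#' Two-phase Louvain optimization of resolution-scaled modularity: greedy
#' local moving of nodes to the neighboring community with the largest
#' modularity gain (ties broken toward the lowest community id), followed by
#' aggregation of communities into super-nodes, repeated until no move
#' improves modularity, and finished with a local refinement pass over the
#' original nodes. Several restarts with different (seed-derived) node
#' visiting orders are run and the best partition kept, so the result is
#' deterministic given `seed`. The returned partition is never worse than
#' the one-community or all-singleton baselines, which are always candidate
#' states.
#'
#' @param graph A `coexpression_graph`.
#' @param resolution Resolution gamma (default 0.75).
#' @param seed Integer seed controlling the node visiting orders.
#' @param restarts Number of seeded restarts (default 5).
#' @return Object of class `partition`: list with `membership` (named integer
#'   vector, community ids dense from 0), `modularity`, and `resolution`.
#' @export
louvain <- function(graph, resolution = 0.75, seed = 1L, restarts = 5L) {
  stopifnot(inherits(graph, "coexpression_graph"))
  n <- length(graph$nodes)
  if (n == 0) abort_validation("empty graph")
  if (nrow(graph$edges) == 0)
    abort_validation("graph has no edges; modularity optimization undefined")
  idx <- edge_index(graph)
  ei <- idx[, 1] ; ej <- idx[, 2] ; w <- rep(1, nrow(idx))
  candidates <- list(rep(1L, n), seq_len(n))
  for (r in seq_len(max(restarts, 1L))) {
    memb <- with_seed(derive_seed(seed, paste0("restart", r)), {
      m0 <- louvain_core(n, ei, ej, w, resolution)
      # refinement: local moves of original nodes from the final partition
      louvain_one_level(n, ei, ej, w, numeric(n), resolution, init = m0)$comm
    })
    candidates <- c(candidates, list(memb))
  }
  qs <- vapply(candidates, function(mm) {
    names(mm) <- graph$nodes
    modularity_score(graph, mm, resolution)
  }, numeric(1))
  best <- candidates[[which.max(qs)]]
  as_partition(best, graph$nodes, max(qs), resolution)
}

as_partition <- function(memb, nodes, q, resolution) {
  dense <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(dense) <- nodes
  structure(list(membership = dense, modularity = q, resolution = resolution),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities, Q = %.4f (gamma = %g)\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity, x$resolution))
  invisible(x)
}

#' Exhaustive modularity-optimal partition (small-graph oracle)
#'
#' Enumerates every set partition of the nodes (restricted-growth-string
#' order) and returns the modularity-maximal one. With ties, the first
#' partition encountered in enumeration order wins, which is the
#' lexicographically smallest canonical labeling. Limited to 10 nodes
#' (Bell-number growth).
#'
#' @param graph A `coexpression_graph` with at most 10 nodes and at least one
#'   edge.
#' @param resolution Resolution gamma.
#' @return A `partition` with the exact maximal modularity.
#' @export
exhaustive_best_partition <- function(graph, resolution = 0.75) {
  stopifnot(inherits(graph, "coexpression_graph"))
  n <- length(graph$nodes)
  if (n > 10) abort_validation("exhaustive enumeration limited to 10 nodes")
  if (n == 0) abort_validation("empty graph")
  m <- nrow(graph$edges)
  if (m < 1) abort_validation("modularity undefined on a graph with no edges")
  idx <- edge_index(graph)
  deg <- as.numeric(graph_degree(graph))
  ei <- idx[, 1] ; ej <- idx[, 2]
  best_q <- -Inf ; best_a <- NULL
  a <- integer(n)
  a[1] <- 1L
  eval_q <- function(a) {
    intra <- sum(a[ei] == a[ej]) / m
    d_c <- rowsum(deg, a)
    intra - resolution * sum((d_c / (2 * m))^2)
  }
  rec <- function(k, mx) {
    if (k > n) {
      q <- eval_q(a)
      if (q > best_q) { best_q <<- q ; best_a <<- a }
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) {
      a[k] <<- v
      rec(k + 1L, max(mx, v))
    }
  }
  if (n == 1) { best_a <- a ; best_q <- eval_q(a) } else rec(2L, 1L)
  as_partition(best_a, graph$nodes, best_q, resolution)
}

# build a coexpression_graph directly from an edge list (used by tests and
# by clustering of externally supplied graphs)
#' Construct a co-expression graph from an explicit edge list
#'
#' Convenience constructor used when the graph does not come from
#' [build_graph()] (e.g. toy graphs in oracle comparisons).
#'
#' @param nodes Character vector of node ids.
#' @param edges Data.frame with columns `gene_a`, `gene_b` (and optionally
#'   `r`; defaults to 1).
#' @param threshold,min_degree Metadata slots (defaults 0).
#' @return A `coexpression_graph`.
#' @export
graph_from_edges <- function(nodes, edges, threshold = 0, min_degree = 0) {
  edges <- as.data.frame(edges)
  if (is.null(edges$r)) edges$r <- rep(1, nrow(edges))
  bad <- !(edges$gene_a %in% nodes) | !(edges$gene_b %in% nodes)
  if (any(bad)) abort_validation("edge endpoint not among nodes")
  if (any(edges$gene_a == edges$gene_b)) abort_validation("self-loops not allowed")
  structure(list(nodes = nodes, edges = edges[, c("gene_a", "gene_b", "r")],
                 threshold = threshold, min_degree = min_degree,
                 removed = character(0), all_nodes = nodes),
            class = "coexpression_graph")
}
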