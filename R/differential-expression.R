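#' Method-of-moments NB dispersion estimates
#'
#' Per gene, estimates the negative-binomial dispersion alpha in
#' `var = mu + alpha * mu^2` from normalized counts: within each condition
#' group with at least two replicates, `(s^2 - mean) / mean^2`, averaged over
#' groups and floored at `floor`. This deliberately omits empirical-Bayes
#' shrinkage; the LRT downstream is calibration-tested rather than matched to
#' any particular moderation scheme.
#'
#' @param x A [count_matrix()].
#' @param size_factors Optional; estimated when omitted.
#' @param groups Optional grouping factor (default: tissue x stage condition).
#' @param floor Lower bound for the estimate (default 1e-8, the
#'   near-Poisson limit).
#' @return Named numeric vector of per-gene dispersions, with attribute
#'   `all_zero` flagging genes with no counts anywhere.
#' @export
estimate_dispersions <- function(x, size_factors = NULL, groups = NULL,
                                 floor = 1e-8) {
  stopifnot(inherits(x, "count_matrix"))
  sf <- size_factors %||% estimate_size_factors(x)
  grp <- groups %||% condition_factor(x$meta)
  grp <- droplevels(as.factor(grp))
  n_per <- as.vector(table(grp))
  if (!any(n_per >= 2))
    abort_validation("dispersion estimation needs >= 2 replicates in some condition")
  nc <- sweep(x$counts, 2, sf, "/")
  m1 <- t(rowsum(t(nc), grp)) ; m2 <- t(rowsum(t(nc^2), grp))
  means <- sweep(m1, 2, n_per, "/")
  # unbiased within-group variance
  vars <- sweep(m2 - sweep(means^2, 2, n_per, "*"), 2, pmax(n_per - 1, 1), "/")
  a <- (vars - means) / means^2
  a[, n_per < 2] <- NA
  a[!is.finite(a)] <- NA
  alpha <- rowMeans(a, na.rm = TRUE)
  all_zero <- rowSums(x$counts) == 0
  alpha[is.nan(alpha) | all_zero] <- floor
  alpha <- pmax(alpha, floor)
  names(alpha) <- rownames(x$counts)
  attr(alpha, "all_zero") <- all_zero
  alpha
}

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

#' Fit a negative-binomial GLM with log link and size-factor offset
#'
#' Maximizes the NB log-likelihood (fixed dispersion) by iteratively
#' reweighted least squares, with `log(size_factor)` as offset.
#'
#' @param y Integer counts for one gene.
#' @param design Design matrix (full column rank).
#' @param size_factors Positive per-sample factors.
#' @param dispersion NB dispersion alpha (> 0).
#' @param max_iter,tol IRLS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return List with `coefficients`, `loglik`, `fitted` (means), `converged`,
#'   `iterations`, and `df` (number of coefficients).
#' @export
fit_nb_glm <- function(y, design, size_factors, dispersion,
                       max_iter = 100L, tol = 1e-10) {
  design <- as.matrix(design)
  offset <- log(size_factors)
  eta <- log(pmax(y, 0.5)) - offset
  fit0 <- stats::lm.fit(design, eta)
  beta <- fit0$coefficients
  beta[is.na(beta)] <- 0
  ll <- -Inf ; converged <- FALSE ; it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    eta <- pmin(pmax(eta + offset, -30), 30) - offset  # guard against overflow
    mu <- exp(eta + offset)
    w <- mu / (1 + dispersion * mu)
    z <- eta + (y - mu) / mu
    wfit <- stats::lm.wfit(design, z, w)
    beta_new <- wfit$coefficients
    beta_new[is.na(beta_new)] <- 0
    mu_new <- exp(pmin(pmax(drop(design %*% beta_new) + offset, -30), 30))
    ll_new <- nb_loglik(y, mu_new, dispersion)
    if (is.finite(ll_new) && ll_new < ll - 1e-6) {
      # step halving if the likelihood worsened
      for (h in 1:10) {
        beta_new <- (beta + beta_new) / 2
        mu_new <- exp(pmin(pmax(drop(design %*% beta_new) + offset, -30), 30))
        ll_new <- nb_loglik(y, mu_new, dispersion)
        if (ll_new >= ll - 1e-6) break
      }
    }
    done <- is.finite(ll_new) && is.finite(ll) &&
      abs(ll_new - ll) < tol * (abs(ll_new) + 1)
    beta <- beta_new ; ll <- ll_new
    if (done) { converged <- TRUE ; break }
  }
  mu <- exp(pmin(pmax(drop(design %*% beta) + offset, -30), 30))
  list(coefficients = beta, loglik = ll, fitted = mu,
       converged = converged, iterations = it, df = ncol(design))
}

#' Per-tissue likelihood-ratio test of the developmental-stage effect
#'
#' For each gene, fits a full NB GLM with a stage factor (optionally plus an
#' experimental-batch covariate) and a reduced intercept-only model (plus the
#' same batch covariate), and tests `2 * (llf - llr)` against a chi-square
#' distribution with `levels(stage) - 1` degrees of freedom. P-values are
#' BH-adjusted and genes with FDR below `fdr_threshold` are called
#' differentially expressed. All-zero or non-converged genes are reported
#' with `NA` p-values and never called.
#'
#' @param x A [count_matrix()]; subset to `tissue` if that argument is given.
#' @param tissue Optional tissue label to subset to.
#' @param include_batch Include the batch factor in both models.
#' @param fdr_threshold DEG call threshold on the BH-adjusted p-value
#'   (default 0.001).
#' @param size_factors,dispersions Optional; estimated on the analyzed subset
#'   when omitted.
#' @param dispersion How to estimate dispersions when `dispersions` is not
#'   supplied: `"shrunk"` (empirical-Bayes moderated, [shrink_dispersions()];
#'   the default, which keeps the chi-square LRT calibrated at small
#'   replication) or `"moment"` (raw method-of-moments,
#'   [estimate_dispersions()]).
#' @return A data.frame of class `deg_table` with columns `gene_id`, `stat`,
#'   `df`, `pvalue`, `fdr`, `is_deg` and one mean-normalized-count column per
#'   stage; attributes `tissue` and `fdr_threshold`.
#' @export
lrt_stage <- function(x, tissue = NULL, include_batch = FALSE,
                      fdr_threshold = 0.001, size_factors = NULL,
                      dispersions = NULL,
                      dispersion = c("shrunk", "moment")) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is.null(tissue)) x <- subset_tissue(x, tissue)
  stage <- droplevels(x$meta$stage)
  if (nlevels(stage) < 2)
    abort_validation("stage needs >= 2 levels within the analyzed tissue")
  if (any(table(stage) == 0))
    abort_validation("a stage level has zero samples")
  dispersion <- match.arg(dispersion)
  sf <- size_factors %||% estimate_size_factors(x)
  batch <- droplevels(x$meta$batch)
  use_batch <- include_batch && nlevels(batch) > 1
  full <- if (use_batch) stats::model.matrix(~ stage + batch)
          else stats::model.matrix(~stage)
  reduced <- if (use_batch) stats::model.matrix(~batch)
             else stats::model.matrix(~1, data = data.frame(row.names = seq_along(stage)))
  disp <- dispersions %||% switch(dispersion,
    shrunk = shrink_dispersions(x, design = full, size_factors = sf),
    moment = estimate_dispersions(x, size_factors = sf, groups = stage))
  df <- nlevels(stage) - 1L

  ng <- nrow(x$counts)
  stat <- rep(NA_real_, ng)
  nc <- sweep(x$counts, 2, sf, "/")
  stage_means <- sweep(t(rowsum(t(nc), stage)), 2,
                       as.vector(table(stage)), "/")
  for (g in seq_len(ng)) {
    y <- x$counts[g, ]
    if (all(y == 0)) next
    ff <- fit_nb_glm(y, full, sf, disp[g])
    fr <- fit_nb_glm(y, reduced, sf, disp[g])
    if (!ff$converged || !fr$converged) next
    stat[g] <- max(2 * (ff$loglik - fr$loglik), 0)
  }
  pvalue <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  fdr <- adjust_fdr(pvalue)
  out <- data.frame(gene_id = rownames(x$counts), stat = stat, df = df,
                    pvalue = pvalue, fdr = fdr,
                    is_deg = !is.na(fdr) & fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  colnames(stage_means) <- paste0("mean_", colnames(stage_means))
  out <- cbind(out, as.data.frame(stage_means))
  rownames(out) <- NULL
  attr(out, "tissue") <- if (is.null(tissue)) NA_character_ else tissue
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment. `NA` p-values are carried through
#' unadjusted and do not count toward the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values in the original order.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    abort_validation("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
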