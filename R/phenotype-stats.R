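#' Fit a Gamma GLM with log link to phenotype values
#'
#' Models strictly positive measurements (e.g. sugar or starch content in
#' mg per g dry weight) as Gamma-distributed with a log-link mean structure
#' over the developmental-stage factor. Dispersion is estimated by Pearson
#' chi-square over residual degrees of freedom.
#'
#' @param values Strictly positive numeric measurements.
#' @param stage Factor of stage labels (same length).
#' @return A `glm` fit (family `Gamma(link = "log")`).
#' @export
fit_gamma_glm <- function(values, stage) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    abort_validation("non-positive phenotype values at rows ",
                     paste(bad, collapse = ", "),
                     " (Gamma support requires values > 0)")
  stage <- droplevels(as.factor(stage))
  dat <- data.frame(value = values, stage = stage)
  fml <- if (nlevels(stage) >= 2) value ~ stage else value ~ 1
  stats::glm(fml, family = stats::Gamma(link = "log"), data = dat)
}

#' Type-II ANOVA for a fitted (generalized) linear model
#'
#' Tests each term by dropping it from the model that contains all other
#' terms. For GLMs the statistic is the scaled-deviance likelihood-ratio
#' chi-square (deviance difference divided by the full model's Pearson
#' dispersion); for Gaussian `lm` fits the classical F statistic is used.
#' With a single factor this reduces to the whole-factor test against the
#' intercept-only model.
#'
#' @param fit A `glm` or `lm` fit.
#' @return Data.frame with one row per term: `term`, `statistic`, `df`,
#'   `p_value`, plus `df_resid` for F tests.
#' @export
anova_typeII <- function(fit) {
  is_glm <- inherits(fit, "glm")
  trms <- attr(stats::terms(fit), "term.labels")
  if (!length(trms)) abort_validation("model has no terms to test")
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  if (qr(X)$rank < ncol(X)) abort_validation("rank-deficient design")
  y <- stats::model.response(stats::model.frame(fit))
  out <- vector("list", length(trms))
  if (is_glm) {
    phi <- sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
    dev_full <- stats::deviance(fit)
    for (k in seq_along(trms)) {
      Xr <- X[, asgn != k, drop = FALSE]
      red <- stats::glm.fit(Xr, y, family = stats::family(fit))
      lr <- (red$deviance - dev_full) / phi
      df <- sum(asgn == k)
      out[[k]] <- data.frame(term = trms[k], statistic = max(lr, 0), df = df,
                             p_value = stats::pchisq(max(lr, 0), df,
                                                     lower.tail = FALSE))
    }
  } else {
    rss_full <- sum(stats::residuals(fit)^2)
    df_resid <- stats::df.residual(fit)
    mse <- rss_full / df_resid
    for (k in seq_along(trms)) {
      Xr <- X[, asgn != k, drop = FALSE]
      red <- stats::lm.fit(Xr, y)
      df <- sum(asgn == k)
      f <- (sum(red$residuals^2) - rss_full) / df / mse
      out[[k]] <- data.frame(term = trms[k], statistic = max(f, 0), df = df,
                             p_value = stats::pf(max(f, 0), df, df_resid,
                                                 lower.tail = FALSE),
                             df_resid = df_resid)
    }
  }
  do.call(rbind, out)
}

#' BH adjustment across a family of models
#'
#' Applies Benjamini-Hochberg adjustment to the per-model ANOVA p-values of
#' a model family (e.g. one Gamma GLM per tissue x analyte) and flags the
#' models significant at `alpha`.
#'
#' @param p Named numeric vector of per-model p-values.
#' @param alpha Significance threshold on the adjusted values (default 0.05).
#' @return List with `fdr` (adjusted values, names kept) and `significant`
#'   (logical).
#' @export
fdr_across_models <- function(p, alpha = 0.05) {
  fdr <- adjust_fdr(p)
  names(fdr) <- names(p)
  list(fdr = fdr, significant = !is.na(fdr) & fdr < alpha)
}

# All pairwise Tukey(-Kramer) comparisons of the levels of the model's
# single factor, on the link scale, with p-values from the studentized range
# distribution with residual df.
tukey_pairwise <- function(fit) {
  trms <- attr(stats::terms(fit), "term.labels")
  if (length(trms) != 1)
    abort_validation("Tukey letters require a single-factor model")
  mf <- stats::model.frame(fit)
  fac <- mf[[trms]]
  lev <- levels(droplevels(fac))
  k <- length(lev)
  if (k < 2) abort_validation("need >= 2 factor levels")
  # level means on the link scale via the contrast of coefficients
  X <- stats::model.matrix(stats::as.formula(paste("~", trms)),
                           data = stats::setNames(data.frame(factor(lev, levels = lev)), trms))
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  est <- drop(X %*% beta)
  names(est) <- lev
  df_resid <- stats::df.residual(fit)
  pairs <- utils::combn(k, 2)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c] ; j <- pairs[2, c]
    ct <- X[i, ] - X[j, ]
    se <- sqrt(drop(t(ct) %*% V %*% ct))
    q <- abs(est[i] - est[j]) / se * sqrt(2)
    pmat[i, j] <- pmat[j, i] <- stats::ptukey(q, nmeans = k, df = df_resid,
                                              lower.tail = FALSE)
  }
  list(estimates = est, p = pmat, df_resid = df_resid)
}

# insert-and-absorb compact letter display from a logical significance
# matrix; returns the maximal sets of mutually non-separated levels.
cld_insert_absorb <- function(levels, sig) {
  cols <- list(levels)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- levels[pairs[r, 1]] ; j <- levels[pairs[r, 2]]
    new_cols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    new_cols <- unique(new_cols)
    # absorb: drop columns contained in another column
    keep <- rep(TRUE, length(new_cols))
    for (aa in seq_along(new_cols)) for (bb in seq_along(new_cols)) {
      if (aa != bb && keep[aa] && keep[bb] &&
          all(new_cols[[aa]] %in% new_cols[[bb]]) &&
          !(all(new_cols[[bb]] %in% new_cols[[aa]]) && aa < bb))
        keep[aa] <- FALSE
    }
    cols <- new_cols[keep]
  }
  cols
}

#' Tukey HSD compact letter display
#'
#' Performs all pairwise comparisons of the fitted model's factor levels on
#' the link scale (Tukey-Kramer studentized-range p-values with residual
#' degrees of freedom) and encodes the result as a compact letter display:
#' two levels share a letter if and only if their adjusted comparison is
#' non-significant at `alpha`. Letters are built by insert-and-absorb, whose
#' letter groups are exactly the maximal cliques of the non-significance
#' graph.
#'
#' @param fit A single-factor `glm` or `lm` fit.
#' @param alpha Significance threshold (comparisons with `p <= alpha`
#'   separate levels; default 0.05).
#' @return Named character vector: factor level -> its letters. Attributes
#'   `p_matrix` (pairwise adjusted p-values) and `estimates` (link-scale
#'   level means).
#' @export
tukey_letters <- function(fit, alpha = 0.05) {
  tk <- tukey_pairwise(fit)
  lev <- names(tk$estimates)
  sig <- !is.na(tk$p) & tk$p <= alpha
  groups <- cld_insert_absorb(lev, sig)
  # order letter groups by the smallest level mean they contain
  ord <- order(vapply(groups, function(g) min(tk$estimates[g]), numeric(1)))
  groups <- groups[ord]
  letters_out <- setNames(rep("", length(lev)), lev)
  for (gi in seq_along(groups))
    for (l in groups[[gi]])
      letters_out[l] <- paste0(letters_out[l], letters[gi])
  structure(letters_out, p_matrix = tk$p, estimates = tk$estimates)
}

#' Per-sugar compartment statistics for NAF fraction tables
#'
#' For each sugar, fits an ordinary linear model of the compartment fraction
#' on the compartment factor, collects the per-sugar ANOVA p-value, adjusts
#' across sugars by Benjamini-Hochberg, and computes Tukey HSD letter groups
#' for the significant models (non-significant models share a single
#' letter).
#'
#' @param naf A data.frame with columns `replicate`, `sugar`, `compartment`,
#'   `fraction` (per replicate and sugar, fractions must sum to 1).
#' @param alpha Threshold on the FDR-adjusted ANOVA p-value (default 0.05).
#' @return List with `models` (data.frame sugar/p_value/fdr/significant) and
#'   `letters` (data.frame sugar/compartment/mean_fraction/letters).
#' @export
naf_test <- function(naf, alpha = 0.05) {
  req <- c("replicate", "sugar", "compartment", "fraction")
  if (!all(req %in% names(naf)))
    abort_validation("naf table needs columns ", paste(req, collapse = ", "))
  sums <- tapply(naf$fraction, list(naf$replicate, naf$sugar), sum)
  if (any(abs(sums - 1) > 1e-9, na.rm = TRUE))
    abort_validation("fractions must sum to 1 per (replicate, sugar)")
  sugars <- unique(as.character(naf$sugar))
  pvals <- setNames(numeric(length(sugars)), sugars)
  fits <- list()
  for (s in sugars) {
    d <- naf[naf$sugar == s, ]
    if (any(table(d$compartment) < 2))
      abort_validation("need >= 2 replicates per compartment for sugar ", s)
    d$compartment <- droplevels(as.factor(d$compartment))
    fits[[s]] <- stats::lm(fraction ~ compartment, data = d)
    pvals[s] <- anova_typeII(fits[[s]])$p_value
  }
  adj <- fdr_across_models(pvals, alpha = alpha)
  rows <- list()
  for (s in sugars) {
    comp <- levels(stats::model.frame(fits[[s]])$compartment)
    if (adj$significant[s]) {
      lt <- tukey_letters(fits[[s]], alpha = 0.05)
    } else {
      lt <- setNames(rep("a", length(comp)), comp)
    }
    means <- tapply(naf$fraction[naf$sugar == s],
                    as.character(naf$compartment[naf$sugar == s]), mean)
    rows[[s]] <- data.frame(sugar = s, compartment = comp,
                            mean_fraction = as.numeric(means[comp]),
                            letters = as.character(lt[comp]),
                            stringsAsFactors = FALSE)
  }
  list(models = data.frame(sugar = sugars, p_value = pvals, fdr = adj$fdr,
                           significant = adj$significant, row.names = NULL),
       letters = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Phenotype statistics across tissues and analytes
#'
#' The full measurement-side workflow: one Gamma GLM (log link) of value on
#' stage per tissue x analyte, type-II ANOVA p-value per model, BH adjustment
#' across all models, and Tukey HSD compact letter displays for the models
#' passing the FDR gate (others share one letter).
#'
#' @param phenotypes Data.frame with columns `tissue`, `stage`, `replicate`,
#'   `analyte`, `value` (values strictly positive).
#' @param alpha Threshold on the FDR-adjusted ANOVA p-value (default 0.05).
#' @param tukey_alpha Pairwise Tukey threshold (default 0.05).
#' @return List with `models` (tissue/analyte/p_value/fdr/significant) and
#'   `letters` (tissue/analyte/stage/mean_value/letters).
#' @export
phenotype_stats <- function(phenotypes, alpha = 0.05, tukey_alpha = 0.05) {
  req <- c("tissue", "stage", "replicate", "analyte", "value")
  if (!all(req %in% names(phenotypes)))
    abort_validation("phenotype table needs columns ", paste(req, collapse = ", "))
  cells <- unique(phenotypes[, c("tissue", "analyte")])
  fits <- list() ; pvals <- numeric(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    d <- phenotypes[phenotypes$tissue == cells$tissue[r] &
                      phenotypes$analyte == cells$analyte[r], ]
    fit <- fit_gamma_glm(d$value, d$stage)
    fits[[r]] <- fit
    pvals[r] <- anova_typeII(fit)$p_value
  }
  names(pvals) <- paste(cells$tissue, cells$analyte, sep = ":")
  adj <- fdr_across_models(pvals, alpha = alpha)
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    stages <- levels(stats::model.frame(fits[[r]])$stage)
    if (adj$significant[r]) {
      lt <- tukey_letters(fits[[r]], alpha = tukey_alpha)
    } else {
      lt <- setNames(rep("a", length(stages)), stages)
    }
    d <- phenotypes[phenotypes$tissue == cells$tissue[r] &
                      phenotypes$analyte == cells$analyte[r], ]
    means <- tapply(d$value, as.character(d$stage), mean)
    rows[[r]] <- data.frame(tissue = cells$tissue[r],
                            analyte = cells$analyte[r], stage = stages,
                            mean_value = as.numeric(means[stages]),
                            letters = as.character(lt[stages]),
                            stringsAsFactors = FALSE)
  }
  list(models = data.frame(tissue = cells$tissue, analyte = cells$analyte,
                           p_value = pvals, fdr = adj$fdr,
                           significant = adj$significant, row.names = NULL),
       letters = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
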