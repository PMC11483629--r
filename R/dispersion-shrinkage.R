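# Empirical-Bayes dispersion moderation for the stage LRT.
#
# Per-gene moment estimates of the NB dispersion are far too noisy at
# typical replication (3-4 plants per stage) to plug into a chi-square LRT:
# genes whose within-stage variance happens to come out small are tested
# with an underestimated dispersion and flood the lower tail of the null
# p-value distribution. Sharing information across genes fixes this without
# sacrificing power: genewise Cox-Reid-adjusted profile-likelihood
# estimates, a parametric mean-dispersion trend, and a maximum-a-posteriori
# estimate under a log-normal prior centered on the trend.

# Cox-Reid adjusted profile log-likelihood of log(alpha) at fixed means.
cr_profile_loglik <- function(la, y, mu, X) {
  a <- exp(la)
  w <- mu / (1 + a * mu)
  sum(stats::dnbinom(y, size = 1 / a, mu = mu, log = TRUE)) -
    0.5 * determinant(crossprod(X * w, X), logarithm = TRUE)$modulus
}

# genewise CR-MLE by alternating mean fits and profile optimization
cr_mle_dispersion <- function(y, X, size_factors, init = 0.1, rounds = 2L,
                              range = c(1e-8, 30)) {
  a <- init
  for (r in seq_len(rounds)) {
    fit <- fit_nb_glm(y, X, size_factors, a)
    o <- stats::optimize(cr_profile_loglik, log(range), y = y,
                         mu = fit$fitted, X = X, maximum = TRUE)
    a <- exp(o$maximum)
  }
  a
}

# parametric mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted by an
# iterated Gamma GLM with outlier trimming; falls back to a flat trimmed
# mean when the parametric fit does not converge.
dispersion_trend <- function(alpha, mu, lower = 1e-7, upper = 25) {
  ok <- mu > 0 & alpha > lower & alpha < upper
  if (sum(ok) < 10) {
    loc <- if (any(ok)) mean(alpha[ok], trim = 0.05) else 0.1
    return(list(fn = function(m) rep(loc, length(m)), parametric = FALSE))
  }
  d <- data.frame(a = alpha[ok], x = 1 / mu[ok])
  fit <- tryCatch({
    f <- stats::glm(a ~ x, data = d, family = stats::Gamma(link = "identity"),
                    start = c(stats::median(d$a), 1))
    for (i in 1:5) {
      fv <- stats::predict(f, newdata = d)
      keep <- d$a > 1e-4 * fv & d$a < 15 * fv
      f <- stats::glm(a ~ x, data = d[keep, , drop = FALSE],
                      family = stats::Gamma(link = "identity"),
                      start = stats::coef(f))
    }
    f
  }, error = function(e) NULL)
  if (is.null(fit) || any(stats::coef(fit) < 0)) {
    loc <- mean(d$a, trim = 0.05)
    return(list(fn = function(m) rep(loc, length(m)), parametric = FALSE))
  }
  co <- stats::coef(fit)
  list(fn = function(m) pmax(co[1] + co[2] / pmax(m, 1e-8), 1e-8),
       parametric = TRUE)
}

#' Empirical-Bayes shrunken NB dispersions
#'
#' Moderated per-gene dispersion estimates for the stage LRT: (1) genewise
#' Cox-Reid-adjusted profile-likelihood estimates under the supplied design;
#' (2) a parametric mean-dispersion trend `a0 + a1/mu` fitted across genes;
#' (3) per gene, the maximum-a-posteriori dispersion under a log-normal
#' prior centered on the trend, whose variance is the spread of the
#' genewise estimates around the trend in excess of their expected sampling
#' variance (`trigamma((m - p)/2)`, floored at 0.25). All-zero genes get the
#' floor dispersion.
#'
#' @param x A [count_matrix()].
#' @param design Design matrix of the full model (default: stage factor of
#'   the metadata).
#' @param size_factors Optional; estimated when omitted.
#' @param floor Lower bound on the returned dispersions.
#' @return Named numeric vector of dispersions with attributes `genewise`,
#'   `trend`, `prior_var`, and `all_zero`.
#' @export
shrink_dispersions <- function(x, design = NULL, size_factors = NULL,
                               floor = 1e-8) {
  stopifnot(inherits(x, "count_matrix"))
  sf <- size_factors %||% estimate_size_factors(x)
  X <- design %||% stats::model.matrix(~stage, data = droplevels(x$meta))
  m <- ncol(x$counts) ; p <- qr(X)$rank
  if (m - p < 1)
    abort_validation("no residual degrees of freedom for dispersion estimation")
  ng <- nrow(x$counts)
  mu_bar <- rowMeans(sweep(x$counts, 2, sf, "/"))
  genewise <- rep(floor, ng)
  nonzero <- which(rowSums(x$counts) > 0)
  for (g in nonzero)
    genewise[g] <- cr_mle_dispersion(x$counts[g, ], X, sf)
  tr <- dispersion_trend(genewise, mu_bar)
  trend <- tr$fn(mu_bar)
  ok <- mu_bar > 0 & genewise > 1e-7 & genewise < 25
  s_samp <- trigamma((m - p) / 2)
  s_prior <- if (sum(ok) >= 10)
    max(stats::mad(log(genewise[ok]) - log(trend[ok]))^2 - s_samp, 0.25)
  else 0.25
  out <- rep(floor, ng)
  for (g in nonzero) {
    y <- x$counts[g, ]
    a <- genewise[g]
    # alternate mean refits with posterior-mode updates of the dispersion
    for (it in 1:2) {
      fit <- fit_nb_glm(y, X, sf, a)
      post <- function(la)
        cr_profile_loglik(la, y, fit$fitted, X) -
          (la - log(trend[g]))^2 / (2 * s_prior)
      a <- exp(stats::optimize(post, log(c(1e-8, 30)), maximum = TRUE)$maximum)
    }
    out[g] <- a
  }
  out <- pmax(out, floor)
  names(out) <- rownames(x$counts)
  attr(out, "genewise") <- genewise
  attr(out, "trend") <- trend
  attr(out, "prior_var") <- s_prior
  attr(out, "all_zero") <- rowSums(x$counts) == 0
  out
}
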