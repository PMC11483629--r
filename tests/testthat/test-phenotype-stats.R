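test_that("Gamma GLM one-group intercept equals the log sample mean", {
  set.seed(1)
  v <- rgamma(30, 10, rate = 10 / 20)
  fit <- fit_gamma_glm(v, rep("PB", 30))
  expect_equal(unname(coef(fit)[1]), log(mean(v)), tolerance = 1e-8)
  expect_error(fit_gamma_glm(c(1, 0, 2), c("a", "b", "c")), "rows 2")
})

test_that("Gamma GLM recovers a planted two-fold stage effect", {
  set.seed(2)
  stage <- rep(c("PB", "DB"), each = 100)
  v <- rgamma(200, 10, rate = 10 / ifelse(stage == "DB", 20, 10))
  fit <- fit_gamma_glm(v, factor(stage, c("PB", "DB")))
  expect_lt(abs(coef(fit)[2] / log(2) - 1), 0.1)
})

test_that("Gamma GLM is scale equivariant: only the intercept shifts", {
  set.seed(3)
  stage <- factor(rep(c("PB", "EB", "DB"), each = 8), c("PB", "EB", "DB"))
  v <- rgamma(24, 10, rate = 10 / 15)
  f1 <- fit_gamma_glm(v, stage)
  f2 <- fit_gamma_glm(v * 37, stage)
  expect_equal(unname(coef(f2)[1] - coef(f1)[1]), log(37), tolerance = 1e-8)
  expect_equal(unname(coef(f2)[-1]), unname(coef(f1)[-1]), tolerance = 1e-8)
  expect_equal(anova_typeII(f2)$p_value, anova_typeII(f1)$p_value,
               tolerance = 1e-8)
})

test_that("type-II ANOVA reduces to the whole-factor LRT for one factor", {
  set.seed(4)
  stage <- factor(rep(c("PB", "EB", "DB"), each = 10), c("PB", "EB", "DB"))
  v <- rgamma(30, 10, rate = 10 / c(PB = 10, EB = 14, DB = 25)[stage])
  fit <- fit_gamma_glm(v, stage)
  tab <- anova_typeII(fit)
  expect_equal(tab$df, 2)
  # identity: scaled deviance difference of full vs intercept-only
  red <- glm(v ~ 1, family = Gamma(link = "log"))
  phi <- sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
  expect_equal(tab$statistic, (deviance(red) - deviance(fit)) / phi,
               tolerance = 1e-8)
  # identical groups (same value multiset per stage): statistic ~ 0, p ~ 1
  fit0 <- fit_gamma_glm(rep(rep(c(5, 6, 7), length.out = 10), 3), stage)
  tab0 <- anova_typeII(fit0)
  expect_lt(tab0$statistic, 1e-10)
  expect_gt(tab0$p_value, 1 - 1e-6)
})

test_that("type-II ANOVA agrees with the car reference on multi-term models", {
  skip_if_not_installed("car")
  set.seed(5)
  d <- data.frame(x = factor(rep(c("a", "b", "c"), 12)),
                  z = factor(rep(c("u", "v"), 18)))
  d$y <- rgamma(36, 10, rate = 10 / (10 * ifelse(d$x == "c", 2, 1)))
  fit <- glm(y ~ x + z, family = Gamma(link = "log"), data = d)
  mine <- anova_typeII(fit)
  ref <- car::Anova(fit, type = "II", test.statistic = "LR")
  # car scales the LR chi-square by the estimated dispersion as well
  expect_equal(mine$statistic, ref[["LR Chisq"]][1:2], tolerance = 1e-6)
  expect_equal(mine$p_value, ref[["Pr(>Chisq)"]][1:2], tolerance = 1e-6)
})

test_that("ANOVA type-I error is controlled on null Gamma data", {
  set.seed(6)
  p <- replicate(400, {
    stage <- factor(rep(c("PB", "EB", "DB"), each = 20))
    anova_typeII(fit_gamma_glm(rgamma(60, 10, rate = 10 / 20), stage))$p_value
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("Tukey letters separate and join groups as designed", {
  set.seed(7)
  stage <- factor(rep(c("PB", "EB", "DB"), each = 10), c("PB", "EB", "DB"))
  # far-separated means: all letters distinct
  v <- rgamma(30, 200, rate = 200 / c(PB = 5, EB = 50, DB = 500)[stage])
  lt <- tukey_letters(fit_gamma_glm(v, stage))
  expect_setequal(unname(lt), c("a", "b", "c"))
  # two identical groups share a letter
  v2 <- rgamma(30, 200, rate = 200 / c(PB = 10, EB = 10, DB = 500)[stage])
  lt2 <- tukey_letters(fit_gamma_glm(v2, stage))
  expect_equal(lt2[["PB"]], lt2[["EB"]])
  expect_false(lt2[["DB"]] == lt2[["PB"]])
})

test_that("letters reproduce the brute-force maximal-clique grouping", {
  set.seed(8)
  for (i in 1:40) {
    k <- sample(3:5, 1)
    n <- sample(4:8, 1)
    lev <- paste0("L", seq_len(k))
    stage <- factor(rep(lev, each = n), lev)
    mu <- exp(rnorm(k, log(20), sample(c(0.05, 0.3, 1), 1)))
    v <- rgamma(k * n, 10, rate = 10 / mu[as.integer(stage)])
    lt <- tukey_letters(fit_gamma_glm(v, stage))
    sig <- !is.na(attr(lt, "p_matrix")) & attr(lt, "p_matrix") <= 0.05
    expect_identical(letters_to_groups(lt), brute_force_letter_groups(sig))
  }
})

test_that("NAF testing validates the simplex and letters forced separations", {
  cfg <- tiny_config(naf_concentration = 5000)
  nf <- generate_naf(cfg)$naf
  res <- naf_test(nf)
  expect_true(all(res$models$significant))
  lt <- res$letters
  for (s in unique(lt$sugar)) {
    sub <- lt[lt$sugar == s, ]
    expect_false(sub$letters[sub$compartment == "vacuole"] ==
                   sub$letters[sub$compartment == "cytosol"])
  }
  # equal compartments: single shared letter
  flat <- nf
  set.seed(9)
  flat$fraction <- 1 / 3 + rep(rnorm(nrow(flat) / 3, sd = 1e-3), 3) *
    rep(c(1, 1, -2) / 2, each = nrow(flat) / 3)
  flat$fraction <- ave(flat$fraction,
                       interaction(flat$replicate, flat$sugar),
                       FUN = function(x) x / sum(x))
  res_flat <- naf_test(flat)
  expect_true(all(res_flat$letters$letters == "a"))
  # broken simplex rejected
  bad <- nf ; bad$fraction[1] <- bad$fraction[1] + 0.1
  expect_error(naf_test(bad), "sum to 1")
})

test_that("fdr_across_models applies BH across the model family", {
  p <- c(m1 = 0.01, m2 = 0.02, m3 = 0.03, m4 = 0.04)
  out <- fdr_across_models(p)
  expect_equal(unname(out$fdr), rep(0.04, 4))
  expect_true(all(out$significant))
  expect_equal(unname(fdr_across_models(c(a = 0.2))$fdr), 0.2)
  none <- fdr_across_models(c(a = 1, b = 1, c = 1))
  expect_false(any(none$significant))
})

test_that("phenotype_stats flags the planted storage-root stage effects", {
  cfg <- sim_config(replicates_per_stage = 6, seed = 55)
  ph <- generate_phenotypes(cfg)$phenotypes
  st <- phenotype_stats(ph)
  sr <- st$models[st$models$tissue == "SR", ]
  expect_true(all(sr$significant))   # 4-fold planted ramps
  sol_glu <- st$models$significant[st$models$tissue == "SoL" &
                                     st$models$analyte == "glucose"]
  expect_false(sol_glu)              # flat truth
  expect_true(all(c("tissue", "analyte", "stage", "mean_value", "letters")
                  %in% names(st$letters)))
})
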