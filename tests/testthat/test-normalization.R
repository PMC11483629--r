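test_that("size factors recover exact scalings and the identity case", {
  m <- matrix(rep(rpois(10, 50) + 1, 6), 10, 6)   # identical samples
  cm <- cm_from_matrix(m)
  expect_equal(unname(estimate_size_factors(cm)), rep(1, 6))
  m2 <- cbind(m[, 1], 2 * m[, 1])
  cm2 <- cm_from_matrix(m2, stage = c("PB", "EB"))
  sf <- estimate_size_factors(cm2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(geomean <- exp(mean(log(sf))), 1)
})

test_that("size factors error when no gene is expressed everywhere", {
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_error(estimate_size_factors(cm_from_matrix(m, stage = c("PB", "EB"))),
               "positive counts in every sample")
})

test_that("size factors recover generated truth within 5%", {
  cfg <- sim_config(n_genes = 2000, tissues = "SR", modules_per_tissue = 0,
                    module_size = 0, seed = 7)
  sim <- generate_counts(cfg)
  sf <- estimate_size_factors(sim$counts)
  expect_lt(max(abs(sf / sim$truth$size_factors - 1)), 0.05)
})

test_that("size-factor estimation agrees with the median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  sim <- generate_counts(tiny_config())
  sf <- estimate_size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts$counts)
  ref <- ref / exp(mean(log(ref)))
  # medians of even-length vectors interpolate on different scales (ratio
  # here, log-ratio in the reference), so agreement is near- but not exact
  expect_equal(unname(sf), unname(ref), tolerance = 1e-3)
})

test_that("scaling one sample's counts scales only its size factor", {
  sim <- generate_counts(tiny_config())
  base <- sim$counts$counts
  base <- base + 1  # every gene positive everywhere -> exact equivariance
  cm <- cm_from_matrix(base, stage = as.character(sim$counts$meta$stage))
  sf0 <- estimate_size_factors(cm)
  scaled <- base
  scaled[, 3] <- scaled[, 3] * 4
  sf1 <- estimate_size_factors(cm_from_matrix(scaled, stage = as.character(sim$counts$meta$stage)))
  c_adj <- 4^(1 / ncol(base))  # geometric-mean anchoring spreads the factor
  expect_equal(unname(sf1[3] / sf0[3]), 4 / c_adj, tolerance = 1e-12)
  expect_equal(unname(sf1[-3] / sf0[-3]), rep(1 / c_adj, ncol(base) - 1),
               tolerance = 1e-12)
})

test_that("transform has the stated closed forms and monotonicity", {
  m <- matrix(c(0, 7, 3, 15), 2, 2)
  cm <- cm_from_matrix(m, stage = c("PB", "EB"))
  norm <- transform_counts(cm, size_factors = c(1, 1))
  expect_equal(norm$values[1, 1], 0)
  expect_equal(norm$values[2, 1], 3)  # log2(7 + 1)
  # doubling a size factor lowers values, preserves within-sample order
  norm2 <- transform_counts(cm, size_factors = c(2, 0.5))
  expect_true(all(norm2$values[, 1] <= norm$values[, 1]))
  expect_equal(order(norm2$values[, 1]), order(norm$values[, 1]))
})

test_that("expression filter keeps genes reaching the mean in one condition", {
  m <- rbind(all_zero = rep(0, 6),
             one_cond = c(50, 50, 0, 0, 0, 0),
             low = rep(10, 6))
  colnames(m) <- paste0("s", 1:6)
  cm <- cm_from_matrix(m, stage = rep(c("PB", "EB", "DB"), each = 2))
  norm <- transform_counts(cm, size_factors = rep(1, 6))
  kept <- expression_filter(norm, threshold = 50)
  expect_setequal(kept, "one_cond")
  expect_setequal(expression_filter(norm, threshold = 0), rownames(m))
  # sample-wise grouping: no single sample of "low" reaches 50
  expect_setequal(expression_filter(norm, threshold = 50, by = "sample"),
                  "one_cond")
})

test_that("batch removal is exact for an additive offset and preserves means", {
  sim <- generate_counts(tiny_config(batch_levels = 1))
  norm <- transform_counts(sim$counts)
  # single batch: identity
  expect_identical(remove_batch(norm), norm)
  # deterministic base (condition means only) plus a pure +delta on batch 2:
  # the offset is exactly identifiable and exactly removed
  batch <- rep(c(1, 2), length.out = nrow(norm$meta))
  cond <- interaction(norm$meta$tissue, norm$meta$stage, drop = TRUE)
  base <- outer(seq_len(20), as.integer(cond))  # gene x condition structure
  dimnames(base) <- list(paste0("g", 1:20), norm$meta$sample_id)
  delta <- 0.7
  meta2 <- norm$meta
  meta2$batch <- factor(batch)
  shifted <- structure(list(values = base + rep(delta * (batch == 2),
                                                each = 20),
                            size_factors = norm$size_factors,
                            meta = meta2),
                       class = "normalized_matrix")
  adj <- remove_batch(shifted)
  for (cc in levels(cond)) {
    gap <- rowMeans(adj$values[, cond == cc & batch == 2, drop = FALSE]) -
      rowMeans(adj$values[, cond == cc & batch == 1, drop = FALSE])
    expect_lt(max(abs(gap)), 1e-8)
  }
  expect_equal(rowMeans(adj$values), rowMeans(shifted$values), tolerance = 1e-12)
})

test_that("refitting batch on adjusted generated data gives a zero coefficient", {
  sim <- generate_counts(tiny_config(batch_levels = 2, replicates_per_stage = 4))
  norm <- transform_counts(sim$counts)
  adj <- remove_batch(norm)
  cond <- interaction(adj$meta$tissue, adj$meta$stage, drop = TRUE)
  X <- model.matrix(~ cond + adj$meta$batch)
  coefs <- t(qr.coef(qr(X), t(adj$values)))
  expect_lt(max(abs(coefs[, ncol(X)])), 1e-8)
})

test_that("confounded batch is rejected", {
  sim <- generate_counts(tiny_config())
  norm <- transform_counts(sim$counts)
  norm$meta$batch <- factor(as.integer(norm$meta$stage == "DB") + 1)
  expect_error(remove_batch(norm), "confounded")
})
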