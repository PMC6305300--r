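make_masked <- function(n_missing_per_protein, n_samples) {
  np <- length(n_missing_per_protein)
  x <- matrix(rnorm(np * n_samples, 20, 2), np, n_samples)
  mask <- matrix(FALSE, np, n_samples)
  for (i in seq_len(np)) {
    if (n_missing_per_protein[i] > 0)
      mask[i, seq_len(n_missing_per_protein[i])] <- TRUE
  }
  x[mask] <- NA
  abundance_matrix(x)
}

test_that("the >50% observation filter applies the 16-of-34 rule", {
  set.seed(1)
  ab <- make_masked(c(0, 16, 17, 18), 34)
  kept <- filter_min_observed(ab)
  expect_identical(kept$protein_ids, c("P1", "P2"))   # <=16 missing kept
  # 4-sample case: 2 missing of 4 is removed
  ab2 <- make_masked(c(0, 0, 2), 4)
  expect_identical(filter_min_observed(ab2)$protein_ids, c("P1", "P2"))
  # fully observed matrix unchanged
  ab3 <- make_masked(rep(0, 5), 10)
  expect_identical(filter_min_observed(ab3)$log2, ab3$log2)
  # everything removed errors
  expect_error(filter_min_observed(make_masked(c(3, 3), 4)), "every protein")
})

test_that("downshift imputation has the prescribed moments and leaves observed cells", {
  set.seed(2)
  x <- matrix(rnorm(2e5, 20, 2), 2000, 100)
  mask <- matrix(runif(2e5) < 0.3, 2000, 100)
  x[mask] <- NA
  ab <- abundance_matrix(x)
  m <- mean(x[!mask]); s <- sd(x[!mask])
  imp <- impute_downshift(ab, seed = 3)
  expect_identical(imp$log2[!mask], x[!mask])
  expect_false(any(imp$mask))
  iv <- imp$log2[mask]
  expect_equal(mean(iv), m - 1.8 * s, tolerance = 0.02 * s)
  expect_equal(sd(iv), 0.3 * s, tolerance = 0.02 * s)
  # width = 0 collapses onto the downshifted mean exactly
  imp0 <- impute_downshift(ab, width = 0, seed = 3)
  expect_true(all(abs(imp0$log2[mask] - (m - 1.8 * s)) < 1e-12))
  # reproducible under the seed
  expect_identical(imp$log2, impute_downshift(ab, seed = 3)$log2)
  # degenerate: constant observed values
  cab <- abundance_matrix(matrix(c(rep(5, 39), NA), 8, 5))
  expect_error(impute_downshift(cab), "zero SD")
})

test_that("connectivity outlier removal finds the planted sample and stops", {
  set.seed(4)
  z <- rnorm(40)
  mat <- sapply(1:20, function(i) 20 + 0.9 * z + rnorm(40, 0, 0.3))
  mat <- cbind(mat, rnorm(40, 20, 1))
  dimnames(mat) <- list(paste0("P", 1:40), paste0("S", 1:21))
  out <- remove_outlier_samples(abundance_matrix(mat))
  expect_identical(unlist(out$report$removed), "S21")
  expect_identical(out$abundance$samples, paste0("S", 1:20))
  # idempotent: a second pass removes nothing
  again <- remove_outlier_samples(out$abundance)
  expect_length(again$report$removed, 0)
  # identical duplicated samples: none removed
  dup <- matrix(rnorm(200, 20), 50, 4)[, c(1:4, 1:4)]
  dimnames(dup) <- list(paste0("P", 1:50), paste0("S", 1:8))
  expect_length(remove_outlier_samples(abundance_matrix(dup))$report$removed, 0)
})

test_that("i.i.d. cohorts rarely trigger outlier removal", {
  removed <- vapply(1:40, function(s) {
    set.seed(s)
    m <- matrix(rnorm(100 * 30, 20), 100, 30)
    length(unlist(remove_outlier_samples(abundance_matrix(m))$report$removed))
  }, numeric(1))
  expect_lt(mean(removed > 0), 0.1)
})

toy_meta <- function(n, seed = 1) {
  set.seed(seed)
  validate_sample_meta(data.frame(
    sample_id = sprintf("S%02d", 1:n),
    diagnosis = rep(c("control", "AD"), length.out = n),
    apoe = rep(c("3/3", "3/3", "2/3", "4/4"), length.out = n),
    age = runif(n, 60, 90), sex = sample(c("M", "F"), n, TRUE),
    pmi = runif(n, 2, 24), braak = sample(0:6, n, TRUE),
    cerad = sample(0:3, n, TRUE)))
}

test_that("exact OLS regression removes covariates and keeps group effects", {
  n <- 40
  meta <- toy_meta(n, seed = 6)
  set.seed(7)
  grp_eff <- ifelse(meta$group == "AD_33", 1.5, 0)
  x <- t(sapply(1:50, function(i)
    20 + 0.1 * (meta$age - 75) + 0.5 * (meta$sex == "M") + grp_eff +
      rnorm(n, 0, 0.2)))
  dimnames(x) <- list(paste0("P", 1:50), meta$sample_id)
  ab <- abundance_matrix(x)
  reg <- regress_covariates(ab, meta,
                            regression_spec(n_bootstrap = 1, resample = FALSE))
  # the group-effect-free component is exactly orthogonal to the removed
  # covariates (the retained group means may still track covariates by
  # chance imbalance, which is intended)
  grp <- factor(meta$group)
  centred <- t(apply(reg$log2, 1, function(v) v - ave(v, grp)))
  expect_lt(max(abs(cor(t(centred), meta$age))), 1e-8)
  expect_lt(max(abs(cor(t(centred), as.numeric(factor(meta$sex))))), 1e-8)
  # planted group effect preserved up to residual noise
  d <- rowMeans(reg$log2[, meta$group == "AD_33"]) -
    rowMeans(reg$log2[, meta$group == "control_33"])
  expect_equal(mean(d), 1.5, tolerance = 0.1)
})

test_that("bootstrap regression approximates the null identity", {
  n <- 40
  meta <- toy_meta(n, seed = 8)
  set.seed(9)
  x <- matrix(rnorm(60 * n, 20, 0.2), 60, n,
              dimnames = list(paste0("P", 1:60), meta$sample_id))
  ab <- abundance_matrix(x)
  reg <- regress_covariates(ab, meta, regression_spec(n_bootstrap = 100,
                                                      seed = 10))
  expect_lt(max(abs(reg$log2 - x)), 0.35)
  expect_lt(mean(abs(reg$log2 - x)), 0.05)
})

test_that("regression rejects incomplete covariates and collinear designs", {
  meta <- toy_meta(8, seed = 11)
  x <- matrix(rnorm(80, 20), 10, 8,
              dimnames = list(paste0("P", 1:10), meta$sample_id))
  ab <- abundance_matrix(x)
  meta_bad <- meta
  meta_bad$age[1] <- NA
  expect_error(regress_covariates(ab, meta_bad, regression_spec()),
               "complete")
  meta_col <- meta
  meta_col$pmi <- meta_col$age        # collinear
  expect_error(regress_covariates(ab, meta_col, regression_spec()),
               "collinear|rank")
})

test_that("the PCA check flags raw covariate structure and clears after regression", {
  meta <- toy_meta(36, seed = 12)
  set.seed(13)
  lam <- rnorm(80, 1, 0.2)
  x <- 20 + outer(lam, 0.15 * (meta$age - 75)) + matrix(rnorm(80 * 36, 0, 0.3), 80)
  dimnames(x) <- list(paste0("P", 1:80), meta$sample_id)
  ab <- abundance_matrix(x)
  pre <- pca_covariate_check(ab, meta)
  expect_gt(max(pre$abs_rho[pre$covariate == "age"]), 0.5)
  reg <- regress_covariates(ab, meta,
                            regression_spec(n_bootstrap = 1, resample = FALSE))
  post <- pca_covariate_check(reg, meta)
  expect_lt(max(post$abs_rho[post$covariate == "age"]),
            max(pre$abs_rho[pre$covariate == "age"]))
  expect_error(pca_covariate_check(ab, meta, n_components = 100),
               "n_components")
})
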