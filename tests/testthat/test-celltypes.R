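test_that("exclusive culling removes overlaps from the new list only", {
  mk <- list(A = c("G1", "G2"), B = c("G3", "G4"), endothelia = c("G1", "G5"))
  out <- cull_exclusive_markers(mk)
  expect_identical(out$markers$endothelia, "G5")
  expect_identical(out$removed, "G1")
  # disjoint input is unchanged
  mk2 <- list(A = "G1", B = "G2", endothelia = "G3")
  expect_identical(cull_exclusive_markers(mk2)$markers, mk2)
  # residual overlap among protein-derived lists errors with the symbols
  mk3 <- list(A = c("G1", "G2"), B = c("G2", "G3"), endothelia = "G9")
  expect_error(cull_exclusive_markers(mk3), "G2")
  # generated marker sets pass through untouched
  co <- small_cohort(seed = 1)
  expect_identical(cull_exclusive_markers(co$markers)$markers,
                   lapply(co$markers, toupper))
})

test_that("gene collapse keeps the maximum-variance isoform with a stable tie-break", {
  x <- rbind(A2 = c(1, 5, 9, 13),     # var 4^2-ish, symbol G1
             A1 = c(1, 2, 3, 4),      # lower variance, symbol G1
             B1 = c(2, 2, 2, 3),      # unique symbol
             C2 = c(0, 2, 4, 6),      # tie with C1, symbol G3
             C1 = c(10, 12, 14, 16))  # same variance, earlier accession
  colnames(x) <- paste0("S", 1:4)
  ab <- abundance_matrix(x, gene_symbols = c("G1", "G1", "G2", "G3", "G3"))
  out <- collapse_to_gene(ab)
  expect_setequal(out$protein_ids, c("A2", "B1", "C1"))
  # all-unique symbols: identity
  ab2 <- abundance_matrix(x, gene_symbols = paste0("U", 1:5))
  expect_identical(collapse_to_gene(ab2)$protein_ids, rownames(x))
  expect_error(collapse_to_gene(abundance_matrix(x)), "symbol")
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  bg <- paste0("G", 1:1000)
  fe <- fisher_enrichment(list(m1 = bg[1:10]), list(ct = bg[1:100]), bg)
  expect_equal(fe$p, oracle_fisher_greater(10, 10, 100, 1000),
               tolerance = 1e-12)
  # random small tables against enumeration
  set.seed(2)
  for (i in 1:30) {
    nb <- sample(20:30, 1)
    bg2 <- paste0("g", seq_len(nb))
    ms <- sample(3:10, 1); ks <- sample(3:10, 1)
    mod <- sample(bg2, ms); mk <- sample(bg2, ks)
    fe2 <- fisher_enrichment(list(m = mod), list(c = mk), bg2)
    ov <- length(intersect(mod, mk))
    expect_equal(fe2$p, oracle_fisher_greater(ov, ms, ks, nb),
                 tolerance = 1e-12)
  }
  # zero overlap and marker list = background both give p = 1
  fe3 <- fisher_enrichment(list(m = bg[1:5]), list(c = bg[6:20]), bg[1:100])
  expect_equal(fe3$p, 1)
  fe4 <- fisher_enrichment(list(m = bg[1:5]), list(c = bg), bg)
  expect_equal(fe4$p, 1)
  expect_error(fisher_enrichment(list(m = "x"), list(c = "y"), character(0)),
               "background")
})

test_that("BH adjustment never decreases a p-value", {
  bg <- paste0("G", 1:200)
  mods <- list(m1 = bg[1:20], m2 = bg[21:50])
  mks <- list(a = bg[1:15], b = bg[40:60])
  fe <- fisher_enrichment(mods, mks, bg)
  expect_true(all(fe$p_adj >= fe$p))
})

test_that("deconvolution closes the loop exactly on noise-free mixtures", {
  d <- cohort_design(n_proteins = 200, markers_per_type = 30,
                     homeostatic_frac = 0,
                     covariate_effects = c(age = 0, sex = 0, pmi = 0),
                     noise_sd = 0, missing_rate = 0, module_plan = list(),
                     n_samples_per_group = c(8, 8, 8, 8), seed = 3)
  co <- generate_cohort(d)
  fr <- dsa_estimate_fractions(collapse_to_gene(co$abundance), co$markers)
  expect_lt(max(abs(fr$fractions - co$truth$true_fractions)), 1e-6)
  expect_lt(max(abs(rowSums(fr$fractions) - 1)), 1e-6)
})

test_that("deconvolution tolerates multiplicative noise", {
  d <- cohort_design(n_proteins = 200, markers_per_type = 30,
                     homeostatic_frac = 0,
                     covariate_effects = c(age = 0, sex = 0, pmi = 0),
                     noise_sd = log2(1.05), missing_rate = 0,
                     module_plan = list(),
                     n_samples_per_group = c(8, 8, 8, 8), seed = 4)
  co <- generate_cohort(d)
  fr <- dsa_estimate_fractions(collapse_to_gene(co$abundance), co$markers)
  expect_lt(sqrt(mean((fr$fractions - co$truth$true_fractions)^2)), 0.02)
})

test_that("degenerate deconvolution inputs are handled", {
  set.seed(5)
  lin <- matrix(2^rnorm(60, 20, 1), 6, 10,
                dimnames = list(paste0("P", 1:6), paste0("S", 1:10)))
  ab <- abundance_matrix(log2(lin), gene_symbols = paste0("G", 1:6),
                         linear_values = lin)
  # single cell type: all fractions 1
  fr <- dsa_estimate_fractions(ab, list(ct = paste0("G", 1:6)))
  expect_true(all(abs(fr$fractions - 1) < 1e-9))
  # too few markers
  expect_error(dsa_estimate_fractions(ab, list(ct = "G1", other = "G2")),
               "fewer than 3")
  # log-scale input triggers the heuristic warning
  ab_log <- abundance_matrix(log2(lin), gene_symbols = paste0("G", 1:6),
                             linear_values = log2(lin))
  expect_warning(dsa_estimate_fractions(ab_log, list(ct = paste0("G", 1:6))),
                 "linear")
})

test_that("scaling all markers of one type rescales its raw weight", {
  d <- cohort_design(n_proteins = 200, markers_per_type = 30,
                     homeostatic_frac = 0,
                     covariate_effects = c(age = 0, sex = 0, pmi = 0),
                     noise_sd = 0, missing_rate = 0, module_plan = list(),
                     n_samples_per_group = c(8, 8, 8, 8), seed = 6)
  co <- generate_cohort(d)
  gl <- collapse_to_gene(co$abundance)
  rows <- which(gl$gene_symbols %in% co$markers$astrocyte)
  lin2 <- gl$linear
  lin2[rows, ] <- lin2[rows, ] * 2
  gl2 <- abundance_matrix(log2(lin2), gene_symbols = gl$gene_symbols,
                          linear_values = lin2)
  f1 <- dsa_estimate_fractions(gl, co$markers)
  f2 <- dsa_estimate_fractions(gl2, co$markers)
  # marker means double, the fitted scale factor halves: fractions invariant
  expect_equal(f2$fractions, f1$fractions, tolerance = 1e-9)
  expect_equal(f2$scale_factors[["astrocyte"]],
               f1$scale_factors[["astrocyte"]] / 2, tolerance = 1e-9)
})

test_that("the covariate-adjusted group test has power and specificity", {
  set.seed(7)
  n <- 32
  meta <- validate_sample_meta(data.frame(
    sample_id = sprintf("S%02d", 1:n),
    diagnosis = rep(c("control", "AD"), each = 16),
    apoe = rep(c("3/3", "2/3", "3/3", "4/4"), each = 8),
    age = runif(n, 60, 90), sex = sample(c("M", "F"), n, TRUE),
    pmi = runif(n, 2, 24), braak = sample(0:6, n, TRUE),
    cerad = sample(0:3, n, TRUE)))
  hits <- replicate(60, {
    fr <- cbind(astrocyte = 0.3 + rnorm(n, 0, 0.02) +
                  0.1 * (meta$diagnosis == "AD"),
                neuron = 0.7 + rnorm(n, 0, 0.02))
    rownames(fr) <- meta$sample_id
    gt <- fraction_group_test(fr, meta)
    c(astro = gt$p[gt$celltype == "astrocyte"] < 0.01,
      neuron_null = gt$p[gt$celltype == "neuron"])
  })
  expect_gte(mean(hits["astro", ]), 0.95)
  expect_gt(ks.test(hits["neuron_null", ], "punif")$p.value, 0.01)
  # rank-based variant runs
  fr <- cbind(astrocyte = runif(n), neuron = runif(n))
  rownames(fr) <- meta$sample_id
  kt <- fraction_group_test(fr, meta, method = "kruskal")
  expect_true(all(is.finite(kt$p)))
})

test_that("fraction-trait correlations behave at the extremes", {
  set.seed(8)
  braak <- sample(0:6, 30, TRUE)
  fr <- cbind(a = braak + 0, b = runif(30), c = rep(0.5, 30))
  rownames(fr) <- sprintf("S%02d", 1:30)
  tc <- fraction_trait_correlation(fr, data.frame(braak = braak))
  expect_equal(tc$bicor[tc$celltype == "a"], 1, tolerance = 1e-9)
  expect_true(is.na(tc$bicor[tc$celltype == "c"]))   # constant fraction
  perm <- fraction_trait_correlation(fr[, "b", drop = FALSE],
                                     data.frame(x = sample(braak)))
  expect_gt(perm$p, 0.0001)
})
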