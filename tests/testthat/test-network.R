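test_that("signed adjacency maps correlations onto [0,1] monotonically", {
  cors <- seq(-1, 1, by = 0.25)
  vals <- vapply(cors, function(r) {
    cm <- matrix(c(1, r, r, 1), 2)
    adjacency(cm, 8)[1, 2]
  }, numeric(1))
  expect_equal(vals[cors == -1], 0)
  expect_equal(vals[cors == 0], 0.00390625)           # 0.5^8
  expect_equal(vals[cors == 1], 1)
  expect_true(all(diff(vals) >= 0))                   # monotone in cor
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("TOM matches hand-computed 2- and 3-node cases and the brute force", {
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  t2 <- tom_similarity(a2)
  expect_equal(t2[1, 2], (0 + 0.4) / (0.4 + 1 - 0.4))   # = a12
  a3 <- matrix(c(1, 0.5, 0.2,
                 0.5, 1, 0.3,
                 0.2, 0.3, 1), 3, byrow = TRUE)
  t3 <- tom_similarity(a3)
  expect_equal(t3[1, 2],
               (0.2 * 0.3 + 0.5) / (min(0.7, 0.8) + 1 - 0.5))
  set.seed(1)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    r <- matrix(runif(n^2), n); r <- (r + t(r)) / 2; diag(r) <- 1
    a <- adjacency(r, 8)
    tom <- tom_similarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(unname(diag(tom)), rep(1, n))
  }
})

test_that("identical rows with unit adjacency give maximal overlap", {
  a <- matrix(1, 4, 4)
  expect_equal(tom_similarity(a)[1, 2], 1)
})

test_that("module eigenproteins summarize rank-1 modules exactly", {
  set.seed(2)
  profile <- rnorm(20)
  mat <- t(sapply(1:5, function(i) 3 * profile + i))   # identical shapes
  dimnames(mat) <- list(paste0("P", 1:5), paste0("S", 1:20))
  ep <- module_eigenprotein(mat, 1:5)
  zp <- (profile - mean(profile)) / sd(profile)
  expect_equal(unname(ep$eigenprotein), zp, tolerance = 1e-9)
  expect_equal(ep$var_explained, 1, tolerance = 1e-12)
  # sign convention invariant under flipping all members
  ep2 <- module_eigenprotein(-mat, 1:5)
  expect_equal(unname(ep2$eigenprotein), -zp, tolerance = 1e-9)
  expect_error(module_eigenprotein(mat, 1), "at least 2")
  cmat <- rbind(mat, P9 = rep(1, 20))
  expect_error(module_eigenprotein(cmat, c(1, 6)), "constant")
})

test_that("eigenprotein matches a direct eigendecomposition oracle", {
  set.seed(3)
  mat <- matrix(rnorm(10 * 25), 10, 25,
                dimnames = list(paste0("P", 1:10), paste0("S", 1:25)))
  ep <- module_eigenprotein(mat, 1:10)
  z <- t(scale(t(mat)))
  ev <- eigen(crossprod(z))          # sample-space covariance
  v1 <- ev$vectors[, 1]
  v1 <- v1 / sd(v1)
  if (cor(v1, colMeans(z)) < 0) v1 <- -v1
  expect_equal(unname(ep$eigenprotein), v1, tolerance = 1e-9)
  expect_equal(ep$var_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-9)
})

test_that("modules merge below the cut height and not above", {
  set.seed(4)
  z <- rnorm(30)
  near1 <- t(sapply(1:6, function(i) z + rnorm(30, 0, 0.15)))
  near2 <- t(sapply(1:6, function(i) z + rnorm(30, 0, 0.15)))
  far <- t(sapply(1:6, function(i) rnorm(30)))
  mat <- rbind(near1, near2, far)
  dimnames(mat) <- list(paste0("P", 1:18), paste0("S", 1:30))
  labels <- rep(c("1", "2", "3"), each = 6)
  eg <- eigenprotein_matrix(mat, labels)
  d12 <- 1 - cor(eg[, "1"], eg[, "2"])
  expect_lt(d12, 0.07)
  merged <- merge_close_modules(mat, labels, 0.07)
  expect_identical(merged[1], merged[7])        # near modules fused
  expect_false(merged[1] == merged[13])         # far module kept
  # orthogonal modules are untouched at the default cut
  labs2 <- rep(c("1", "2"), each = 6)
  expect_identical(merge_close_modules(mat[c(1:6, 13:18), ], labs2, 0.07),
                   labs2)
})

test_that("kME is the Pearson correlation with eigenproteins", {
  set.seed(5)
  mat <- matrix(rnorm(12 * 20), 12, 20,
                dimnames = list(paste0("P", 1:12), paste0("S", 1:20)))
  labels <- rep(c("1", "2"), each = 6)
  eg <- eigenprotein_matrix(mat, labels)
  km <- kme(mat, eg)
  expect_equal(km[3, "1"], cor(mat[3, ], eg[, "1"]))
  # a protein equal to an eigenprotein has kME 1
  mat2 <- rbind(mat, P13 = eg[, "1"])
  expect_equal(kme(mat2, eg)["P13", "1"], 1)
  # constant protein reported missing
  mat3 <- rbind(mat, P13 = rep(2, 20))
  expect_true(all(is.na(kme(mat3, eg)["P13", ])))
})

test_that("module-trait correlations recover perfect and null relations", {
  set.seed(6)
  eg <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("M1", "M2")))
  traits <- data.frame(braak = eg[, 1], flat = rep(1, 30))
  tc <- module_trait_correlation(eg, traits)
  row <- tc[tc$module == "M1" & tc$trait == "braak", ]
  expect_equal(row$bicor, 1, tolerance = 1e-9)
  expect_lt(row$p, 1e-20)
  expect_identical(row$stars, "***")
  expect_true(is.na(tc$bicor[tc$trait == "flat"][1]))  # constant trait
  # permuted trait: no signal
  perm <- module_trait_correlation(eg, data.frame(x = sample(eg[, 1])))
  expect_lt(abs(perm$bicor[1]), 0.5)
})

test_that("module naming ranks by size with grey preserved", {
  labels <- c(rep("7", 3), rep("2", 5), "grey", "0")
  out <- name_modules_by_size(labels)
  expect_identical(out, c(rep("M2", 3), rep("M1", 5), "grey", "grey"))
})

test_that("two well-separated blocks are recovered exactly", {
  bm <- make_block_matrix(c(50, 50), c(0.9, 0.9), 40, 0, seed = 7)
  net <- build_network(bm$mat)
  mods <- setdiff(unique(net$labels), "grey")
  expect_identical(length(mods), 2L)
  expect_equal(oracle_ari(bm$truth, net$labels), 1)
})

test_that("minimum module size larger than any block leaves everything grey", {
  bm <- make_block_matrix(c(20, 20), c(0.9, 0.9), 30, 10, seed = 8)
  net <- build_network(bm$mat, params = network_params(min_module_size = 25))
  expect_true(all(net$labels == "grey"))
})

test_that("structureless data stays almost entirely unassigned", {
  for (s in 1:3) {
    set.seed(s)
    x <- matrix(rnorm(150 * 40), 150, 40)
    net <- build_network(x)
    expect_gte(mean(net$labels == "grey"), 0.9)
  }
})

test_that("planted cohort modules are recovered through the full network stage", {
  co <- small_cohort(seed = 10, covariate_effects = c(age = 0, sex = 0, pmi = 0))
  net <- build_network(co$abundance$log2)
  tm <- co$truth$true_modules
  ari <- oracle_ari(tm, net$labels[names(tm)])
  expect_gte(ari, 0.9)
  # kME of module members is highest for their own module
  km <- net$kme
  own <- vapply(names(tm), function(p) {
    lab <- net$labels[p]
    if (lab == "grey") return(NA_real_)
    km[p, lab] - max(km[p, setdiff(colnames(km), lab)])
  }, numeric(1))
  expect_gt(mean(own > 0, na.rm = TRUE), 0.9)
})
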