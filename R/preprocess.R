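as_log2 <- function(x) if (inherits(x, "abundance_matrix")) x$log2 else as.matrix(x)

#' Filter proteins by missing-value fraction
#'
#' Keeps proteins quantified in more than half of the samples (by
#' default): a protein is retained when its missing count is strictly
#' below `max_missing_fraction * n_samples`.  In a 34-sample cohort this
#' keeps proteins with up to 16 missing values and removes those with 17
#' or more.  Protein order is preserved.
#'
#' @param abundance an [abundance_matrix()].
#' @param max_missing_fraction maximum tolerated missing fraction
#'   (default 0.5, i.e. the >50% observed rule).
#' @return the filtered `abundance_matrix`.
#' @export
filter_min_observed <- function(abundance, max_missing_fraction = 0.5) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  n <- ncol(abundance$log2)
  if (n == 0 || nrow(abundance$log2) == 0) stop("empty abundance matrix")
  keep <- rowSums(abundance$mask) < max_missing_fraction * n
  if (!any(keep)) stop("filtering removed every protein")
  subset_abundance(abundance, which(keep))
}

#' Gaussian-downshift imputation of missing values
#'
#' Perseus-style imputation for left-censored LFQ missingness: with `m`
#' and `s` the mean and standard deviation of all observed log2 values in
#' the matrix, each missing cell is drawn from
#' `Normal(m - shift * s, (width * s)^2)`, i.e. a narrow Gaussian
#' down-shifted into the low-abundance tail.  The whole-matrix statistics
#' are the default; `per_sample = TRUE` applies the same rule within each
#' sample column instead.  Observed cells are never altered.
#'
#' @param abundance an [abundance_matrix()] on the log2 scale.
#' @param shift downshift in observed SD units (default 1.8).
#' @param width imputation SD in observed SD units (default 0.3).
#' @param seed RNG seed.
#' @param per_sample use per-column statistics instead of whole-matrix.
#' @return the imputed `abundance_matrix` (mask cleared).
#' @export
impute_downshift <- function(abundance, shift = 1.8, width = 0.3, seed = 1,
                             per_sample = FALSE) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  x <- abundance$log2
  mask <- abundance$mask
  if (sum(!mask) < 30) stop("need at least 30 observed values to impute")
  set.seed(seed)
  if (per_sample) {
    for (j in seq_len(ncol(x))) {
      obs <- x[!mask[, j], j]
      s <- stats::sd(obs)
      if (is.na(s) || s == 0) stop("zero SD of observed values in sample ", j)
      nmiss <- sum(mask[, j])
      if (nmiss)
        x[mask[, j], j] <- stats::rnorm(nmiss, mean(obs) - shift * s, width * s)
    }
  } else {
    obs <- x[!mask]
    s <- stats::sd(obs)
    if (s == 0) stop("zero SD of observed values; cannot impute")
    x[mask] <- stats::rnorm(sum(mask), mean(obs) - shift * s, width * s)
  }
  abundance_matrix(x, matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x)),
                   gene_symbols = abundance$gene_symbols)
}

#' Iterative connectivity-based sample outlier removal
#'
#' Computes the sample-sample biweight midcorrelation matrix, sample
#' connectivity `k_i = sum_{j != i} (1 + cor_ij) / 2`, standardizes to Z
#' scores and removes every sample whose connectivity Z falls below
#' `-z_threshold`; the procedure repeats on the remaining samples until
#' no outlier is detected (capped at `max_iter` iterations to guarantee
#' termination).
#'
#' @param abundance an [abundance_matrix()] with no missing values.
#' @param z_threshold removal threshold in SD units (default 3).
#' @param max_iter iteration cap (default 10).
#' @param method correlation used for connectivity: `"bicor"` (default,
#'   matching the network stage) or `"pearson"`.
#' @return list with `abundance` (outliers dropped) and `report`
#'   (`removed` per iteration, `final_z` per retained sample).
#' @export
remove_outlier_samples <- function(abundance, z_threshold = 3, max_iter = 10,
                                   method = c("bicor", "pearson")) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  method <- match.arg(method)
  x <- abundance$log2
  if (anyNA(x)) stop("outlier removal expects an imputed (complete) matrix")
  if (ncol(x) < 4) stop("need at least 4 samples")
  keep <- colnames(x)
  removed <- list()
  z <- NULL
  for (it in seq_len(max_iter)) {
    sub <- x[, keep, drop = FALSE]
    cc <- if (method == "bicor") bicor_matrix(sub) else stats::cor(sub)
    k <- colSums((1 + cc) / 2) - 1       # exclude self term
    z <- (k - mean(k)) / stats::sd(k)
    out <- keep[z < -z_threshold]
    if (!length(out)) break
    removed[[length(removed) + 1L]] <- out
    keep <- setdiff(keep, out)
    if (length(keep) < 4) stop("outlier removal left fewer than 4 samples")
  }
  list(abundance = subset_abundance(abundance, samples = keep),
       report = list(removed = removed,
                     final_z = stats::setNames(z, keep)))
}

#' Covariate regression specification
#'
#' @param protected categorical metadata column whose effects are kept
#'   (default the diagnosis/genotype `group`).
#' @param removed covariates regressed out (default age, sex, pmi).
#' @param n_bootstrap number of bootstrap resamples over which covariate
#'   coefficients are averaged (default 100).
#' @param resample set `FALSE` to fit once on the full sample (with
#'   `n_bootstrap = 1` this is exact OLS).
#' @param seed RNG seed for the resamples.
#' @return a `regression_spec` list.
#' @export
regression_spec <- function(protected = "group",
                            removed = c("age", "sex", "pmi"),
                            n_bootstrap = 100, resample = TRUE, seed = 1) {
  if (protected %in% removed) stop("protected trait cannot also be removed")
  structure(list(protected = protected, removed = removed,
                 n_bootstrap = n_bootstrap, resample = resample, seed = seed),
            class = "regression_spec")
}

#' Bootstrap regression of covariates from the abundance matrix
#'
#' Per protein, fits `log2 ~ protected group + covariates` and subtracts
#' the fitted covariate component, leaving group effects untouched.
#' Covariate coefficients are averaged over bootstrap resamples drawn
#' with replacement within each protected group (stratification keeps
#' small groups represented); with `n_bootstrap = 1` and resampling
#' disabled the result is the exact OLS partial residual, orthogonal to
#' every removed covariate.
#'
#' @param abundance an [abundance_matrix()] with no missing values.
#' @param meta metadata data.frame (see [read_sample_meta()]), rows
#'   matching the samples.
#' @param spec a [regression_spec()].
#' @return the regressed `abundance_matrix` (linear slot keeps the
#'   unregressed intensities for deconvolution).
#' @export
regress_covariates <- function(abundance, meta, spec = regression_spec()) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  x <- abundance$log2
  if (anyNA(x)) stop("regression expects an imputed (complete) matrix")
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  for (v in c(spec$protected, spec$removed))
    if (!v %in% names(meta)) stop("metadata is missing column: ", v)
  if (any(vapply(meta[spec$removed], anyNA, logical(1))))
    stop("covariates must be complete for all samples")

  grp <- factor(meta[[spec$protected]])
  covs <- meta[spec$removed]
  covs[] <- lapply(covs, function(v) {
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1  # e.g. sex as 0/1
    v - mean(v)   # centred so the removed component is mean-zero
  })
  X <- stats::model.matrix(~ grp + ., data = covs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[-seq_len(qrX$rank)], collapse = ", "))
  cov_cols <- seq.int(nlevels(grp) + 1L, ncol(X))
  Y <- t(x)                                  # samples x proteins

  set.seed(spec$seed)
  beta_sum <- matrix(0, length(cov_cols), ncol(Y))
  for (b in seq_len(spec$n_bootstrap)) {
    idx <- if (spec$resample) {
      unlist(lapply(split(seq_len(nrow(X)), grp),
                    function(i) sample(i, length(i), replace = TRUE)),
             use.names = FALSE)
    } else seq_len(nrow(X))
    Xb <- X[idx, , drop = FALSE]
    if (qr(Xb)$rank < ncol(Xb)) next       # degenerate resample: skip
    B <- solve(crossprod(Xb), crossprod(Xb, Y[idx, , drop = FALSE]))
    beta_sum <- beta_sum + B[cov_cols, , drop = FALSE]
  }
  beta_cov <- beta_sum / spec$n_bootstrap
  fitted_cov <- X[, cov_cols, drop = FALSE] %*% beta_cov
  out <- t(Y - fitted_cov)
  abundance_matrix(out, gene_symbols = abundance$gene_symbols,
                   linear_values = abundance$linear)
}

#' PCA verification of covariate regression
#'
#' Spearman correlation of the top principal-component sample scores with
#' each removed covariate, used to verify that covariate structure has
#' been regressed out of the matrix.  Well-regressed data show |rho|
#' below a few hundredths.
#'
#' @param abundance an [abundance_matrix()] (regressed or raw).
#' @param meta metadata data.frame.
#' @param n_components number of leading components tested (default 5).
#' @param covariates metadata columns to test (default age, sex, pmi).
#' @param threshold pass/fail |rho| threshold (default 0.02, the
#'   post-regression expectation).
#' @return data.frame with columns component, covariate, rho, abs_rho,
#'   pass; attribute `"max_abs_rho"`.
#' @export
pca_covariate_check <- function(abundance, meta, n_components = 5,
                                covariates = c("age", "sex", "pmi"),
                                threshold = 0.02) {
  x <- as_log2(abundance)
  if (anyNA(x)) stop("PCA check expects a complete matrix")
  if (n_components > min(dim(x))) stop("n_components exceeds matrix dimensions")
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- expand.grid(component = colnames(scores), covariate = covariates,
                     stringsAsFactors = FALSE)
  out$rho <- vapply(seq_len(nrow(out)), function(i) {
    v <- meta[[out$covariate[i]]]
    if (!is.numeric(v)) v <- as.numeric(factor(v))
    suppressWarnings(stats::cor(scores[, out$component[i]], v,
                                method = "spearman"))
  }, numeric(1))
  out$abs_rho <- abs(out$rho)
  out$pass <- out$abs_rho < threshold
  attr(out, "max_abs_rho") <- max(out$abs_rho, na.rm = TRUE)
  out
}
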