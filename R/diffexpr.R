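#' One-way ANOVA with Tukey pairwise tests, per protein
#'
#' For every protein row: a one-way ANOVA F test across the
#' diagnosis/genotype groups, plus Tukey HSD p-values for every group
#' pair from the studentized-range distribution with the pooled
#' within-group variance.  Unbalanced groups use the Tukey-Kramer
#' standard error `sqrt(s2/2 * (1/n_a + 1/n_b))`.  Pair `B-A` reports the
#' difference `mean(B) - mean(A)`.
#'
#' @param mat proteins x samples numeric matrix (a single vector is
#'   treated as one protein); typically the regressed log2 matrix.
#' @param groups per-sample group labels (factor level order defines the
#'   pair orientation).
#' @return a `diff_result` list: `group_means` (proteins x groups), `n`
#'   (per group), `F`, `p` (per protein), `diff` and `p_tukey`
#'   (proteins x pairs), `pairs`.
#' @export
anova_tukey <- function(mat, groups) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1,
                                       dimnames = list("x", names(mat)))
  mat <- as.matrix(mat)
  groups <- if (is.factor(groups)) droplevels(groups)
            else factor(groups, levels = unique(groups))
  if (ncol(mat) != length(groups)) stop("groups length must match sample count")
  ng <- table(groups)
  if (length(ng) < 2) stop("need at least 2 groups")
  if (any(ng < 2)) stop("every group needs at least 2 samples: ",
                        paste(names(ng)[ng < 2], collapse = ", "))
  k <- length(ng)
  N <- ncol(mat)
  G <- stats::model.matrix(~ 0 + groups)            # samples x groups
  means <- mat %*% G %*% diag(1 / as.numeric(ng))   # proteins x groups
  colnames(means) <- levels(groups)
  grand <- rowMeans(mat)
  ssb <- colSums((t(means) - rep(grand, each = k))^2 * as.numeric(ng))
  fitted <- means[, as.integer(groups), drop = FALSE]
  ssw <- rowSums((mat - fitted)^2)
  df1 <- k - 1; df2 <- N - k
  s2 <- ssw / df2
  Fstat <- (ssb / df1) / pmax(s2, .Machine$double.eps)
  pF <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(levels(groups), 2)
  pair_names <- apply(pairs, 2, function(p) paste(p[2], p[1], sep = "-"))
  diffs <- sapply(seq_len(ncol(pairs)), function(j)
    means[, pairs[2, j]] - means[, pairs[1, j]])
  se <- sapply(seq_len(ncol(pairs)), function(j)
    sqrt(s2 / 2 * (1 / ng[[pairs[1, j]]] + 1 / ng[[pairs[2, j]]])))
  diffs <- matrix(diffs, nrow(mat), dimnames = list(rownames(mat), pair_names))
  se <- matrix(se, nrow(mat))
  q <- abs(diffs) / pmax(se, .Machine$double.eps)
  p_tukey <- matrix(stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE),
                    nrow(mat), dimnames = dimnames(diffs))
  structure(list(group_means = means, n = ng,
                 F = stats::setNames(Fstat, rownames(mat)),
                 p = stats::setNames(pF, rownames(mat)),
                 diff = diffs, p_tukey = p_tukey, pairs = pair_names),
            class = "diff_result")
}

#' Per-module differential-abundance summary
#'
#' For each module and each pairwise comparison against the reference
#' group: the fraction of module members whose Tukey p passes `alpha`,
#' and the mean log2 difference over those significant members, signed as
#' case minus reference.
#'
#' @param labels per-protein module labels (named by protein).
#' @param diff a `diff_result` from [anova_tukey()].
#' @param reference reference group name (default `"control_33"`).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: module, comparison, n_members, n_significant,
#'   fraction, mean_log2_diff.
#' @export
module_diff_fraction <- function(labels, diff, reference = "control_33",
                                 alpha = 0.05) {
  stopifnot(inherits(diff, "diff_result"))
  comp <- grep(paste0("(^", reference, "-|-", reference, "$)"), diff$pairs,
               value = TRUE)
  if (!length(comp)) stop("no comparison involves the reference group")
  mods <- module_label_levels(labels)
  out <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    members <- intersect(members, rownames(diff$p_tukey))
    if (!length(members)) {
      warning("module ", m, " has no members in the differential result; skipped")
      next
    }
    for (cc in comp) {
      sig <- diff$p_tukey[members, cc] < alpha
      d <- diff$diff[members, cc]
      # orient as case minus reference
      if (startsWith(cc, paste0(reference, "-"))) d <- -d
      out[[length(out) + 1L]] <- data.frame(
        module = m, comparison = cc, n_members = length(members),
        n_significant = sum(sig), fraction = mean(sig),
        mean_log2_diff = if (any(sig)) mean(d[sig]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
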