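#' Cull marker lists to exclusive gene sets
#'
#' For the designated newly-added list (by default `endothelia`, an
#' RNA-derived list joined to four protein-derived lists), removes any
#' symbol that already appears in one of the other lists, then verifies
#' that all lists are pairwise disjoint.  Residual overlap among the
#' remaining lists is an error that names the offending symbols, since
#' the deconvolution model assumes exclusive markers.
#'
#' @param markers named list of gene-symbol vectors.
#' @param new_list name of the list to cull against the others.
#' @return list with `markers` (culled, disjoint) and `removed` (symbols
#'   culled from `new_list`).
#' @export
cull_exclusive_markers <- function(markers, new_list = "endothelia") {
  if (length(markers) < 2) stop("need at least 2 marker lists")
  markers <- lapply(markers, function(x) unique(toupper(x)))
  removed <- character(0)
  if (new_list %in% names(markers)) {
    others <- unique(unlist(markers[setdiff(names(markers), new_list)]))
    removed <- intersect(markers[[new_list]], others)
    markers[[new_list]] <- setdiff(markers[[new_list]], others)
  }
  nm <- names(markers)
  for (i in seq_along(nm)) for (j in seq_len(i - 1L)) {
    ov <- intersect(markers[[i]], markers[[j]])
    if (length(ov))
      stop(sprintf("marker lists '%s' and '%s' overlap: %s",
                   nm[j], nm[i], paste(ov, collapse = ", ")))
  }
  list(markers = markers, removed = removed)
}

#' Collapse protein isoforms to one row per gene symbol
#'
#' For every gene symbol, keeps the single protein row with the maximum
#' variance across samples; ties are broken by the lexicographically
#' first accession.  Run on unregressed abundances ahead of
#' deconvolution.
#'
#' @param abundance an [abundance_matrix()] with gene symbols.
#' @return the collapsed `abundance_matrix` (row names become accessions
#'   of the kept rows; one row per symbol).
#' @export
collapse_to_gene <- function(abundance) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  sym <- abundance$gene_symbols
  if (is.null(sym)) stop("abundance matrix has no gene symbol column")
  v <- apply(abundance$log2, 1, stats::var)
  v[is.na(v)] <- -Inf
  ord <- order(sym, -v, abundance$protein_ids)
  keep <- ord[!duplicated(sym[ord], incomparables = NA)]
  keep <- sort(keep[!is.na(sym[keep])])
  subset_abundance(abundance, keep)
}

#' Fisher exact cell-type enrichment of network modules
#'
#' One-sided (enrichment) Fisher exact test of every module x cell-type
#' 2x2 table over a background of network genes, with Benjamini-Hochberg
#' correction across the whole table.
#'
#' @param module_sets named list of per-module gene-symbol vectors.
#' @param markers named list of cell-type marker symbols.
#' @param background character vector of all network gene symbols.
#' @return data.frame: module, celltype, overlap, module_size,
#'   marker_size, odds_ratio, p, p_adj, stars.
#' @export
fisher_enrichment <- function(module_sets, markers, background) {
  background <- unique(toupper(background))
  if (!length(background)) stop("empty background")
  out <- list()
  for (m in names(module_sets)) {
    mod <- intersect(unique(toupper(module_sets[[m]])), background)
    for (ctype in names(markers)) {
      mk <- intersect(unique(toupper(markers[[ctype]])), background)
      a <- length(intersect(mod, mk))
      b <- length(mod) - a
      cc <- length(mk) - a
      d <- length(background) - a - b - cc
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2), alternative = "greater")
      out[[length(out) + 1L]] <- data.frame(
        module = m, celltype = ctype, overlap = a,
        module_size = length(mod), marker_size = length(mk),
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$stars <- p_stars(out$p_adj)
  out
}

#' Digital-sorting estimation of cell-type fractions
#'
#' Marker-based linear-model deconvolution of bulk tissue.  For each
#' sample `i` and cell type `j`, `s_ij` is the mean linear-scale
#' intensity of type `j`'s markers; per-type scale factors `q` solve the
#' least-squares system `S q = 1` (the proportions of every sample must
#' sum to one), and the fraction estimate is `f_ij = s_ij * q_j`.
#' Negative weights (possible in the unconstrained solution) are clipped
#' to zero and rows renormalized; pre-clip values are kept as
#' diagnostics.  Inputs must be linear-scale, unregressed, gene-collapsed
#' abundances.
#'
#' @param abundance an [abundance_matrix()] after [collapse_to_gene()];
#'   the `linear` slot is used.
#' @param markers named list of cell-type marker symbols (each needs >= 3
#'   markers present in the matrix).
#' @return a `cell_fractions` list: `fractions` (samples x cell types,
#'   rows sum to 1), `raw_weights` (pre-clip), `scale_factors`,
#'   `marker_counts`, `residual_norm`, `negative_cells`.
#' @export
dsa_estimate_fractions <- function(abundance, markers) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  lin <- abundance$linear
  lin[abundance$mask] <- NA_real_
  if (stats::median(lin, na.rm = TRUE) < 50 &&
      (max(lin, na.rm = TRUE) / max(stats::median(lin, na.rm = TRUE), 1e-12)) < 100)
    warning("input looks log-scaled; deconvolution expects linear intensities")
  sym <- abundance$gene_symbols
  types <- names(markers)
  S <- matrix(NA_real_, ncol(lin), length(types),
              dimnames = list(colnames(lin), types))
  counts <- integer(length(types)); names(counts) <- types
  for (j in types) {
    rows <- which(sym %in% toupper(markers[[j]]))
    counts[j] <- length(rows)
    if (length(rows) < 3)
      stop("cell type ", j, " has fewer than 3 markers present in the matrix")
    S[, j] <- colMeans(lin[rows, , drop = FALSE], na.rm = TRUE)
  }
  if (qr(S)$rank < ncol(S))
    stop("singular marker-mean matrix; cell-type profiles are collinear")
  q <- stats::lsfit(S, rep(1, nrow(S)), intercept = FALSE)$coefficients
  if (any(q < 0)) {
    warning("negative scale factor(s) clipped: ",
            paste(types[q < 0], collapse = ", "))
    q[q < 0] <- .Machine$double.eps
  }
  raw <- sweep(S, 2, q, `*`)
  frac <- pmax(raw, 0)
  frac <- frac / rowSums(frac)
  structure(list(fractions = frac, raw_weights = raw,
                 scale_factors = stats::setNames(as.numeric(q), types),
                 marker_counts = counts,
                 residual_norm = sqrt(sum((rowSums(raw) - 1)^2)),
                 negative_cells = which(raw < 0, arr.ind = TRUE)),
            class = "cell_fractions")
}

#' Group test of cell-type fractions adjusting for covariates
#'
#' Per cell type, fits `fraction ~ group + age + sex + pmi` and reports
#' the partial F test for the group factor (the covariate-adjusted test
#' of whether the estimated fraction differs among diagnosis/genotype
#' groups).  A rank-based Kruskal-Wallis test without covariates is
#' available as an alternative.
#'
#' @param fractions samples x cell types matrix (or `cell_fractions`).
#' @param meta metadata data.frame with `group`, `age`, `sex`, `pmi`.
#' @param covariates covariate columns adjusted for (default age, sex,
#'   pmi); ignored for the Kruskal-Wallis variant.
#' @param method `"partial_F"` (default) or `"kruskal"`.
#' @return data.frame: celltype, statistic, df1, df2, p.
#' @export
fraction_group_test <- function(fractions, meta,
                                covariates = c("age", "sex", "pmi"),
                                method = c("partial_F", "kruskal")) {
  method <- match.arg(method)
  if (inherits(fractions, "cell_fractions")) fractions <- fractions$fractions
  meta <- meta[match(rownames(fractions), meta$sample_id), , drop = FALSE]
  out <- list()
  for (ctype in colnames(fractions)) {
    y <- fractions[, ctype]
    if (method == "kruskal") {
      kt <- stats::kruskal.test(y, factor(meta$group))
      out[[ctype]] <- data.frame(celltype = ctype,
                                 statistic = unname(kt$statistic),
                                 df1 = unname(kt$parameter), df2 = NA_real_,
                                 p = kt$p.value, stringsAsFactors = FALSE)
    } else {
      df <- data.frame(y = y, group = factor(meta$group),
                       meta[covariates], stringsAsFactors = FALSE)
      df$sex <- if ("sex" %in% names(df)) as.numeric(factor(df$sex)) - 1
      full <- stats::lm(y ~ ., data = df)
      if (any(is.na(stats::coef(full)))) stop("rank-deficient design for ", ctype)
      reduced <- stats::lm(y ~ . - group, data = df)
      an <- stats::anova(reduced, full)
      out[[ctype]] <- data.frame(celltype = ctype, statistic = an$F[2],
                                 df1 = an$Df[2], df2 = an$Res.Df[2],
                                 p = an$`Pr(>F)`[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Correlation of cell-type fractions with AD pathology traits
#'
#' Biweight midcorrelation of each estimated cell-type fraction with each
#' numeric trait (Braak stage, CERAD score, ordinal APOE risk score, ...)
#' plus the t-approximation p-value.
#'
#' @param fractions samples x cell types matrix (or `cell_fractions`).
#' @param traits data.frame of numeric traits, rows matching the samples.
#' @return data.frame: celltype, trait, bicor, p, stars.
#' @export
fraction_trait_correlation <- function(fractions, traits) {
  if (inherits(fractions, "cell_fractions")) fractions <- fractions$fractions
  n <- nrow(fractions)
  out <- expand.grid(celltype = colnames(fractions), trait = names(traits),
                     stringsAsFactors = FALSE)
  out$bicor <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    y <- fractions[, out$celltype[i]]
    tr <- traits[[out$trait[i]]]
    if (length(unique(y)) < 2 || length(unique(tr)) < 2) next
    r <- bicor(y, tr)
    out$bicor[i] <- r
    out$p[i] <- cor_pvalue(r, n)
  }
  out$stars <- p_stars(out$p)
  out
}
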