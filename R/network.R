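#' Network parameters
#'
#' Parameter bundle for the signed weighted co-expression network.
#' Defaults are the settings used throughout the pipeline: soft power
#' `beta = 8`, `deep_split = 4`, minimum module size 12, eigenprotein
#' merge cut height 0.07, PAM stage respecting the dendrogram, and a
#' kME reassignment threshold of p < 0.05.
#'
#' @param beta soft-threshold power applied to the signed similarity.
#' @param deep_split cluster-splitting sensitivity, 0 (coarse) to 4 (fine).
#' @param min_module_size smallest allowed module.
#' @param merge_cut_height eigenprotein dissimilarity (1 - correlation)
#'   below which modules are merged.
#' @param pam_stage assign leftover proteins to the nearest module when
#'   consistent with their dendrogram branch.
#' @param reassign_p p-value threshold for kME-based reassignment.
#' @return a `network_params` list.
#' @export
network_params <- function(beta = 8, deep_split = 4, min_module_size = 12,
                           merge_cut_height = 0.07, pam_stage = TRUE,
                           reassign_p = 0.05) {
  stopifnot(beta >= 1, deep_split %in% 0:4, min_module_size >= 2,
            merge_cut_height > 0, merge_cut_height < 1)
  structure(list(beta = beta, deep_split = deep_split,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 pam_stage = pam_stage, reassign_p = reassign_p),
            class = "network_params")
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`: correlations are mapped onto \[0, 1\]
#' preserving their sign (anticorrelated pairs approach 0) and then raised
#' to a soft-threshold power that suppresses weak connections.
#'
#' @param cor_matrix symmetric correlation matrix with unit diagonal.
#' @param beta soft power (default 8).
#' @param signed signed transform (default); unsigned uses `|cor|^beta`.
#' @return adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
adjacency <- function(cor_matrix, beta = 8, signed = TRUE) {
  a <- if (signed) ((1 + cor_matrix) / 2)^beta else abs(cor_matrix)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Similarity of two nodes' network neighborhoods:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `u != i, j` and `k` the connectivity (row sum excluding the diagonal).
#' The diagonal is set to 1.
#'
#' @param adj symmetric adjacency matrix in \[0, 1\] with unit diagonal.
#' @return symmetric TOM in \[0, 1\].
#' @export
tom_similarity <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a              # sum_u a_iu a_uj over u != i, j
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Module eigenprotein
#'
#' First principal component of a module's proteins after per-protein
#' standardization, i.e. the summary abundance profile of the module.
#' Scores are scaled to unit standard deviation and sign-aligned so the
#' eigenprotein correlates positively with the module's average
#' standardized profile.
#'
#' @param mat proteins x samples log2 abundance matrix.
#' @param members protein ids or row indices of the module (>= 2).
#' @return list with `eigenprotein` (per-sample scores, unit SD),
#'   `var_explained` (proportion of member variance captured).
#' @export
module_eigenprotein <- function(mat, members) {
  if (is.character(members)) members <- match(members, rownames(mat))
  if (length(members) < 2) stop("a module needs at least 2 members")
  sub <- mat[members, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) stop("constant protein profile in module")
  z <- (sub - rowMeans(sub)) / sds
  sv <- svd(z)
  scores <- sv$v[, 1]
  scores <- scores / stats::sd(scores)
  avg <- colMeans(z)
  if (stats::cor(scores, avg) < 0) scores <- -scores
  list(eigenprotein = stats::setNames(scores, colnames(mat)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigenprotein matrix for a set of module labels
#'
#' @param mat proteins x samples log2 matrix.
#' @param labels per-protein module labels ("grey"/0 = unassigned).
#' @return samples x modules matrix of eigenprotein scores with a
#'   `var_explained` attribute.
#' @export
eigenprotein_matrix <- function(mat, labels) {
  mods <- module_label_levels(labels)
  if (!length(mods)) stop("no modules to summarize")
  eg <- sapply(mods, function(m) {
    module_eigenprotein(mat, which(labels == m))$eigenprotein
  })
  ve <- vapply(mods, function(m) {
    module_eigenprotein(mat, which(labels == m))$var_explained
  }, numeric(1))
  eg <- matrix(eg, nrow = ncol(mat), dimnames = list(colnames(mat), mods))
  attr(eg, "var_explained") <- ve
  eg
}

module_label_levels <- function(labels) {
  mods <- setdiff(unique(labels), c("grey", "0", 0, NA))
  # numeric module ids sort numerically, names like M1/M2 by module number
  num <- suppressWarnings(as.numeric(gsub("^M", "", mods)))
  if (!anyNA(num)) mods <- mods[order(num)]
  mods
}

#' Merge modules with similar eigenproteins
#'
#' Iteratively merges the closest pair of modules whose eigenprotein
#' dissimilarity `1 - cor` falls below the cut height, recomputing
#' eigenproteins after every merge until no pair is below the cut.
#'
#' @param mat proteins x samples log2 matrix.
#' @param labels per-protein module labels.
#' @param merge_cut_height dissimilarity threshold (default 0.07).
#' @return merged label vector.
#' @export
merge_close_modules <- function(mat, labels, merge_cut_height = 0.07) {
  labels <- as.character(labels)
  repeat {
    mods <- module_label_levels(labels)
    if (length(mods) < 2) break
    eg <- eigenprotein_matrix(mat, labels)
    d <- 1 - stats::cor(eg)
    diag(d) <- Inf
    if (min(d) >= merge_cut_height) break
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    keep <- mods[min(idx)]; drop <- mods[max(idx)]
    labels[labels == drop] <- keep
  }
  labels
}

#' Module membership (kME) table
#'
#' Pearson correlation of every protein profile with every module
#' eigenprotein.  Proteins with constant profiles get `NA`.
#'
#' @param mat proteins x samples log2 matrix.
#' @param eigenproteins samples x modules matrix.
#' @return proteins x modules kME matrix.
#' @export
kme <- function(mat, eigenproteins) {
  if (ncol(mat) != nrow(eigenproteins))
    stop("sample dimensions of matrix and eigenproteins disagree")
  suppressWarnings(stats::cor(t(mat), eigenproteins))
}

#' Module-trait correlation table
#'
#' Biweight midcorrelation of each module eigenprotein with each numeric
#' trait (e.g. Braak stage, CERAD score, the ordinal APOE risk score),
#' with Student-t p-values and significance stars.
#'
#' @param eigenproteins samples x modules matrix.
#' @param traits data.frame of numeric traits (rows = samples).
#' @return data.frame with columns module, trait, bicor, p, stars.
#' @export
module_trait_correlation <- function(eigenproteins, traits) {
  n <- nrow(eigenproteins)
  out <- expand.grid(module = colnames(eigenproteins), trait = names(traits),
                     stringsAsFactors = FALSE)
  out$bicor <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    tr <- traits[[out$trait[i]]]
    if (length(unique(tr)) < 2) next   # constant trait: left missing
    r <- bicor(eigenproteins[, out$module[i]], tr)
    out$bicor[i] <- r
    out$p[i] <- cor_pvalue(r, n)
  }
  out$stars <- p_stars(out$p)
  out
}

#' Rename module labels by descending size
#'
#' Largest module becomes "M1", second largest "M2", ...; unassigned
#' proteins keep the label "grey".
#'
#' @param labels per-protein labels (any coding; 0/"0"/"grey" = grey).
#' @return character vector of "M<k>"/"grey" labels.
#' @export
name_modules_by_size <- function(labels) {
  labels <- as.character(labels)
  labels[labels %in% c("0", "grey", NA)] <- "grey"
  mods <- setdiff(unique(labels), "grey")
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  map <- stats::setNames(paste0("M", seq_along(ord)), ord)
  out <- ifelse(labels == "grey", "grey", map[labels])
  unname(out)
}

# kME-based reassignment: a protein whose kME to another module exceeds its
# own-module kME, with the foreign kME significant at reassign_p, moves to
# that module (approximation of the reassignment threshold of the reference
# blockwise procedure).
reassign_by_kme <- function(mat, labels, reassign_p = 0.05) {
  mods <- module_label_levels(labels)
  if (length(mods) < 2) return(labels)
  eg <- eigenprotein_matrix(mat, labels)
  km <- kme(mat, eg)
  n <- ncol(mat)
  assigned <- which(labels %in% mods)
  for (i in assigned) {
    own <- labels[i]
    best <- colnames(km)[which.max(km[i, ])]
    if (!identical(best, own) &&
        isTRUE(km[i, best] > km[i, own]) &&
        cor_pvalue(km[i, best], n) < reassign_p) {
      labels[i] <- best
    }
  }
  labels
}

#' Build a signed weighted protein co-expression network
#'
#' Full network stage: pairwise biweight midcorrelations between protein
#' profiles, signed soft-threshold adjacency, topological overlap,
#' average-linkage clustering of 1 - TOM with a dynamic hybrid tree cut,
#' eigenprotein-based module merging, size-ranked module naming, kME
#' computation with reassignment, and module-trait correlations.
#'
#' @param mat proteins x samples log2 abundance matrix (imputed/regressed;
#'   no missing values).
#' @param traits optional data.frame of numeric per-sample traits for the
#'   module-trait table.
#' @param params a [network_params()] bundle.
#' @return a `network_result` list: `labels`, `eigenproteins`, `kme`,
#'   `trait_correlations`, `var_explained`, `dendrogram`, `params`.
#' @export
build_network <- function(mat, traits = NULL, params = network_params()) {
  if (anyNA(mat)) stop("network input must be fully observed (impute first)")
  cormat <- bicor_matrix(t(mat))
  adj <- adjacency(cormat, beta = params$beta)
  tom <- tom_similarity(adj)
  cut <- detect_modules(1 - tom, params)
  labels <- merge_close_modules(mat, cut$labels, params$merge_cut_height)
  labels <- name_modules_by_size(labels)
  if (length(module_label_levels(labels)) >= 2)
    labels <- name_modules_by_size(
      reassign_by_kme(mat, labels, params$reassign_p))
  if (length(module_label_levels(labels))) {
    eg <- eigenprotein_matrix(mat, labels)
    km <- kme(mat, eg)
    trait_cor <- if (!is.null(traits)) module_trait_correlation(eg, traits)
  } else {
    eg <- NULL; km <- NULL; trait_cor <- NULL
  }
  structure(list(labels = stats::setNames(labels, rownames(mat)),
                 eigenproteins = eg, kme = km,
                 trait_correlations = trait_cor,
                 var_explained = if (!is.null(eg)) attr(eg, "var_explained"),
                 dendrogram = cut$dendrogram, params = params),
            class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  mods <- module_label_levels(x$labels)
  cat(sprintf("network_result: %d proteins, %d modules, %d grey\n",
              length(x$labels), length(mods), sum(x$labels == "grey")))
  invisible(x)
}
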