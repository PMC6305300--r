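#' Split significant cell-type markers by direction of change
#'
#' From the defining pairwise comparison (AD E3/3 versus control E3/3 by
#' default), takes each cell type's markers that pass the Tukey p
#' threshold and splits them by the sign of the AD-minus-control log2
#' difference: increased markers are "disease-associated" (they move
#' with the bulk cell-type abundance change), decreased markers are
#' "homeostatic" (they move against it).  Non-markers are excluded
#' regardless of significance.
#'
#' @param diff a `diff_result` from [anova_tukey()] containing the
#'   defining comparison.
#' @param markers named list of cell-type marker symbols.
#' @param gene_symbols per-protein symbols named by protein id (used to
#'   match markers to protein rows).
#' @param comparison pair label of the defining comparison (default
#'   `"AD_33-control_33"`; the reversed orientation is accepted).
#' @param alpha significance threshold (default 0.05).
#' @return a `direction_split` list, per cell type: `increased` and
#'   `decreased` data.frames (protein, symbol, p, log2_diff).
#' @export
split_markers_by_direction <- function(diff, markers, gene_symbols,
                                       comparison = "AD_33-control_33",
                                       alpha = 0.05) {
  stopifnot(inherits(diff, "diff_result"))
  flip <- FALSE
  if (!comparison %in% diff$pairs) {
    rev_cmp <- paste(rev(strsplit(comparison, "-", fixed = TRUE)[[1]]),
                     collapse = "-")
    if (!rev_cmp %in% diff$pairs)
      stop("comparison '", comparison, "' not present in the differential result")
    comparison <- rev_cmp
    flip <- TRUE
  }
  p <- diff$p_tukey[, comparison]
  d <- diff$diff[, comparison]
  if (flip) d <- -d
  sym <- toupper(gene_symbols[rownames(diff$p_tukey)])
  out <- list()
  for (ctype in names(markers)) {
    is_marker <- sym %in% toupper(markers[[ctype]])
    sig <- which(is_marker & p < alpha)
    tab <- data.frame(protein = rownames(diff$p_tukey)[sig],
                      symbol = sym[sig], p = p[sig], log2_diff = d[sig],
                      row.names = NULL, stringsAsFactors = FALSE)
    out[[ctype]] <- list(increased = tab[tab$log2_diff > 0, , drop = FALSE],
                         decreased = tab[tab$log2_diff < 0, , drop = FALSE])
  }
  structure(out, class = "direction_split", comparison = comparison)
}

#' Synthetic eigenprotein of an arbitrary protein list
#'
#' Treats a protein list (e.g. a direction-split marker group) as a
#' synthetic co-expression module and computes its eigenprotein on the
#' regressed abundance matrix — the identical computation to
#' [module_eigenprotein()].
#'
#' @param mat regressed proteins x samples log2 matrix.
#' @param proteins protein ids (>= 2 must be present in the matrix).
#' @return list with `eigenprotein`, `var_explained`, `n_used`,
#'   `n_dropped` (markers absent from the matrix).
#' @export
synthetic_eigenprotein <- function(mat, proteins) {
  present <- intersect(proteins, rownames(mat))
  dropped <- length(proteins) - length(present)
  if (dropped)
    message(dropped, " protein(s) absent from the matrix were dropped")
  if (length(present) < 2)
    stop("fewer than 2 listed proteins present in the matrix")
  ep <- module_eigenprotein(mat, present)
  c(ep, list(n_used = length(present), n_dropped = dropped))
}

#' Group comparison of a phenotype eigenprotein
#'
#' One-way ANOVA with Tukey pairwise tests of a synthetic eigenprotein
#' across the diagnosis/genotype groups, plus per-group box-plot summary
#' statistics (median and quartiles).
#'
#' @param eigenprotein named per-sample eigenprotein scores.
#' @param groups per-sample group labels.
#' @return list with `anova_p`, `tukey` (data.frame: comparison, diff,
#'   p), `group_summary` (median/quartiles per group).
#' @export
phenotype_group_comparison <- function(eigenprotein, groups) {
  dr <- anova_tukey(matrix(eigenprotein, nrow = 1,
                           dimnames = list("eigenprotein",
                                           names(eigenprotein))), groups)
  qs <- tapply(eigenprotein, groups, stats::quantile,
               probs = c(0.25, 0.5, 0.75))
  gs <- data.frame(group = names(qs),
                   q1 = vapply(qs, `[`, numeric(1), 1),
                   median = vapply(qs, `[`, numeric(1), 2),
                   q3 = vapply(qs, `[`, numeric(1), 3),
                   row.names = NULL, stringsAsFactors = FALSE)
  list(anova_p = unname(dr$p),
       tukey = data.frame(comparison = dr$pairs,
                          diff = as.numeric(dr$diff),
                          p = as.numeric(dr$p_tukey),
                          stringsAsFactors = FALSE),
       group_summary = gs)
}

#' Direction-split eigenprotein analysis for every cell type
#'
#' Convenience wrapper running [synthetic_eigenprotein()] and
#' [phenotype_group_comparison()] for the increased (disease-associated)
#' and decreased (homeostatic) marker group of each cell type.
#'
#' @param split a `direction_split` from [split_markers_by_direction()].
#' @param mat regressed proteins x samples log2 matrix.
#' @param groups per-sample group labels.
#' @param min_members smallest marker group analysed (default 2).
#' @return nested list `[[celltype]][[direction]]` with elements
#'   `eigenprotein`, `anova_p`, `tukey`, `group_summary`, `n_members`;
#'   directions are `disease_associated` (increased) and `homeostatic`
#'   (decreased).
#' @export
phenotype_analysis <- function(split, mat, groups, min_members = 2) {
  stopifnot(inherits(split, "direction_split"))
  out <- list()
  for (ctype in names(split)) {
    for (dir in c("increased", "decreased")) {
      tab <- split[[ctype]][[dir]]
      label <- if (dir == "increased") "disease_associated" else "homeostatic"
      if (nrow(tab) < min_members) next
      ep <- synthetic_eigenprotein(mat, tab$protein)
      cmp <- phenotype_group_comparison(ep$eigenprotein, groups)
      out[[ctype]][[label]] <- c(list(eigenprotein = ep$eigenprotein,
                                      n_members = nrow(tab)), cmp)
    }
  }
  out
}
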