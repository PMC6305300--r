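#' Pipeline configuration
#'
#' Collects file paths and every stage parameter with the pipeline
#' defaults: >50% observation filter, downshift imputation at 1.8/0.3 SD,
#' outlier threshold Z < -3, signed network at beta 8 with deep split 4,
#' minimum module size 12 and merge cut height 0.07, and alpha 0.05 for
#' differential tests.  Any override is recorded in the run manifest.
#'
#' @param abundance,meta,markers_dir,peptides input paths (peptides
#'   optional).
#' @param out output run directory.
#' @param seed global seed; per-stage child seeds are derived from it by
#'   stable hashing of the stage name.
#' @param ... parameter overrides (see Defaults in the source).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(abundance, meta, markers_dir = NULL,
                            peptides = NULL, out = "apoenet_run",
                            seed = 1, ...) {
  params <- list(
    max_missing_fraction = 0.5,
    impute_shift = 1.8, impute_width = 0.3,
    outlier_z = 3,
    beta = 8, deep_split = 4, min_module_size = 12, merge_cut_height = 0.07,
    pam_stage = TRUE, reassign_p = 0.05,
    n_bootstrap = 100, alpha = 0.05,
    reference_group = "control_33",
    defining_comparison = "AD_33-control_33",
    new_marker_list = "endothelia")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  params[names(dots)] <- dots
  structure(list(abundance = abundance, meta = meta,
                 markers_dir = markers_dir, peptides = peptides,
                 out = out, seed = as.integer(seed), params = params,
                 overrides = names(dots)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML file holds the input paths at the top level and stage
#' parameter overrides under `params:`.
#'
#' @param path YAML config path.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("abundance", "meta", "markers_dir",
                                  "peptides", "out", "seed"))]
  do.call(pipeline_config, c(args, y$params))
}

# stable per-stage child seed below 2^31
stage_seed <- function(seed, stage) {
  (seed * 10007L + sum(utf8ToInt(stage)) * 131L) %% 2147483647L
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s (check the stage inputs and the %s parameters in the config)",
                 name, conditionMessage(e), name), call. = FALSE))
}

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- data.frame(stats::setNames(list(rownames(df)), rownames_as),
                     as.data.frame(df), check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (filter, impute, outlier removal, covariate
#' regression, PCA check), the optional peptide quantification, the
#' co-expression network, differential expression, cell-type enrichment
#' and deconvolution, and the direction-split phenotype analysis, writing
#' every stage output plus a run manifest into the output directory.
#' Identical configuration and seed yield identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of in-memory stage results; side effect:
#'   TSV/JSON outputs under `config$out`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  abund <- run_stage("io", read_abundance(config$abundance))
  meta <- run_stage("io", read_sample_meta(config$meta))
  markers <- if (!is.null(config$markers_dir))
    run_stage("io", read_marker_sets(config$markers_dir))

  ## ---- preprocess ----------------------------------------------------
  res <- list()
  pre <- run_stage("preprocess", {
    f <- filter_min_observed(abund, p$max_missing_fraction)
    imp <- impute_downshift(f, p$impute_shift, p$impute_width,
                            seed = stage_seed(config$seed, "impute"))
    orr <- remove_outlier_samples(imp, p$outlier_z)
    meta_kept <- meta[meta$sample_id %in% orr$abundance$samples, ,
                      drop = FALSE]
    reg <- regress_covariates(orr$abundance, meta_kept,
                              regression_spec(n_bootstrap = p$n_bootstrap,
                                              seed = stage_seed(config$seed,
                                                                "regress")))
    pca <- pca_covariate_check(reg, meta_kept)
    list(unregressed = orr$abundance, regressed = reg, meta = meta_kept,
         outliers = orr$report, pca = pca)
  })
  res$preprocess <- pre
  jsonlite::write_json(
    list(removed = pre$outliers$removed,
         final_z = as.list(round(pre$outliers$final_z, 4))),
    file.path(config$out, "outlier_report.json"), auto_unbox = TRUE)
  write_tsv(pre$pca, file.path(config$out, "pca_check.tsv"))

  ## ---- peptide quantification (optional) -----------------------------
  if (!is.null(config$peptides)) {
    res$peptides <- run_stage("peptide_quant", {
      pt <- read_peptide_table(config$peptides)
      tau <- tau_mtbr_ratio(pt)
      write_tsv(tau, file.path(config$out, "tau_mtbr_ratio.tsv"))
      tau
    })
  }

  ## ---- network -------------------------------------------------------
  traits <- pre$meta[, c("braak", "cerad", "apoe_ordinal")]
  net <- run_stage("network", build_network(
    pre$regressed$log2, traits,
    network_params(beta = p$beta, deep_split = p$deep_split,
                   min_module_size = p$min_module_size,
                   merge_cut_height = p$merge_cut_height,
                   pam_stage = p$pam_stage, reassign_p = p$reassign_p)))
  res$network <- net
  write_tsv(data.frame(protein = names(net$labels), module = net$labels,
                       symbol = pre$regressed$gene_symbols),
            file.path(config$out, "module_labels.tsv"))
  if (!is.null(net$eigenproteins)) {
    write_tsv(net$eigenproteins, file.path(config$out, "eigenproteins.tsv"),
              rownames_as = "sample_id")
    write_tsv(round(net$kme, 6), file.path(config$out, "kme.tsv"),
              rownames_as = "protein")
    write_tsv(net$trait_correlations,
              file.path(config$out, "module_trait_correlations.tsv"))
    writeLines(as.character(net$dendrogram$height),
               file.path(config$out, "dendrogram_heights.txt"))
  }

  ## ---- differential expression ---------------------------------------
  groups <- factor(pre$meta$group, levels = unique(pre$meta$group))
  diffres <- run_stage("diffexpr", anova_tukey(pre$regressed$log2, groups))
  res$diff <- diffres
  voltab <- data.frame(protein = rownames(diffres$diff),
                       symbol = pre$regressed$gene_symbols,
                       anova_F = diffres$F, anova_p = diffres$p)
  for (cc in diffres$pairs) {
    voltab[[paste0("diff.", cc)]] <- diffres$diff[, cc]
    voltab[[paste0("p.", cc)]] <- diffres$p_tukey[, cc]
  }
  write_tsv(voltab, file.path(config$out, "differential_expression.tsv"))
  if (!is.null(net$eigenproteins)) {
    mdf <- run_stage("diffexpr", module_diff_fraction(
      net$labels, diffres, reference = p$reference_group, alpha = p$alpha))
    res$module_diff <- mdf
    write_tsv(mdf, file.path(config$out, "module_diff_fractions.tsv"))
  }

  ## ---- cell types ----------------------------------------------------
  if (!is.null(markers)) {
    ct <- run_stage("celltypes", {
      culled <- cull_exclusive_markers(markers, p$new_marker_list)
      gene_level <- collapse_to_gene(pre$unregressed)
      mods <- module_label_levels(net$labels)
      module_sets <- lapply(stats::setNames(mods, mods), function(m)
        stats::na.omit(pre$regressed$gene_symbols[net$labels == m]))
      enr <- if (length(mods)) fisher_enrichment(
        module_sets, culled$markers,
        background = stats::na.omit(pre$regressed$gene_symbols))
      fr <- dsa_estimate_fractions(gene_level, culled$markers)
      gt <- fraction_group_test(fr, pre$meta)
      tc <- fraction_trait_correlation(fr, traits)
      list(markers = culled$markers, culled = culled$removed,
           enrichment = enr, fractions = fr, group_test = gt,
           trait_correlation = tc)
    })
    res$celltypes <- ct
    if (!is.null(ct$enrichment))
      write_tsv(ct$enrichment, file.path(config$out, "cell_type_enrichment.tsv"))
    write_tsv(round(ct$fractions$fractions, 6),
              file.path(config$out, "cell_fractions.tsv"),
              rownames_as = "sample_id")
    write_tsv(ct$group_test, file.path(config$out, "fraction_group_tests.tsv"))
    write_tsv(ct$trait_correlation,
              file.path(config$out, "fraction_trait_correlations.tsv"))

    ## ---- phenotypes --------------------------------------------------
    phen <- run_stage("phenotypes", {
      split <- split_markers_by_direction(
        diffres, ct$markers, stats::setNames(pre$regressed$gene_symbols,
                                             pre$regressed$protein_ids),
        comparison = p$defining_comparison, alpha = p$alpha)
      phenotype_analysis(split, pre$regressed$log2, groups)
    })
    res$phenotypes <- phen
    jsonlite::write_json(
      lapply(phen, function(ctl) lapply(ctl, function(z)
        list(n_members = z$n_members, anova_p = z$anova_p,
             tukey = z$tukey, group_summary = z$group_summary))),
      file.path(config$out, "phenotype_eigenproteins.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  ## ---- manifest ------------------------------------------------------
  param_str <- paste(names(p), vapply(p, paste, character(1), collapse = ","),
                     sep = "=", collapse = ";")
  manifest <- list(
    package = "apoenet",
    version = as.character(utils::packageVersion("apoenet")),
    seed = config$seed,
    inputs = list(abundance = config$abundance, meta = config$meta,
                  markers_dir = config$markers_dir,
                  peptides = config$peptides),
    parameters = p, overrides = config$overrides,
    parameter_hash = sprintf("%08x", sum(utf8ToInt(param_str) *
                                           seq_along(utf8ToInt(param_str))) %%
                               .Machine$integer.max),
    n_proteins = nrow(pre$regressed$log2),
    n_samples = ncol(pre$regressed$log2),
    n_modules = length(module_label_levels(net$labels)))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(res)
}

#' Summarize a pipeline run as a markdown report
#'
#' Collects the tabular outputs of [run_pipeline()] into a single
#' markdown document: module counts and module-trait correlations, the
#' per-module differential-abundance fractions, the cell-type enrichment
#' grid, cell-fraction summaries and the direction-split phenotype
#' eigenprotein comparisons.  Sections whose output files are absent are
#' skipped with a note, so partial runs yield partial reports.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path output file (default `report.md` inside `run_dir`).
#' @return the report path, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  lines <- c("# apoenet run report", "")
  manifest_file <- file.path(run_dir, "manifest.json")
  if (file.exists(manifest_file)) {
    mf <- jsonlite::read_json(manifest_file)
    lines <- c(lines,
               sprintf("- proteins analysed: %s", mf$n_proteins),
               sprintf("- samples retained: %s", mf$n_samples),
               sprintf("- modules detected: %s", mf$n_modules),
               sprintf("- seed: %s; parameter hash: %s", mf$seed,
                       mf$parameter_hash), "")
  }
  md_table <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 4) else x)
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  section <- function(title, file, note) {
    fp <- file.path(run_dir, file)
    if (!file.exists(fp)) return(c(paste("##", title), "", note, ""))
    df <- utils::read.delim(fp, check.names = FALSE)
    c(paste("##", title), "", md_table(df), "")
  }
  lines <- c(lines,
    section("Module-trait correlations", "module_trait_correlations.tsv",
            "_No module-trait table (no modules detected or traits absent)._"),
    section("Module differential-abundance fractions",
            "module_diff_fractions.tsv", "_No module summary available._"),
    section("Cell-type enrichment", "cell_type_enrichment.tsv",
            "_No marker lists supplied; enrichment section omitted._"),
    section("Cell-type fraction group tests", "fraction_group_tests.tsv",
            "_No deconvolution output._"),
    section("Cell-type fraction trait correlations",
            "fraction_trait_correlations.tsv", "_No deconvolution output._"))
  phen_file <- file.path(run_dir, "phenotype_eigenproteins.json")
  lines <- c(lines, "## Phenotype eigenproteins", "")
  if (file.exists(phen_file)) {
    ph <- jsonlite::read_json(phen_file)
    for (ctype in names(ph)) for (dir in names(ph[[ctype]])) {
      z <- ph[[ctype]][[dir]]
      lines <- c(lines, sprintf("- %s / %s: %s members, ANOVA p = %.3g",
                                ctype, dir, z$n_members, z$anova_p))
    }
  } else {
    lines <- c(lines, "_No phenotype eigenprotein output._")
  }
  writeLines(lines, path)
  invisible(path)
}
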