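#' Construct an abundance matrix
#'
#' The central container of the pipeline: a proteins x samples matrix of
#' log2 LFQ intensities with an explicit missing-value mask.  Linear-scale
#' originals are kept alongside because cell-type deconvolution operates on
#' unlogged, unregressed intensities while every other stage works on the
#' log2 scale.
#'
#' @param log2_values numeric matrix, proteins in rows, samples in columns;
#'   cells under the mask may be `NA`.
#' @param missing_mask logical matrix of the same dimension; `TRUE` marks a
#'   missing (non-detected) cell.  Defaults to `is.na(log2_values)`.
#' @param gene_symbols optional character vector of per-protein gene
#'   symbols (upper-cased for marker matching); `NA` allowed.
#' @param linear_values optional matrix of linear-scale intensities; when
#'   omitted it is reconstructed as `2^log2_values`.
#' @return an object of class `abundance_matrix` with elements `log2`,
#'   `mask`, `linear`, `protein_ids`, `gene_symbols`, `samples`.
#' @export
abundance_matrix <- function(log2_values, missing_mask = NULL,
                             gene_symbols = NULL, linear_values = NULL) {
  if (!is.matrix(log2_values)) log2_values <- as.matrix(log2_values)
  if (is.null(rownames(log2_values)))
    rownames(log2_values) <- paste0("P", seq_len(nrow(log2_values)))
  if (is.null(colnames(log2_values)))
    colnames(log2_values) <- paste0("S", seq_len(ncol(log2_values)))
  if (anyDuplicated(rownames(log2_values)))
    stop("duplicate protein accessions in abundance matrix")
  if (is.null(missing_mask)) missing_mask <- is.na(log2_values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(log2_values)))
    stop("missing_mask dimensions do not match log2_values")
  if (any(is.na(log2_values) & !missing_mask))
    stop("NA values outside the missing mask")
  storage.mode(missing_mask) <- "logical"
  dimnames(missing_mask) <- dimnames(log2_values)
  if (is.null(linear_values)) {
    linear_values <- 2^log2_values
  } else {
    linear_values <- as.matrix(linear_values)
    dimnames(linear_values) <- dimnames(log2_values)
    if (any(linear_values[!missing_mask] <= 0, na.rm = TRUE))
      stop("linear values must be strictly positive where observed")
  }
  if (!is.null(gene_symbols)) {
    if (length(gene_symbols) != nrow(log2_values))
      stop("gene_symbols length does not match protein count")
    gene_symbols <- toupper(as.character(gene_symbols))
    gene_symbols[gene_symbols == ""] <- NA_character_
  }
  structure(list(
    log2 = log2_values,
    mask = missing_mask,
    linear = linear_values,
    protein_ids = rownames(log2_values),
    gene_symbols = gene_symbols,
    samples = colnames(log2_values)
  ), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$log2), ncol(x$log2), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$log2)

#' Subset an abundance matrix by protein and/or sample
#'
#' @param x an `abundance_matrix`.
#' @param proteins,samples row / column selectors (indices or names).
#' @return the subsetted `abundance_matrix`.
#' @export
subset_abundance <- function(x, proteins = NULL, samples = NULL) {
  if (is.null(proteins)) proteins <- seq_len(nrow(x$log2))
  if (is.null(samples)) samples <- seq_len(ncol(x$log2))
  if (is.character(proteins)) proteins <- match(proteins, x$protein_ids)
  abundance_matrix(
    x$log2[proteins, samples, drop = FALSE],
    x$mask[proteins, samples, drop = FALSE],
    gene_symbols = if (!is.null(x$gene_symbols)) x$gene_symbols[proteins],
    linear_values = x$linear[proteins, samples, drop = FALSE]
  )
}

#' Read a wide TSV abundance table
#'
#' Expects a header row of sample identifiers, a first column of protein
#' accessions and optionally a `Symbol` column of gene symbols.  Blank
#' cells and zeros are treated as missing, following the MaxQuant
#' convention that zero LFQ intensity means non-detection.
#'
#' @param path TSV file path.
#' @param log_transform if `TRUE` (default) values are log2-transformed;
#'   set `FALSE` when the table already holds log2 values.
#' @return an [abundance_matrix()].
#' @export
read_abundance <- function(path, log_transform = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("abundance table needs an accession column and at least one sample")
  acc <- df[[1]]
  if (anyDuplicated(acc))
    stop("duplicate accessions: ", paste(unique(acc[duplicated(acc)]), collapse = ", "))
  symcol <- which(tolower(names(df)) %in% c("symbol", "gene", "gene_symbol"))[1]
  symbols <- if (!is.na(symcol)) df[[symcol]] else NULL
  valcols <- setdiff(seq_along(df)[-1], symcol)
  vals <- df[, valcols, drop = FALSE]
  num <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(acc, names(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- trimws(vals[[j]])
    blank <- v == "" | is.na(v)
    x <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(x))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d (%s), column '%s': '%s'",
                   bad[1], acc[bad[1]], names(vals)[j], v[bad[1]]))
    x[blank] <- NA_real_
    num[, j] <- x
  }
  num[num == 0] <- NA_real_     # zero intensity is non-detection
  mask <- is.na(num)
  if (log_transform) {
    if (any(num[!mask] <= 0)) stop("non-positive intensity cannot be log2-transformed")
    lin <- num
    num <- log2(num)
    abundance_matrix(num, mask, gene_symbols = symbols, linear_values = lin)
  } else {
    abundance_matrix(num, mask, gene_symbols = symbols)
  }
}

#' Write an abundance matrix as a wide TSV table
#'
#' Missing cells are written blank.  The inverse of [read_abundance()];
#' a write/read round trip preserves observed values and the mask.
#'
#' @param x an `abundance_matrix`.
#' @param path output TSV path.
#' @param scale write `"linear"` intensities (default, readable with
#'   `log_transform = TRUE`) or `"log2"` values.
#' @export
write_abundance <- function(x, path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  m <- if (scale == "linear") x$linear else x$log2
  out <- format(m, digits = 15, trim = TRUE, scientific = FALSE)
  out[x$mask] <- ""
  df <- data.frame(Accession = x$protein_ids, stringsAsFactors = FALSE)
  if (!is.null(x$gene_symbols)) df$Symbol <- x$gene_symbols
  df <- cbind(df, as.data.frame(out, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `diagnosis` (control/AD), `apoe`
#' (genotype such as "3/3"), `age`, `sex` (M/F), `pmi`, `braak` (0-6) and
#' `cerad`.  Adds the derived ordinal APOE risk score column
#' `apoe_ordinal` (see [encode_apoe_ordinal()]) and a combined
#' diagnosis-genotype `group` factor.
#'
#' @param path TSV file path.
#' @return a data.frame of per-sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "diagnosis", "apoe", "age", "sex", "pmi", "braak", "cerad")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  validate_sample_meta(df)
}

#' Validate and derive fields of a sample metadata table
#'
#' @param df data.frame with the columns documented in [read_sample_meta()].
#' @return the data.frame with `apoe_ordinal` and `group` columns added.
#' @export
validate_sample_meta <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if (!all(df$diagnosis %in% c("control", "AD")))
    stop("diagnosis must be 'control' or 'AD'")
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(df$braak < 0 | df$braak > 6)) stop("braak stage must lie in [0, 6]")
  df$apoe_ordinal <- vapply(df$apoe, encode_apoe_ordinal, integer(1))
  df$group <- paste(ifelse(df$diagnosis == "control", "control", "AD"),
                    gsub("/", "", df$apoe), sep = "_")
  df
}

#' Ordinal APOE risk score of a genotype
#'
#' Each allele contributes its AD-risk direction: E2 = -1, E3 = 0,
#' E4 = +1; the genotype score is the allele sum, so "4/4" scores 2 and
#' "2/3" scores -1.
#'
#' @param genotype genotype string such as `"3/3"`, `"2/3"`, `"4/4"`.
#' @return integer risk score in -2..2.
#' @examples
#' encode_apoe_ordinal("4/4")  # 2
#' encode_apoe_ordinal("2/3")  # -1
#' @export
encode_apoe_ordinal <- function(genotype) {
  alleles <- strsplit(as.character(genotype), "/", fixed = TRUE)[[1]]
  if (length(alleles) != 2 || !all(alleles %in% c("2", "3", "4")))
    stop("cannot parse APOE genotype '", genotype, "'")
  score <- c(`2` = -1L, `3` = 0L, `4` = 1L)
  sum(score[alleles])
}

#' Read cell-type marker lists from a directory
#'
#' Each `<celltype>.txt` file holds one gene symbol per line.  Symbols are
#' upper-cased to tolerate mixed mouse/human casing in source lists.
#'
#' @param dir directory of marker files.
#' @return named list of character vectors (a `MarkerSets` object).
#' @export
read_marker_sets <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no marker .txt files found in ", dir)
  sets <- lapply(files, function(f) {
    x <- toupper(trimws(readLines(f, warn = FALSE)))
    unique(x[x != ""])
  })
  names(sets) <- sub("\\.txt$", "", basename(files))
  sets
}

#' Write cell-type marker lists to a directory
#'
#' @param markers named list of gene-symbol vectors.
#' @param dir output directory (created if needed).
#' @export
write_marker_sets <- function(markers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in names(markers))
    writeLines(markers[[ct]], file.path(dir, paste0(ct, ".txt")))
  invisible(dir)
}

#' Read a peptide-level quantification table
#'
#' TSV with columns `sequence`, `accession`, `region` (one of MTBR,
#' deltaMTBR, abeta, other) followed by one intensity column per sample;
#' blank or zero cells are missing.
#'
#' @param path TSV file path.
#' @return a `peptide_table` data.frame; intensity columns are numeric
#'   with `NA` for missing.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sequence", "accession", "region")
  if (!all(req %in% names(df)))
    stop("peptide table needs columns: ", paste(req, collapse = ", "))
  valcols <- setdiff(names(df), req)
  for (j in valcols) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    x[!is.na(x) & x == 0] <- NA_real_
    df[[j]] <- x
  }
  class(df) <- c("peptide_table", class(df))
  df
}

peptide_sample_cols <- function(peptides)
  setdiff(names(peptides), c("sequence", "accession", "region"))
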