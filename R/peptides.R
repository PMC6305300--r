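#' Classify a tau peptide by microtubule-binding region membership
#'
#' Locates the peptide in the tau reference sequence and tags it `"MTBR"`
#' when its residue span lies fully inside the (1-based, inclusive)
#' microtubule-binding region, `"deltaMTBR"` when fully outside.  For the
#' canonical 441-residue tau isoform (accession P10636-8) the MTBR spans
#' residues 224-370.
#'
#' @param peptide peptide sequence (must occur exactly once in the
#'   reference).
#' @param reference tau reference protein sequence.
#' @param mtbr_range inclusive residue range of the MTBR (default
#'   `c(224, 370)`).
#' @return `"MTBR"` or `"deltaMTBR"`; an error for absent, repeated, or
#'   boundary-straddling peptides.
#' @export
classify_tau_peptide <- function(peptide, reference,
                                 mtbr_range = c(224, 370)) {
  hits <- gregexpr(peptide, reference, fixed = TRUE)[[1]]
  if (hits[1] == -1) stop("peptide not found in reference: ", peptide)
  if (length(hits) > 1) stop("peptide occurs more than once in reference: ", peptide)
  start <- hits[1]
  end <- start + nchar(peptide) - 1L
  inside <- start >= mtbr_range[1] && end <= mtbr_range[2]
  outside <- end < mtbr_range[1] || start > mtbr_range[2]
  if (inside) return("MTBR")
  if (outside) return("deltaMTBR")
  stop(sprintf("peptide spans the MTBR boundary (residues %d-%d)", start, end))
}

#' Tau MTBR / deltaMTBR abundance ratio
#'
#' Per sample, sums the intensities of peptides inside the
#' microtubule-binding region (MTBR) and of peptides outside it
#' (deltaMTBR) and reports their ratio, the domain-level tau measure that
#' tracks neurofibrillary tangle burden better than total tau.
#'
#' @param peptides a `peptide_table` with `region` tags `MTBR` /
#'   `deltaMTBR` (see [read_peptide_table()] or
#'   [generate_peptide_fixture()]).
#' @return data.frame per sample: `mtbr`, `delta_mtbr`, `ratio`.
#' @export
tau_mtbr_ratio <- function(peptides) {
  sc <- peptide_sample_cols(peptides)
  mt <- peptides$region == "MTBR"
  dm <- peptides$region == "deltaMTBR"
  if (!any(mt) || !any(dm)) stop("need at least one MTBR and one deltaMTBR peptide")
  mtbr <- colSums(as.matrix(peptides[mt, sc, drop = FALSE]), na.rm = TRUE)
  delta <- colSums(as.matrix(peptides[dm, sc, drop = FALSE]), na.rm = TRUE)
  if (any(delta == 0))
    stop("zero deltaMTBR intensity in sample(s): ",
         paste(sc[delta == 0], collapse = ", "))
  data.frame(sample_id = sc, mtbr = mtbr, delta_mtbr = delta,
             ratio = mtbr / delta, row.names = NULL)
}

#' Two-peptide amyloid-beta LFQ intensity
#'
#' Amyloid-beta abundance per sample is the sum of the MS1 intensities of
#' the peptides HDSGYEVHHQK and LVFFAEDVGSNK, multiplied by the ratio of
#' APP LFQ intensity to APP summed intensity.  Missing cells of either
#' peptide are first imputed as the lowest non-missing value of that
#' peptide within the sample's case-status group (control / AD).
#'
#' @param peptides a `peptide_table` containing the two target peptides.
#' @param app_lfq named per-sample APP LFQ intensity.
#' @param app_summed named per-sample APP summed intensity (> 0).
#' @param case_status named per-sample case status ("control"/"AD").
#' @return data.frame per sample: `abeta`, `imputed` (any cell imputed).
#' @export
abeta_lfq <- function(peptides, app_lfq, app_summed, case_status) {
  targets <- c("HDSGYEVHHQK", "LVFFAEDVGSNK")
  rows <- match(targets, peptides$sequence)
  if (anyNA(rows)) stop("peptide table lacks target peptide(s): ",
                        paste(targets[is.na(rows)], collapse = ", "))
  sc <- peptide_sample_cols(peptides)
  app_lfq <- app_lfq[sc]; app_summed <- app_summed[sc]
  case_status <- case_status[sc]
  if (any(is.na(app_summed)) || any(app_summed == 0))
    stop("APP summed intensity must be nonzero for every sample")
  m <- as.matrix(peptides[rows, sc, drop = FALSE])
  imputed <- matrix(FALSE, 2, length(sc))
  for (g in unique(case_status)) {
    gi <- which(case_status == g)
    for (p in 1:2) {
      vals <- m[p, gi]
      if (all(is.na(vals)))
        stop(sprintf("peptide %s entirely missing within group %s",
                     targets[p], g))
      miss <- is.na(vals)
      if (any(miss)) {
        m[p, gi[miss]] <- min(vals, na.rm = TRUE)
        imputed[p, gi[miss]] <- TRUE
      }
    }
  }
  data.frame(sample_id = sc,
             abeta = as.numeric(colSums(m) * app_lfq / app_summed),
             imputed = apply(imputed, 2, any), row.names = NULL)
}
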