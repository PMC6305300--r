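#' Synthetic cohort design
#'
#' Parameter bundle describing a synthetic post-mortem brain LFQ cohort
#' with the statistical structure the pipeline assumes: four
#' diagnosis/genotype groups (E3/3 controls; AD E2/3, E3/3 and E4/4),
#' proteins that are noisy convex mixtures of five cell-type signature
#' profiles, planted "homeostatic" marker subsets that move opposite to
#' the bulk cell-type fraction in disease, additive age/sex/PMI covariate
#' effects, planted correlated co-expression blocks on non-marker
#' proteins, and intensity-dependent missingness.
#'
#' Default group sizes are 10 controls and 8 AD cases per genotype.  Cell
#' fractions are drawn from a Dirichlet centred on a neuron-dominant
#' brain composition; AD E3/3 and E4/4 receive an astrocyte/microglia/
#' endothelia increase at neuronal expense while AD E2/3 is left at
#' control composition, emulating E2 protection.  Disease effect sizes
#' are free parameters of the generator, not estimates of any cohort.
#'
#' @param n_samples_per_group integer vector, one count per group.
#' @param groups ordered group labels.
#' @param n_proteins total protein count.
#' @param celltypes cell-type names (defines `n_celltypes`).
#' @param markers_per_type markers planted per cell type.
#' @param base_fracs expected cell-type composition (sums to 1).
#' @param frac_shift groups x celltypes matrix of additive shifts applied
#'   to the true fractions before renormalization.
#' @param homeostatic_frac fraction of each type's markers planted to
#'   move opposite to the bulk fraction.
#' @param covariate_effects named log2 slopes for `age` (per year),
#'   `sex` (M vs F) and `pmi` (per hour).
#' @param module_plan list of `c(size, cor)` pairs for planted
#'   co-expression blocks on non-marker proteins.
#' @param noise_sd residual log2 SD.
#' @param missing_rate,mnar_strength missingness controls (see
#'   [apply_missingness()]).
#' @param fraction_model `"lognormal"` (default): per-sample fractions
#'   are the shifted composition times i.i.d. log-normal noise,
#'   renormalized, keeping log-scale composition noise homoskedastic
#'   across groups (matching the log2-based downstream statistics);
#'   `"dirichlet"`: classical Dirichlet draws with additive shifts
#'   applied afterwards.
#' @param fraction_cv coefficient of variation of the per-sample
#'   composition noise (log-normal model).
#' @param dirichlet_conc Dirichlet concentration (Dirichlet model).
#' @param seed RNG seed.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_samples_per_group = c(10, 8, 8, 8),
                          groups = c("control_33", "AD_23", "AD_33", "AD_44"),
                          n_proteins = 3000,
                          celltypes = c("neuron", "astrocyte", "microglia",
                                        "oligodendrocyte", "endothelia"),
                          markers_per_type = 40,
                          base_fracs = c(0.40, 0.25, 0.10, 0.20, 0.05),
                          frac_shift = NULL,
                          homeostatic_frac = 0.3,
                          covariate_effects = c(age = 0.005, sex = 0.1,
                                                pmi = 0.005),
                          module_plan = list(c(60, 0.80), c(50, 0.75),
                                             c(40, 0.70), c(30, 0.85),
                                             c(30, 0.65)),
                          noise_sd = 0.2,
                          missing_rate = 0.1, mnar_strength = 1,
                          fraction_model = c("lognormal", "dirichlet"),
                          fraction_cv = 0.1,
                          dirichlet_conc = 150, seed = 1) {
  fraction_model <- match.arg(fraction_model)
  if (length(n_samples_per_group) != length(groups))
    stop("n_samples_per_group must have one entry per group")
  if (any(n_samples_per_group < 2)) stop("every group needs at least 2 samples")
  base_fracs <- base_fracs / sum(base_fracs)
  if (length(base_fracs) != length(celltypes))
    stop("base_fracs must have one entry per cell type")
  if (is.null(frac_shift)) {
    frac_shift <- matrix(0, length(groups), length(celltypes),
                         dimnames = list(groups, celltypes))
    ad <- intersect(c("AD_33", "AD_44"), groups)
    if (length(ad)) {
      shift <- c(neuron = -0.20, astrocyte = 0.15, microglia = 0.06,
                 oligodendrocyte = 0.05, endothelia = 0.03)
      use <- intersect(names(shift), celltypes)
      frac_shift[ad, use] <- matrix(shift[use], length(ad), length(use),
                                    byrow = TRUE)
    }
  }
  frac_shift <- as.matrix(frac_shift)
  dimnames(frac_shift) <- list(groups, celltypes)
  sizes <- vapply(module_plan, `[`, numeric(1), 1)
  if (length(module_plan) && any(sizes < 12))
    stop("planted modules must satisfy the downstream minimum module size (12)")
  n_marker <- markers_per_type * length(celltypes)
  if (n_marker + sum(sizes) > n_proteins)
    stop("markers plus planted modules exceed n_proteins")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(list(
    n_samples_per_group = n_samples_per_group, groups = groups,
    n_proteins = n_proteins, celltypes = celltypes,
    markers_per_type = markers_per_type, base_fracs = base_fracs,
    frac_shift = frac_shift, homeostatic_frac = homeostatic_frac,
    covariate_effects = covariate_effects, module_plan = module_plan,
    noise_sd = noise_sd, missing_rate = missing_rate,
    mnar_strength = mnar_strength, fraction_model = fraction_model,
    fraction_cv = fraction_cv, dirichlet_conc = dirichlet_conc,
    seed = seed), class = "cohort_design")
}

marker_prefixes <- function(celltypes) {
  pre <- toupper(substr(celltypes, 1, 3))
  if (anyDuplicated(pre)) pre <- toupper(substr(celltypes, 1, 5))
  pre
}

#' Generate a synthetic cohort
#'
#' Realizes a [cohort_design()] into an abundance matrix, sample
#' metadata, marker sets, and a ground-truth record used only by tests.
#' Linear-scale abundance of a marker of cell type `j` in sample `i` is
#' `fraction_ij * signature_p * 2^(covariate effects + noise)`;
#' homeostatic-planted markers substitute the geometrically mirrored
#' fraction `f0_j^2 / fraction_ij` around the control composition
#' `f0_j`, so they decrease when the bulk fraction increases.  Planted
#' co-expression blocks overlay shared latent factors on non-marker
#' proteins at the requested within-block correlation.  Deterministic for
#' a fixed seed.
#'
#' @param design a [cohort_design()].
#' @return a `synthetic_cohort` list: `abundance` ([abundance_matrix()]),
#'   `meta` (data.frame), `markers` (named list), `truth` (list with
#'   `true_fractions`, `true_modules`, `homeostatic_markers`,
#'   `disease_markers`, `full_log2`).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  ct <- design$celltypes
  n_ct <- length(ct)
  n <- sum(design$n_samples_per_group)

  ## --- metadata -------------------------------------------------------
  group <- rep(design$groups, design$n_samples_per_group)
  apoe <- vapply(strsplit(group, "_"), function(g)
    paste(strsplit(g[2], "")[[1]], collapse = "/"), character(1))
  diagnosis <- ifelse(startsWith(group, "control"), "control", "AD")
  braak <- integer(n)
  braak[diagnosis == "control"] <- sample(0:2, sum(diagnosis == "control"), TRUE)
  braak[group == "AD_23"] <- sample(4:5, sum(group == "AD_23"), TRUE)
  braak[diagnosis == "AD" & group != "AD_23"] <-
    sample(5:6, sum(diagnosis == "AD" & group != "AD_23"), TRUE)
  cerad <- ifelse(diagnosis == "control", sample(0:1, n, TRUE),
                  sample(2:3, n, TRUE))
  meta <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    diagnosis = diagnosis, apoe = apoe,
    age = round(stats::runif(n, 60, 90), 1),
    sex = sample(c("M", "F"), n, TRUE),
    pmi = round(stats::runif(n, 2, 24), 1),
    braak = braak, cerad = cerad,
    stringsAsFactors = FALSE)
  meta <- validate_sample_meta(meta)

  ## --- true cell fractions -------------------------------------------
  if (design$fraction_model == "lognormal") {
    centre <- matrix(design$base_fracs, n, n_ct, byrow = TRUE) +
      design$frac_shift[group, , drop = FALSE]
    centre <- pmax(centre, 0.005)
    sdlog <- sqrt(log(1 + design$fraction_cv^2))
    fr <- centre * matrix(stats::rlnorm(n * n_ct, -sdlog^2 / 2, sdlog), n, n_ct)
  } else {
    alpha <- design$dirichlet_conc * design$base_fracs
    g <- matrix(stats::rgamma(n * n_ct, shape = rep(alpha, each = n)), n, n_ct)
    fr <- g / rowSums(g)
    fr <- fr + design$frac_shift[group, , drop = FALSE]
    fr <- pmax(fr, 0.005)
  }
  fr <- fr / rowSums(fr)
  dimnames(fr) <- list(meta$sample_id, ct)

  ## --- covariate term -------------------------------------------------
  ce <- design$covariate_effects
  cov_term <- ce[["age"]] * (meta$age - mean(meta$age)) +
    ce[["sex"]] * (meta$sex == "M") +
    ce[["pmi"]] * (meta$pmi - mean(meta$pmi))

  ## --- protein layout -------------------------------------------------
  n_marker <- design$markers_per_type * n_ct
  sizes <- vapply(design$module_plan, `[`, numeric(1), 1)
  cors <- vapply(design$module_plan, `[`, numeric(1), 2)
  n_module <- sum(sizes)
  n_noise <- design$n_proteins - n_marker - n_module
  protein_ids <- sprintf("P%05d", seq_len(design$n_proteins))
  pre <- marker_prefixes(ct)
  symbols <- character(design$n_proteins)
  log2mat <- matrix(NA_real_, design$n_proteins, n,
                    dimnames = list(protein_ids, meta$sample_id))

  markers <- list()
  homeo <- list(); disease <- list()
  f0 <- design$base_fracs
  names(f0) <- ct
  row <- 0L
  for (j in seq_len(n_ct)) {
    syms <- sprintf("%s%d", pre[j], seq_len(design$markers_per_type))
    markers[[ct[j]]] <- syms
    n_h <- round(design$homeostatic_frac * design$markers_per_type)
    is_homeo <- seq_len(design$markers_per_type) <= n_h
    homeo[[ct[j]]] <- syms[is_homeo]
    disease[[ct[j]]] <- syms[!is_homeo]
    f_dis <- fr[, j]
    # geometric mirror around the control composition: homeostatic markers
    # move opposite to the bulk fraction by the same log-scale excess
    f_hom <- pmin(f0[j]^2 / f_dis, 3 * f0[j])
    for (p in seq_len(design$markers_per_type)) {
      row <- row + 1L
      symbols[row] <- syms[p]
      # signature scaled so marker abundance (fraction x signature) sits on
      # the same log2 intensity scale as the rest of the proteome
      sig <- 2^stats::rnorm(1, 23 - log2(f0[j]), 1.2)
      f_eff <- if (is_homeo[p]) f_hom else f_dis
      lam <- stats::rnorm(1, 1, 0.25)
      log2mat[row, ] <- log2(f_eff * sig) + lam * cov_term +
        stats::rnorm(n, 0, design$noise_sd)
    }
  }

  # Planted blocks realize the requested within-correlation: the latent
  # factor is standardized to exact unit sample variance and successive
  # block factors are orthogonalized (planted modules are independent by
  # construction); per-protein residuals are orthogonalized against the
  # factor, so the sample correlation of a pair is the requested value up
  # to O(1/n) residual cross-terms.
  true_modules <- character(0)
  sigma_mod <- 0.4
  zs <- NULL
  orthonorm <- function(v, basis) {
    if (!is.null(basis))   # basis columns are mutually orthogonal
      v <- v - basis %*% (crossprod(basis, v) / colSums(basis^2))
    as.numeric(scale(v))
  }
  b <- 0L
  for (k in seq_along(sizes)) {
    b <- b + 1L
    z <- orthonorm(stats::rnorm(n), zs)
    zs <- cbind(zs, z)
    for (p in seq_len(sizes[k])) {
      row <- row + 1L
      symbols[row] <- sprintf("GENE%05d", row)
      mu <- stats::rnorm(1, 23, 1.5)
      lam <- stats::rnorm(1, 1, 0.25)
      eps <- orthonorm(stats::rnorm(n), cbind(z))
      log2mat[row, ] <- mu + sigma_mod *
        (sqrt(cors[k]) * z + sqrt(1 - cors[k]) * eps) + lam * cov_term
      true_modules[protein_ids[row]] <- paste0("block", b)
    }
  }

  if (n_noise > 0) for (p in seq_len(n_noise)) {
    row <- row + 1L
    symbols[row] <- sprintf("GENE%05d", row)
    mu <- stats::rnorm(1, 23, 1.5)
    lam <- stats::rnorm(1, 1, 0.25)
    log2mat[row, ] <- mu + lam * cov_term + stats::rnorm(n, 0, design$noise_sd)
  }

  abund <- abundance_matrix(log2mat, gene_symbols = symbols)
  full_log2 <- abund$log2
  if (design$missing_rate > 0) {
    abund <- apply_missingness(abund, design$missing_rate,
                               design$mnar_strength,
                               seed = design$seed + 1L)
  }
  structure(list(
    abundance = abund, meta = meta, markers = markers,
    truth = list(true_fractions = fr, true_modules = true_modules,
                 homeostatic_markers = homeo, disease_markers = disease,
                 full_log2 = full_log2)),
    class = "synthetic_cohort")
}

#' Apply intensity-dependent missingness
#'
#' Masks cells with probability following a logistic function of the
#' rank-standardized log2 intensity with slope `-mnar_strength`
#' (low-abundance cells go missing more often), with the intercept
#' calibrated so the marginal missing fraction approximates
#' `missing_rate`.  `mnar_strength = 0` gives missingness independent of
#' intensity.  Masked cells are set to `NA`; the pre-masking values are
#' attached as attribute `"masked_values"`.
#'
#' @param abundance an [abundance_matrix()].
#' @param missing_rate target marginal missing fraction in \[0, 1).
#' @param mnar_strength intensity dependence of missingness (>= 0).
#' @param seed RNG seed.
#' @return the masked `abundance_matrix`.
#' @export
apply_missingness <- function(abundance, missing_rate, mnar_strength = 1,
                              seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (missing_rate == 0) return(abundance)
  set.seed(seed)
  x <- abundance$log2
  z <- stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
  if (mnar_strength == 0) {
    p <- rep(missing_rate, length(x))
  } else {
    f <- function(a) mean(stats::plogis(a - mnar_strength * z)) - missing_rate
    a <- stats::uniroot(f, c(-50, 50))$root
    p <- stats::plogis(a - mnar_strength * z)
  }
  new_miss <- matrix(stats::runif(length(x)) < p, nrow(x), ncol(x))
  mask <- abundance$mask | new_miss
  masked_values <- x
  x[mask] <- NA_real_
  lin <- abundance$linear
  lin[mask] <- NA_real_
  out <- abundance_matrix(x, mask, gene_symbols = abundance$gene_symbols,
                          linear_values = lin)
  attr(out, "masked_values") <- masked_values
  out
}

#' Generate a synthetic peptide-level fixture
#'
#' Emits a small peptide table for the tau/amyloid-beta quantification
#' stage: two tryptic peptides inside the tau microtubule-binding region
#' (residues 224-370 of a synthetic 441-residue reference sequence), two
#' outside it, the two amyloid-beta peptides HDSGYEVHHQK and
#' LVFFAEDVGSNK with some planted missing cells, and per-sample APP LFQ
#' and summed intensities.  The tau reference is a random sequence (not
#' the biological tau sequence) carrying the fixture peptides at known
#' coordinates.
#'
#' @param n_samples number of samples (>= 1).
#' @param seed RNG seed.
#' @param n_missing_abeta count of amyloid-beta cells planted missing.
#' @return a `peptide_fixture` list: `peptides` (a `peptide_table`),
#'   `tau_reference` (synthetic 441-residue sequence), `tau_positions`
#'   (named start positions), `app_lfq`, `app_summed`, `case_status`.
#' @export
generate_peptide_fixture <- function(n_samples, seed = 1,
                                     n_missing_abeta = 2) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")
  ref <- sample(aa, 441, TRUE)
  tau_pep <- list(mtbr1 = 230, mtbr2 = 300, nterm = 10, cterm = 400)
  seqs <- character(0)
  for (nm in names(tau_pep)) {
    start <- tau_pep[[nm]]
    ref[start + 11] <- "K"            # tryptic-like terminus
    seqs[nm] <- paste(ref[start:(start + 11)], collapse = "")
  }
  refseq <- paste(ref, collapse = "")
  samples <- sprintf("S%02d", seq_len(n_samples))
  intens <- function(mu) round(2^stats::rnorm(n_samples, mu, 0.4))
  tab <- data.frame(
    sequence = c(seqs[["mtbr1"]], seqs[["mtbr2"]], seqs[["nterm"]],
                 seqs[["cterm"]], "HDSGYEVHHQK", "LVFFAEDVGSNK"),
    accession = c(rep("TAU_SYN", 4), "APP_SYN", "APP_SYN"),
    region = c("MTBR", "MTBR", "deltaMTBR", "deltaMTBR", "abeta", "abeta"),
    stringsAsFactors = FALSE)
  vals <- rbind(intens(24), intens(23.5), intens(24.2), intens(23.8),
                intens(22), intens(22.5))
  colnames(vals) <- samples
  if (n_missing_abeta > 0 && n_samples >= 2) {
    cells <- cbind(sample(5:6, n_missing_abeta, TRUE),
                   sample(seq_len(n_samples), n_missing_abeta, TRUE))
    vals[cells] <- NA_real_
  }
  tab <- cbind(tab, as.data.frame(vals))
  class(tab) <- c("peptide_table", class(tab))
  structure(list(
    peptides = tab, tau_reference = refseq,
    tau_positions = vapply(tau_pep, identity, numeric(1)),
    app_lfq = stats::setNames(intens(25), samples),
    app_summed = stats::setNames(intens(26), samples),
    case_status = stats::setNames(
      rep(c("control", "AD"), length.out = n_samples), samples)),
    class = "peptide_fixture")
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Produces the wide abundance TSV, metadata TSV, one marker file per
#' cell type, and the ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(cohort$abundance, file.path(dir, "abundance.tsv"))
  utils::write.table(
    cohort$meta[, c("sample_id", "diagnosis", "apoe", "age", "sex", "pmi",
                    "braak", "cerad")],
    file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_marker_sets(cohort$markers, file.path(dir, "markers"))
  truth <- cohort$truth
  truth$full_log2 <- NULL
  truth$true_fractions <- as.data.frame(truth$true_fractions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
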