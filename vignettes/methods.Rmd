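---
title: "Methods: APOE proteomic network and cell-type pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APOE proteomic network and cell-type pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`apoenet` implements a systems-level proteomic analysis of *APOE*
genotype effects in post-mortem Alzheimer's disease (AD) brain: LFQ
preprocessing, signed weighted protein co-expression networking,
marker-based cell-type deconvolution, and a direction-split analysis of
"homeostatic" versus "disease-associated" cell-type marker groups. This
vignette is the package's account of the statistical model behind each
stage, the parameters that matter, the synthetic data used for
validation, and the numerical and design choices made where the design
was genuinely open.

## Study design and data model

The intended input is a proteins × samples matrix of raw LFQ intensities
from a cohort of roughly 30–40 dorsolateral prefrontal cortex samples in
four diagnosis/genotype groups — E3/3 controls and AD cases carrying
E2/3, E3/3 or E4/4 — together with per-sample metadata: diagnosis, APOE
genotype, age at death (years), sex, post-mortem interval (hours), Braak
stage (0–6 ordinal tangle spread) and CERAD score (ordinal plaque
burden). Intensities are analysed on the log2 scale; zeros and blanks
are treated as non-detection (the MaxQuant convention), and the missing
mask is carried explicitly. Linear-scale intensities are retained
alongside because deconvolution operates on unlogged, unregressed data.

APOE genotype is additionally encoded as an ordinal AD-risk score
summing per-allele contributions E2 = −1, E3 = 0, E4 = +1, so 4/4 ↦ 2,
3/3 ↦ 0 and 2/3 ↦ −1. This makes "risk direction" a single numeric trait
that module eigenproteins and cell fractions can be correlated with.

## Preprocessing

**Missing-value filter.** A protein is kept when it is quantified in
more than half of the samples, i.e. its missing count is strictly less
than `max_missing_fraction` (default 0.5) times the sample count. In a
34-sample cohort this keeps proteins with up to 16 missing values and
removes those with 17 or more.

**Downshift imputation.** Data-dependent acquisition censors
low-abundance proteins, so missing values are drawn from a narrow
Gaussian shifted into the low-intensity tail: with *m* and *s* the mean
and SD of **all** observed log2 values, missing cells draw from
N(*m* − `shift`·*s*, (`width`·*s*)²), defaults `shift = 1.8` and
`width = 0.3` SD units. The whole-matrix variant is the default; a
per-sample-column variant (`per_sample = TRUE`) is available, since both
conventions are in circulation. Observed cells are never altered, and
the draw is seeded. Degenerate input (zero SD of observed values) is an
error rather than a silent fill.

**Connectivity-based outlier removal.** Sample connectivity is
*k*ᵢ = Σ_{j≠i}(1 + cor᎐ᵢⱼ)/2 with biweight midcorrelation (bicor) between
sample profiles — the same robust correlation the network uses; Pearson
is available by option. Samples with connectivity Z-score below
−`z_threshold` (default 3) are removed and the procedure iterates to a
fixed point, with a hard cap of 10 iterations to guarantee termination.
Removal is idempotent, and under i.i.d. null cohorts the Z < −3 rule
fires rarely; both properties are exercised in the tests.

**Covariate regression.** Per protein, the model
`log2 ~ group + age + sex + PMI` is fitted with the diagnosis/genotype
group as a protected categorical effect. Only the covariate component is
subtracted; group effects pass through untouched. Covariate coefficients
are averaged over `n_bootstrap` (default 100) resamples drawn with
replacement *within* each protected group — stratification keeps groups
of 6–10 samples from emptying — and covariates are mean-centred so the
removed component is mean-zero per protein. With `n_bootstrap = 1` and
resampling disabled the result is the exact OLS partial residual: the
group-effect-free component is then exactly orthogonal to every removed
covariate. The resample count and the use of the mean (rather than
median) across resamples are free choices; both are configurable.

**PCA verification.** After regression, the absolute Spearman
correlation of the top five principal-component sample scores with each
removed covariate is reported with a configurable pass threshold.  Two
caveats are deliberate: rank correlations have a sampling floor of order
1/√n even when the linear component is exactly zero, so a strict
threshold like 0.02 is only meaningful for cohorts of hundreds of
samples; and the retained group component can track a covariate through
chance group–covariate imbalance, which is a property of the design, not
a regression failure. The package's own validation therefore measures
covariate removal on a large group-null synthetic cohort (60 samples per
group) and asserts group-effect preservation separately on a cohort with
planted group effects.

## Signed co-expression network

**bicor.** For a vector *x*, *u*ᵢ = (xᵢ − med(x))/(9·MAD(x)) with the raw
(unscaled) median absolute deviation, weights (1 − uᵢ²)² for |uᵢ| < 1 and
zero otherwise; the correlation is the normalized inner product of the
weighted, median-centred vectors. When MAD = 0 the weights are undefined
and the implementation falls back to Pearson for that vector, which
keeps perfectly collinear inputs at ±1. Module–trait and
fraction–trait p-values use the Student-t approximation with n − 2
degrees of freedom.

**Adjacency and TOM.** The signed soft-threshold adjacency is
((1 + cor)/2)^β with β = 8: anti-correlated pairs map near zero rather
than being folded onto positive values, and the power suppresses weak
edges while keeping the matrix differentiable in the correlation.
Topological overlap replaces raw adjacency with neighbourhood
agreement, TOMᵢⱼ = (Σ_{u≠i,j} aᵢᵤaᵤⱼ + aᵢⱼ)/(min(kᵢ,kⱼ) + 1 − aᵢⱼ),
which denoises sparse single-edge similarity. Both matrices are
symmetric with unit diagonal and entries in [0, 1]; the implementation
is checked against a brute-force triple loop.

**Dynamic hybrid tree cut.** Proteins are clustered by average-linkage
on 1 − TOM. The branch decomposition declares a dendrogram branch a
module when three conditions hold:

1. **size** ≥ `min_module_size` (default 12);
2. **core scatter** — the mean of the branch's lowest merge heights
   (over a core of `min_module_size + √(size − min_module_size)`
   merges) — is small relative to the tree's height range, below the
   `deep_split` preset;
3. **gap** — the branch's top merge height sits below the height at
   which its lineage first joins another branch of substantial size
   (≥ `min_module_size`), by at least the `deep_split` preset.

`deep_split` 0–4 maps to core-scatter limits 0.64/0.73/0.82/0.91/0.95
(fractions of the height range above the 5th-percentile reference
height) with gap requirement 0.75·(1 − limit). Two numerical choices
deserve note. The *gap* is measured on the raw 1 − TOM scale, which is
already normalized to [0, 1]: in structureless data all merge heights
concentrate near the top of the tree, no branch separates from its
surroundings by a material dissimilarity margin, and (nearly) everything
stays grey — the intended null behaviour. And the attachment height
skips stray attachments of single proteins or tiny twigs, because a
handful of borderline members joining a branch should not mask its
separation from the rest of the network. Nested qualifying branches are
resolved in favour of the deepest ones, which is what makes larger
`deep_split` produce finer modules.

Leftover proteins are assigned by an optional PAM stage to the nearest
module by average dissimilarity, restricted to modules inside the
protein's own dendrogram component below the cut height (cut height =
5th percentile + 0.99 of the height range). Proteins in no module are
labelled grey. This re-implementation is validated by planted-module
recovery (adjusted Rand index against ground truth) and by the grey
fraction on pure-noise matrices, not by label-for-label agreement with
any particular reference implementation, whose undocumented heuristics
are out of scope.

**Eigenproteins, merging, kME.** A module eigenprotein is the first
principal component of the member submatrix after per-protein
standardization, scaled to unit SD and sign-aligned so it correlates
positively with the members' average profile (the sign of an SVD is
otherwise arbitrary). Modules whose eigenproteins differ by less than
`merge_cut_height = 0.07` in correlation dissimilarity are merged
iteratively, closest pair first, with eigenproteins recomputed after
every merge. Modules are then named M1, M2, … by decreasing size. kME is
the Pearson correlation of each protein with each eigenprotein; after
merging, a member whose kME to a foreign module exceeds its own-module
kME, with the foreign kME significant at `reassign_p = 0.05`, is
reassigned. This reassignment rule is an explicit approximation of the
reference blockwise procedure's internal threshold, which is not
documented in enough detail to reproduce exactly.

## Differential abundance

Per protein, one-way ANOVA across the four groups and Tukey pairwise
p-values from the studentized range with pooled within-group variance;
unbalanced groups use the Tukey–Kramer standard error. The
implementation is vectorized over proteins and agrees with
`aov`/`TukeyHSD` per protein and, for two groups, with the pooled
t-test through the q = t·√2 identity. Raw p < 0.05 defines
per-protein significance (no across-protein correction, matching how
such protein lists are conventionally reported; BH correction is applied
within the enrichment table, where a whole grid of tests is
interpreted at once). Module-level summaries report, per module and per
comparison against the control group, the fraction of members passing
α and the mean log2 difference of those members, signed AD minus
control. Whether the mean should run over significant members only or
all members was open; significant members only is implemented, since the
fraction already reports how representative they are.

## Cell types

**Exclusive markers.** Marker lists must be pairwise disjoint for the
deconvolution model to identify types. The designated newly-added list
(endothelia, RNA-derived) is culled of any symbol present in the four
protein-derived lists; residual overlap among those four is an error
naming the offending symbols. Symbols are upper-cased on input because
mouse and human symbol casing differs.

**Gene collapse.** Protein isoforms are collapsed to one row per gene
symbol by keeping the row with maximum variance across samples, on
unregressed abundances; variance ties break to the lexicographically
first accession so the collapse is deterministic.

**DSA deconvolution.** With *s*ᵢⱼ the mean linear-scale intensity of
type *j*'s markers in sample *i*, the estimator solves the least-squares
system *S q* = **1** — writing the "fractions sum to one" constraint for
every sample — and sets *f*ᵢⱼ = *s*ᵢⱼ·*q*ⱼ. The LM solution can produce
negative weights; they are clipped to zero and rows renormalized, with
pre-clip values kept as diagnostics. A singular marker-mean matrix
(collinear cell-type profiles) is an error. Deconvolution runs on
unregressed, linear-scale, gene-collapsed data; a heuristic warns when
the input looks log-scaled. In the noise-free closed loop with the
synthetic generator the estimator recovers planted fractions to
numerical precision, which is the designed identifiability check. Note
the estimator is not invariant to rescaling a single gene row (only the
marker-mean enters), but rescaling *all* markers of a type is absorbed
by its scale factor — both properties are tested.

**Group tests and enrichment.** Fraction differences across groups are
tested by the partial F test of the group factor in
`fraction ~ group + age + sex + PMI`. The source description of this
test mixes rank-based and F-based language; the F-based reading is
implemented as the default (it matches the stated use of the F
distribution), and a plain Kruskal–Wallis test without covariates is
available by option. Module × cell-type enrichment uses the one-sided
Fisher exact test (enrichment direction only) over the network's gene
background with BH correction across the entire grid.

## Direction-split phenotypes

Markers of each cell type that changed significantly in AD E3/3 versus
control E3/3 (Tukey p < α in the defining comparison, which isolates the
disease effect on the reference genotype) are split by sign of the log2
difference: increased markers form the disease-associated list, decreased
markers the homeostatic list. Each list is treated as a synthetic module:
its eigenprotein is computed on the **regressed** matrix by the same
routine as network eigenproteins, and compared across all four groups by
ANOVA + Tukey with per-group quartile summaries for plotting. Whether
the defining significance should be the Tukey pairwise p or the
unadjusted ANOVA p was ambiguous; the Tukey pairwise p is used, since
the defining contrast is a specific pair. Markers absent from the
filtered matrix are dropped with a message.

## The synthetic cohort generator

The generator (`cohort_design()` / `generate_cohort()`) emulates the
structure the analysis assumes, with defaults chosen once as the
package's study conditions:

- **Design**: 10 control E3/3 and 8 AD cases per genotype (34 samples);
  ~3,000 proteins; five cell types (neuron-dominant composition
  0.40/0.25/0.10/0.20/0.05 for neuron/astrocyte/microglia/
  oligodendrocyte/endothelia); 40 markers per type.
- **Fractions**: per-sample composition is the group-shifted base
  composition times i.i.d. log-normal noise (10% CV), renormalized to
  the simplex. The log-normal model is the default because it keeps
  composition noise homoskedastic on the log2 scale on which all
  downstream statistics operate; a classical Dirichlet draw (with
  additive shifts applied afterwards) is available via
  `fraction_model = "dirichlet"`, but additive shifts there make
  within-group log-scale variance differ systematically between shifted
  and unshifted groups, which biases pooled-variance pairwise tests on
  eigenproteins — a property of the simulation model, not of the
  pipeline under test.
- **Disease effects**: AD E3/3 and E4/4 receive composition shifts of
  −0.20 (neuron), +0.15 (astrocyte), +0.06 (microglia), +0.05
  (oligodendrocyte), +0.03 (endothelia); AD E2/3 stays at control
  composition, planting the E2 protection pattern. The source cohort
  publishes no effect sizes, so these are free parameters set to
  magnitudes consistent with end-stage AD gliosis and neuronal loss and
  large enough that the planted pattern is statistically identifiable at
  cohort scale; they are not estimates of any real cohort.
- **Markers**: marker abundance is fraction × signature × covariate and
  noise multipliers, with signatures scaled so markers sit on the same
  log2 intensity scale as the rest of the proteome (markers of rare
  types would otherwise land several log2 units low and be preferentially
  censored by intensity-dependent missingness). A configurable fraction
  (default 30%) of each type's markers is planted homeostatic: they
  follow the geometrically mirrored fraction f₀²/f, i.e. an equal and
  opposite log2 excess around the control composition.
- **Modules**: co-expression blocks are planted only on non-marker
  proteins (keeping deconvolution and network tests independent), each
  as a shared latent factor at a requested within-block correlation. The
  factor is standardized to exact unit sample variance, successive
  factors are orthogonalized, and per-protein residuals are
  orthogonalized against the factor, so the realized within-block
  correlation equals the requested one up to O(1/n) cross-terms rather
  than inheriting the sampling variance of the latent draw.
- **Covariates**: age uniform over 60–90 years, sex Bernoulli, PMI
  uniform over 2–24 h, with additive log2 slopes (defaults 0.005/0.1/
  0.005 per year/M-vs-F/hour) times a per-protein sensitivity drawn
  around 1 — matching the linear model the regression stage fits.
- **Missingness**: each cell is masked with probability following a
  logistic function of its rank-standardized log2 intensity with slope
  −`mnar_strength`, calibrated by root-finding so the marginal missing
  fraction hits `missing_rate` (default 0.10); `mnar_strength = 0` gives
  intensity-independent missingness.

What the generator does **not** emulate: peptide-to-protein roll-up,
batch structure or acquisition drift, heavy-tailed technical outliers,
shared-peptide ambiguity between isoforms, correlated marker expression
within a cell type beyond the shared fraction, or realistic biological
covariance between cell types. Passing tests on this generator therefore
show the pipeline recovers the structure it models — planted modules,
planted fractions, planted covariate and group effects — not that real
cohorts satisfy those modelling assumptions.

Validation experiments choose their own design points: module recovery
runs at 40 samples with five blocks spanning within-correlation 0.6–0.9
and no missingness; the deconvolution closed loop uses noise-free,
homeostatic-free mixtures (exactness) and 5% multiplicative noise
(stability); covariate-removal checks use 240-sample group-null cohorts
(the rank-correlation floor at 34 samples would swamp the threshold);
and the E2/3 protection pattern runs on a complete-case cohort of the
default size, evaluated on the microglia direction-split eigenproteins,
since partial marker selection under heavy imputation adds a selection
bias that is a property of small-cohort marker selection rather than of
the phenotype-stage logic under test. Problem sizes throughout are
chosen to make each property measurable in seconds to a few minutes.

## Peptide-level tau and amyloid-β

Tau peptides are located by exact substring match in a caller-supplied
tau reference sequence and classified MTBR if the matched span lies
fully inside the inclusive 1-based microtubule-binding region (default
residues 224–370 of the 441-residue numbering), ΔMTBR if fully outside;
straddling the boundary, absence, or multiple matches are errors. The
package deliberately ships no hard-coded tau sequence — the reference is
an argument, and the synthetic fixture carries its own synthetic
441-residue sequence with fixture peptides at known coordinates. The
MTBR/ΔMTBR ratio divides the summed member-peptide intensities per
sample; sums use raw reported intensities (whether the source applied
LFQ normalization first is unstated; raw is the default and the choice
is isolated in one function). The amyloid-β measure is
(HDSGYEVHHQK + LVFFAEDVGSNK) × APP LFQ / APP summed intensity, after
imputing missing cells of either peptide as the lowest non-missing value
of that peptide within the sample's case-status group (control/AD — case
status, not genotype, defines the imputation group).

## Orchestration and reproducibility

`run_pipeline()` executes preprocess → (optional peptide quantification)
→ network → differential expression → cell types → phenotypes from one
configuration object, writing every stage output as TSV/JSON plus a
manifest (package version, seed, parameters, parameter hash). All
randomness flows from one global seed through per-stage child seeds
derived by stable hashing of the stage name, so a partial rerun of a
stage reproduces its draws; identical configuration and seed give
byte-identical outputs. `make_report()` collates the run into a markdown
summary and tolerates partial runs. The parameter defaults — filter 0.5,
imputation 1.8/0.3, outlier Z 3, β 8, deep split 4, minimum module size
12, merge height 0.07, α 0.05 — are the pipeline's canonical settings;
any override is recorded in the manifest.

## Known limitations

- The dynamic tree cut is a re-implementation validated by planted-module
  recovery; on real data its module boundaries will differ in detail
  from other implementations of dynamic hybrid cutting.
- DSA assumes exclusive, abundance-proportional markers. Homeostatic
  marker subsets violate proportionality by design; with 30% of markers
  homeostatic the marker means of rare cell types can lose contrast and
  produce negative LM weights, which are clipped with a warning — on
  real data this warrants inspecting the pre-clip diagnostics.
- The bootstrap regression protects group means but, like any
  regression on ~32 samples, cannot remove chance group–covariate
  confounding; the PCA check reports, it does not fix.
- Tukey pairwise tests assume homoskedastic groups; strongly
  heteroskedastic fraction noise (e.g. additive composition shifts on a
  Dirichlet model) inflates specific pairwise error rates.
- Peptide handling covers domain-level summaries only: no PTM
  localization, isoform deconvolution, or spectral processing.
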