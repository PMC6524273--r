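---
title: "Serum miRNA biomarker discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum miRNA biomarker discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seromiR)
```

## The problem

Cell-free miRNAs circulating in blood serum are stable against RNase
degradation and can be assayed from a routine blood draw, which makes them
attractive candidates for non-invasive detection of cancers that are
otherwise diagnosed late — pancreatic cancer (PC) and biliary tract cancer
(BTC) being the canonical examples. A discovery study of this kind profiles
serum small-RNA sequencing counts in cancer patients and healthy controls
(HC), asks which miRNAs are dysregulated after adjusting for clinical
covariates, and then asks the harder question: how well does a small panel
of those miRNAs actually classify new samples?

seromiR implements that full analysis chain on a miRNA-by-sample read-count
matrix: expression filtering, TMM normalization, covariate-adjusted
negative-binomial (NB) likelihood-ratio tests, PCA and silhouette-based
cluster-number estimation, k-nearest-neighbour (KNN) marker ranking with
leave-one-out cross-validation (LOOCV), t-test validation on an independent
expression table, and target-gene set enrichment. Because serum cohorts of
this kind are rarely deposited, the package ships a cohort simulator with
planted ground truth, so every stage is testable end to end.

## Models and procedures

### Expression filter

A miRNA is "expressed" when its raw count strictly exceeds `min_reads`
(default 10, i.e. at least 11 reads) in at least `min_samples` (default 2)
samples. The strict inequality is deliberate; a count of exactly 10 does not
qualify. The filter is applied to raw counts, before normalization, and is
idempotent.

### TMM normalization

Sequencing depth and composition differ between samples, so counts are put
on a common scale with trimmed-mean-of-M-values (TMM) scaling factors. With
count fraction $p_{gi} = y_{gi}/N_i$ for miRNA $g$ in sample $i$, and a
reference sample $r$ chosen as the one whose 75th-percentile count fraction
is closest to the mean across samples, each miRNA contributes

$$M_g = \log_2 \frac{p_{gi}}{p_{gr}}, \qquad
  A_g = \tfrac12\left(\log_2 p_{gi} + \log_2 p_{gr}\right)$$

over the miRNAs nonzero in both samples. The M distribution is trimmed
two-sided by 30% and the A distribution by 5% (the reference method's
settings), and the factor is $2$ raised to the precision-weighted mean of
the surviving M-values, with inverse delta-method binomial variances
$w_g^{-1} = \frac{N_i - y_{gi}}{N_i y_{gi}} + \frac{N_r - y_{gr}}{N_r y_{gr}}$
as weights. Factors are rescaled to geometric mean 1. One caveat worth
stating: because the weights depend on depth, the factors are invariant to
rescaling a single sample's counts only up to roughly $10^{-4}$; the
unweighted trimmed mean is exactly invariant.

Downstream expression is `log2cpm()`:
$\log_2\!\big(y_{gi} \cdot 10^6 / (N_i f_i) + 1\big)$, i.e. log2
counts-per-million on TMM-effective library sizes with pseudocount 1. We use
log2-CPM everywhere because Euclidean distance on raw counts would be
dominated by a handful of high-abundance miRNAs, and the log transform is
the standard variance stabilizer for counts. Zero counts map to exactly
0. Studies in this area rarely state the expression scale fed to PCA and
KNN; this is the package's documented choice.

### Differential expression

Counts for each miRNA are modelled as NB with mean
$\mu_{gi} = \exp(x_i^\top\beta_g + \log N_i f_i)$ and variance
$\mu + \phi\mu^2$. The full design is intercept + two group indicators (HC
is the reference level) + age + gender + BMI; the reduced design drops the
group columns. Age and BMI are centered and scaled to unit variance for
conditioning, gender is coded 0/1 (F/M). Cancer stage is deliberately not a
covariate: per-stage subgroups are far too small at these cohort sizes, so
the cancer groups are modelled as wholes. The likelihood-ratio statistic is
the deviance difference between the two fits, referred to $\chi^2_2$, and
p-values are Benjamini–Hochberg adjusted. Pairwise log2 fold changes (PC vs
HC, BTC vs HC, BTC vs PC) come from the fitted group coefficients, and a
separate descriptive screen (`pairwise_log2fc()`) flags >2-fold differences
of group-mean log2-CPM, which is what heatmap-style figures usually show.

Dispersion is estimated by a deliberately simple, self-contained two-step
scheme rather than a full empirical-Bayes apparatus: a common $\phi$
maximizes the Cox–Reid adjusted profile likelihood summed over miRNAs,
scanned on a 24-point log grid over $\phi \in [10^{-4}, 10^{0.7}]$ and then
refined inside the bracketing interval with a 1-D optimizer (the coarse grid
alone biases $\phi$ low by up to ~10%, which inflates significance); each
miRNA's moment estimate is then shrunk 70% of the way toward the common
value. On 500-miRNA cohorts simulated at $\phi = 0.2$ the common estimate
lands at 0.19–0.21. The estimator is validated by what it must deliver —
type-I error control and power — not by coefficient-level equality with any
particular package.

GLM fitting is iteratively reweighted least squares at relative tolerance
$10^{-8}$, at most 50 iterations. Non-converged fits are flagged and
excluded from the FDR adjustment rather than raising an error; all-constant
miRNAs get a dispersion floor of $10^{-6}$.

### Cluster structure

PCA treats samples as observations and miRNAs as centered, unscaled
variables — all features already share the log2-CPM scale, so variance
scaling would only up-weight noise. The optimal number of clusters is
estimated by cutting an average-linkage hierarchical tree (the linkage is
configurable; the source method said only "hierarchical clustering") on
correlation distances $d = 1 - r$ (Pearson and Spearman) at each
$k \in 2..k_\text{max}$ (default 10) and maximizing the average silhouette
width

$$s(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))},$$

with $a$ the mean intra-cluster distance, $b$ the best mean distance to
another cluster, singletons assigned $s = 0$, and ties resolved toward the
smallest $k$.

A point worth knowing when interpreting the profile: correlation distance
sees *shared per-feature structure*, not mean shifts that are constant
across features. On full-transcriptome profiles where only ~6% of miRNAs
carry a modest group effect, the correlation structure is noise-dominated
and the silhouette profile is flat; the two-cluster (cancer vs control)
structure is cleanly recovered on the differentially expressed subset, which
is also the subset such studies feed to their clustering figures.

### KNN marker evaluation

The classifier is deliberately minimal: Euclidean distance on log2-CPM
(without per-feature z-scoring, configurable), majority vote among the $k =
11$ nearest neighbours. Because 3-class votes with $k = 11$ can tie, the tie
rules are fully specified: distance ties at the k-th position are broken by
stable training order; vote ties by the smallest summed distance to the
query among the tied labels, then label lexicographic order. LOOCV puts
samples in canonical (sample-id) order first, so reports are invariant to
input ordering.

Marker selection ranks every candidate by its individual LOOCV performance,
then evaluates each prefix of the ranking as a cumulative feature set. The
ranking is computed once on the full data set and is *not* re-nested inside
each LOOCV fold — this is how descriptive cumulative-accuracy curves are
constructed in this literature, and it is optimistically biased as an
estimate of generalization error. The bias is the user's to keep in mind; the
individual-marker reports are unaffected.

The number of neighbours is checked by bootstrap: samples are resampled with
replacement, out-of-bag samples form the evaluation set, and per $k$ (odd,
1–21) the mean out-of-bag accuracy and the mean winning-vote proportion are
recorded. The selection rule — smallest $k$ within one bootstrap standard
error of the maximum mean accuracy — is the package's documented
convention; bootstrap-and-vote-proportion plots in the field usually leave
the exact decision rule unstated. Replicates missing a class are discarded
(error if more than half are).

Two-group analysis collapses PC and BTC to "cancer" and HC to "control",
with "cancer" as the positive class for sensitivity.

### Validation t tests

Candidates are re-tested on an independent normalized expression table
(in practice qRT-PCR-derived; Ct-to-expression preprocessing is out of
scope) with a two-sided Welch t test between cancer and control. "Pairwise
t test" in this context means an unpaired two-group comparison — the groups
have different sizes (34 vs 19), so a paired design is impossible; the
Welch variant is the default because group variances are not assumed equal,
and the pooled-variance Student test is available via `var_equal = TRUE`.
No multiplicity correction is applied: each candidate is a pre-specified
hypothesis carried into validation.

### Enrichment

Candidate miRNAs map to target genes through a user-supplied interaction
table (any table with `mirna_id`/`gene_symbol` columns; curated databases
are not bundled). Gene sets are tested by the hypergeometric upper tail on
the 2×2 table of list/set membership within a background universe
(defaulting to the union of the supplied sets), with fold enrichment
$(\text{count}/\text{list size})/(\text{set size}/\text{background size})$
and Bonferroni correction over the tested sets. The EASE variant (overlap
reduced by one, so single-gene overlaps are never significant) is available
because DAVID-style tools use it; published enrichment tables depend on
that service's background and are not reproducible from a table alone.

## The cohort simulator

`simulate_cohort()` emulates the study conditions the pipeline is designed
for: 24 PC / 10 BTC / 21 HC samples, 677 miRNAs of which 42 are planted
with $|\log_2 FC| = 1$, NB counts with dispersion $\phi = 0.2$ (serum
miRNA-seq dispersions are not well characterized; 0.2 is a documented,
config-exposed assumption), heavy-tailed log-normal baseline abundances,
and library sizes uniform on 0.5–2 million reads. 80% of planted miRNAs
carry the identical effect in both cancer groups — this is what makes the
simulated PC and BTC serum profiles nearly indistinguishable, reproducing
the central difficulty such cohorts present. Covariate distributions match
the cohort structure the simulator targets: cancer patients average ~62.8
years vs ~43.9 for controls, male fractions 11/24, 7/10 and 15/21, BMI
means 21.7, 23.2 and 23.8 kg/m².

The age imbalance is **on by default**, so the covariate-adjusted LRT is
exercised against genuine confounding. This is also why the default
conditions are hard: adjusting for a covariate collinear with the group
indicator inflates the group-coefficient variance, and at
$|\log_2 FC| = 1$, $\phi = 0.2$, recall at FDR ≤ 0.05 is ~35–50% — for this
package's estimator and for a reference NB pipeline alike. Parameter
recovery is therefore measured in the `confound = FALSE` mode, which
isolates the pure group signal (recall ≥ 85%, precision ~95% at these
settings); the confounded default is what the calibration and end-to-end
structural tests use. Optionally, `n_outliers` controls with cancer-like
profiles can be planted among the HCs, mirroring the stone-disease controls
that depress two-group accuracy in real data.

What the simulator does *not* emulate: hemolysis and other pre-analytic
artifacts, batch effects, per-miRNA dispersion heterogeneity, sequence-level
biases, or any real miRNA identity (all features are `sim-mir-*`). Passing
tests on this generator therefore demonstrate that the statistical machinery
does what it claims under the declared model — not that any particular
serum panel will validate in patients.

`simulate_qpcr()` generates the validation-cohort analog: Gaussian
expression for a small panel with specified cancer-vs-control shifts at the
34/19 group sizes.

## Numerical choices, in one place

- IRLS tolerance $10^{-8}$, max 50 iterations; non-convergence flags the
  record instead of erroring.
- Dispersion: 24-point log grid $[10^{-4}, 10^{0.7}]$ + bracketed
  `optimize()` refinement; shrinkage weight 0.7 toward the common value;
  floor $10^{-6}$. For matrices above 400 miRNAs the grid scan uses 400
  rows spread across the abundance range (the profile likelihood is
  effectively common to all rows; the final per-miRNA estimates use every
  row).
- log2-CPM pseudocount 1 → zero counts map to 0 and all values are finite.
- Silhouette: singletons get 0; ties in the $k$ profile go to the smallest
  $k$.
- KNN tie-breaks as specified above; `order()`'s stable sort implements the
  training-order rule.
- BH via the standard step-up implementation; inputs outside $[0,1]$ error.
- TMM guards: samples sharing no nonzero miRNA with the reference raise an
  error naming the sample; an all-zero M set returns factor 1.

## Problem sizes

The shipped tests and the acceptance script run at the simulator's own
cohort scale — 677 miRNAs × 55 samples for discovery, 1000 replicates for t-test
calibration, 100-instance brute-force comparisons for the KNN oracle, B =
100–200 bootstrap replicates — sizes chosen so a full run completes in a
few minutes on a single core while keeping every statistical check at the
cohort dimensions it is meant to certify.

## Known limitations

- The non-nested marker ranking overstates cumulative performance; use the
  individual LOOCV reports, or nest the selection yourself, when an honest
  generalization estimate matters.
- The dispersion model is common-plus-shrinkage; strongly heterogeneous
  per-miRNA dispersions will be over-shrunk, and the $\chi^2$ reference for
  the LRT is asymptotic (calibration at n = 55 is verified by simulation,
  at ~5–6% empirical size).
- Correlation-distance clustering cannot detect signals that are constant
  across features, and on noise-dominated full-matrix profiles the
  silhouette profile is uninformative.
- Enrichment results are only as meaningful as the supplied target map and
  background; nothing curated is bundled.
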