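---
title: "Methods: from baseline (phospho)proteomes to drug-response markers"
author: "proteoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from baseline (phospho)proteomes to drug-response markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoscreen)
```

proteoscreen connects two measurements of the same cancer cell-line panel: a
baseline molecular layer (full proteome and phosphoproteome intensity
matrices from search-engine output tables) and a phenotypic layer (viability
screens of the same lines against a drug library). The package implements
the statistical chain in between — normalisation and imputation,
dose-response summarisation, kinase-activity scoring, cell-cycle
deconvolution, and two complementary marker-discovery methods — together
with a synthetic-data generator that plants known structure so that every
stage has a recovery test. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the tests do
and do not demonstrate.

## Intensity preprocessing

Search-engine protein and p-site tables report linear-scale intensities and
use 0 for non-detection, so the readers map both zeros and empty cells to
missing; treating 0 as an observation would corrupt everything downstream.

* **Median-centring.** After log10 transformation, each sample is shifted
  additively so that its median over observed values equals the grand median
  of the dataset. This corrects unequal loading amounts. Centring on the
  log10 scale is equivalent to a multiplicative per-sample correction on the
  linear scale, which is why the transform comes first; the operation is
  idempotent and exact to floating-point precision.
* **Half-minimum imputation.** A missing cell in a feature row is filled
  with half the lowest *linear* intensity observed in that row (i.e.
  `min - log10(2)` on the log10 scale). Halving is a linear-scale notion:
  intensities are linear quantities, and "half the weakest observed signal"
  is the intended conservative guess for a value below detection. Observed
  cells are never altered; rows with no observation are left missing and
  reported rather than invented.

## Dose-response curves and the standardised AUC

Raw well signals are normalised per plate against the vehicle (negative) and
cytotoxic (positive) control means, so 1 means full viability and 0 full
response; values are clipped to [0, 1.2] and capped at 1 before fitting.
Replicates are averaged per dose. The symmetric four-parameter log-logistic
model

$$f(x) = c + \frac{d - c}{1 + \exp\!\big(b(\log x - \log e)\big)}$$

is fitted per (drug, cell line) by bounded Levenberg-Marquardt least squares
(`minpack.lm`). The natural log is used inside the exponent (the base only
rescales the slope `b`; this is documented so slopes are comparable).
Initialisation is `d = max(v)`, `c = min(v)`, `e` at the dose nearest the
half-maximal response, `b = 1`, with bounds `c, d` in `[-0.2, 1.3]` and `e`
within two decades of the tested dose range — these tame the well-known 4PL
identifiability problems with flat or one-sided curves. A response range
below 0.01 is not fitted at all: the curve is flagged non-converged with an
infinite ED50 sentinel, and the AUC falls back to the empirical trapezoid on
the observed points.

The response summary is the standardised area under the fitted curve in
log10-dose space over the tested range, divided by the width of that range,
clipped to [0, 1]: 1 = no response, 0 = full response. The standardisation
makes the value invariant to the dose unit. Quadrature uses adaptive
integration with relative tolerance 1e-8. The maximal relative inhibition is
defined as 1 minus the minimum of the fitted curve over the tested range
(noise-robust, unlike the single lowest observed point). Potency filters
combine EC50 < 0.1 uM, AUC < 0.9 and maximal inhibition > 0.5; the Z-prime
factor `1 - 3(sd+ + sd-)/|mu+ - mu-|` is the plate-quality statistic.

## The four-layer kinase activity landscape

Per kinase and cell line, four evidence layers are computed and each is
standardised per kinase across cell lines (z-score, sample SD convention,
n-1): (a) kinase protein abundance (log10, median-centred); (b) the sum of
linear intensities of the kinase's own p-sites, log10-transformed;
(c) the same restricted to annotated activation-loop sites; (d) the same
over the kinase's annotated substrate sites. Sums treat a missing site as 0
when at least one site is observed in that line — summation on the linear
scale expresses additive evidence — and are missing only when nothing is
observed. Constant rows get z = 0 rather than missing so that layer
availability stays meaningful.

The combined score adds layer (a) and every available phosphorylation
layer. Protein-level quantification is a hard requirement: without layer (a)
no score is produced. We additionally require at least one of (b), (c), (d),
because an abundance-only "activity" score would just restate expression;
abundance-only kinases are listed separately for transparency. Whether
multiple phosphorylation layers should be summed or averaged was genuinely
open; summation is used, matching the additive description of the
combination, with the caveat that kinases with more available layers have
larger score ranges — rankings are within a cell line, where this affects
all kinases alike. Rankings break ties lexicographically for determinism.

## Cell-cycle phase proportions

Five clusters of periodic proteins (proteins whose abundance oscillates over
the cell cycle) act as phase surrogates: per cell line, member intensities
are summed per cluster; each cluster is min-max rescaled across the panel to
remove the bias of clusters with more members; and the five rescaled values
of a line are normalised to proportions summing to 1. A cluster constant
across lines carries no contrast and is set to the uninformative 0.5 before
normalisation. The cluster-to-phase labels (1: G1, 2: S, 3: G2, 4: early M,
5: M) are annotation metadata, not computed. Because the rescaling is across
lines, a uniform multiplicative change of one line's intensities *does*
move its proportions — the estimator assumes loading-normalised input; a
test documents this sensitivity deliberately.

Cluster proportions are then correlated (Pearson) with drug AUC profiles,
restricted to drugs whose minimum AUC across the panel is below 0.8 (drugs
with no real effect would contribute spurious correlations); r < -0.5 flags
a sensitivity association, r > +0.5 the resistance side.

## Sparse multiblock PLS regression (SMBPLSR)

Given predictor blocks $X_1$ (protein) and $X_2$ (p-site) and the response
block $Y$ (AUC values), each component maximises
$\sum_k \mathrm{cov}^2(X_k u_k, Y v)$ over sparse loadings. Sparsity is
implemented in cardinality form — exactly `k_drugs = 6` drugs and
`k_features = 50` features carry nonzero loadings — because the
configuration is stated as exact counts; a hard top-k threshold reproduces
them deterministically, which a penalty weight would not. Columns are
centred, not scaled; covariance uses the n-1 denominator.

Two implementation facts matter. First, with each block loading
L2-normalised on its support, block k contributes
$\|X_k^\top s\|^2_{S_k}/(n-1)^2$ to the objective, so the exact maximiser of
the feature step under a *pooled* cardinality budget is the global top-k of
the concatenated gradient magnitudes $|X_k^\top s|$ — the budget splits
itself across blocks by the data, no allocation heuristic is needed, and
the "50 features" read naturally as one pooled list. Second, the drug-step
update for K > 1 has no closed form; the solver evaluates two candidates —
the hard-thresholded super-score gradient $\sum_k Y^\top t_k$ and a
truncated power step on the induced quadratic form — and keeps the better,
accepting an iterate only if the objective did not decrease. Convergence is
declared when the objective changes by less than `tol = 1e-6`.

The problem is non-convex, so the solver restarts deterministically: from
the leading right singular vector of Y, from every single-drug indicator,
and — when the drug or feature space is small enough to enumerate
(`choose(q, k_drugs)` or `choose(p, k_features)` up to 256) — from the best
rank-1 direction inside every admissible support. On tiny instances this
makes the iterative solution coincide with exhaustive support enumeration
(verified against a brute-force oracle in the tests); on panel-scale
problems the indicator restarts remain and cost little. Deflation is the
standard PLS scheme: each block on its own score, the response block on the
sample-wise sum of block scores. Sign indeterminacy is fixed by making the
largest-magnitude drug loading positive, so a negative feature loading with
a positive drug loading reads as "higher abundance, lower AUC", i.e. a
sensitivity marker. Twelve components are fitted by default.

## Bootstrapped elastic-net marker discovery

Per drug, the elastic net minimises
$\tfrac{1}{2n}\|y - X\beta - \beta_0\|^2 +
\lambda(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2)$
(solved by glmnet; the unpenalised limit is computed exactly as OLS, and the
single-feature case by its closed form). Hyperparameters follow a two-stage
schedule: the penalty strength along the glmnet path at fixed
$\alpha = 0.05$, then the mixing parameter from {0.01, 0.05, 0.1} at that
fixed penalty.

Two design choices required care at panel scale (n = 17 cell lines,
hundreds of features):

* **A global association gate precedes the penalty search.** With a
  near-ridge alpha grid, even a perfect single marker is shrunk so strongly
  at admissible penalties that its cross-validated gain is of the same
  order as CV noise; no pure-CV rule can simultaneously keep a null
  response empty and a genuine marker selected. The gate therefore tests
  the global null of no feature-response association with the omnibus
  statistic $\max_j |\mathrm{cor}(x_j, y)|$ against 20 seeded permutations
  of the response — a sharp separator, since a genuine marker's correlation
  exceeds the best-of-hundreds decoy correlation. When the gate detects
  association the CV-minimising penalty is used; otherwise the conservative
  one-SE penalty, which typically is the near-empty model. This is an
  omnibus-test-then-select design, not stability selection (no per-feature
  error control is claimed).
* **Folds are a seeded 10-fold split** (leave-one-out only when n < 12).
  Leave-one-out folds yield single-observation squared errors whose spread
  badly mis-calibrates one-SE comparisons; grouped fold means behave. The
  mixing parameter stays at 0.05 unless another grid value is better by
  more than one fold-mean SE — switching alpha at a fixed penalty changes
  the effective regularisation, so the switch must be earned.

With tuned hyperparameters, 100 bootstrap resamples of the cell lines (with
replacement, original size) are refitted; the report per feature contains
the mean coefficient over all models — zeros from unselected features
included, so magnitude is comparable across features — and the selection
frequency, the fraction of models with a nonzero coefficient. Volcano-style
plots of frequency against mean coefficient highlight candidates; negative
coefficients against an AUC response mean sensitivity. Degenerate resamples
(constant response) are redrawn up to 10 times.

The companion correlation screen computes Pearson r for every feature-drug
pair over pairwise-complete observations on the *non-imputed* matrix and
keeps pairs with more than eight complete observations (n >= 9; the
boundary is exclusive by definition of the rule). p-values from the
t-transform of r are reported but deliberately not used as a filter.

## Time-course analysis

Reporter matrices are median-normalised per channel (equal channel medians,
multiplicative), methionine-oxidation tokens are stripped from modified
sequences and duplicates summed channel-wise (phospho tokens are preserved),
and every channel is divided by the time-zero channel, so each feature is a
ratio curve equal to 1 at t0 over the grid {0, 5, 10, 15, 30, 90, 180, 360,
720, 1440} minutes. A duplicated t0 bridge channel (shared between
multiplexed batches) is reduced to the single t0 reference after
normalisation. Internal gaps are linearly interpolated on the minute axis
(no extrapolation). Features are ranked by the absolute maximal response
measured on the log2 scale, so 4-fold down and 4-fold up are equally
extreme, and a feature is called regulated when some post-treatment ratio is
strictly below 0.5 or strictly above 2 (the boundary itself does not
qualify); the direction is the sign at the time of maximal response.

## The synthetic study and what the tests show

`generate_panel()` emulates the study conditions at desk scale: 17 cell
lines, 2000 proteins (60 kinases), 4000 p-sites, 30 drugs over a 10-point
1:3 dilution ladder (micromolar, from a 10 mM-scale stock), log-normal
intensities (per-cell log10 noise SD 0.2), 10% missingness, and screen noise
with SD 2% of the negative-control mean — the order of a well-replicated
viability screen. Planted structure drives every downstream recovery test:

* Five (cell line, kinase) pairs get a +0.7 log10 shift of the kinase's
  protein, its p-sites, its activation-loop site and its substrates, and
  drugs targeting an active kinase have their true ED50 divided by 100 in
  that line. The sensitisation exponent scales with the planted molecular
  effect, so a zero effect breaks the causal chain entirely rather than
  attenuating it — the null-generator test relies on this.
* The planted (kinase, line) protein-abundance cells are exempt from the
  missingness mask (5 cells of ~34,000). The activity landscape requires
  protein evidence as a hard gate, so masking the planted cell would void
  the planted pair and the recovery test would measure the mask, not the
  method. All other planted evidence (sites, substrates) stays maskable.
* Each line has a dominant periodic cluster (+0.7 log10 on its members),
  assigned round-robin; one designated drug is sensitive exactly in the
  lines whose dominant cluster is 2, planting the anti-correlation the
  cell-cycle screen must find.
* Marker links overwrite a few non-kinase features with linear functions of
  a drug's true AUC profile (slope sign recorded), and the time-course
  generator plants exponential approaches to a plateau fold change
  (log2 plateau 1.5-3, time constants 20-120 min) in the treated arm only.

One master seed fans out to per-table child seeds, so regenerating one
table does not perturb the others, and everything is byte-identical under a
fixed seed.

What the generator does *not* emulate: peptide-level quantification and
roll-up, TMT reporter interference, batch structure or systematic (non-
uniform) missingness, correlated noise between proteome and phosphoproteome,
and dose-response shapes beyond the symmetric 4PL. Passing recovery tests
therefore demonstrates that the implementations recover the structure they
model under realistic noise — not that the models capture every property of
real acquisitions.

Problem sizes in the test-suite and acceptance runs are the defaults above;
simulation-based checks use 10-50 replicate seeds (50 noisy curve fits for
ED50 recovery, 10 panels for activity recovery, 20 tiny instances for the
SMBPLSR oracle, 10 permutation seeds for the elastic-net null, 10 simulated
time courses), which keeps the whole suite in the tens of seconds on one
CPU.

## Known limitations

* The 4PL fit reports `e` at the bound rather than failing when the true
  ED50 lies far outside the tested dose range; EC50-based filters should be
  read together with the AUC.
* Activity scores compare kinases within a line; the sum over available
  layers makes scores of kinases with different layer availability only
  partially comparable across kinases.
* The elastic-net association gate tests a global null; it does not control
  per-feature error rates, and selection frequencies retain their usual
  bootstrap optimism.
* Cell-cycle proportions are a deconvolution surrogate: they assume the
  panel spans enough phase contrast for min-max rescaling to be meaningful,
  and they inherit loading normalisation from preprocessing.
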