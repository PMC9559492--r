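---
title: "Methods: dose-response endpoints, sensitivity biomarkers and synergy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response endpoints, sensitivity biomarkers and synergy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsense)
```

`panelsense` implements the computational arm of a cell-line panel drug
screen: per-line dose-response endpoints, panel-level sensitivity classes,
expression-based biomarker discovery with a cross-validated classifier,
drug-combination synergy scoring, and two downstream validation assays. This
vignette describes the models, the parameters that matter, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Dose-response model and AUC endpoint

Viability signals are converted to percent inhibition against the vehicle
control, `100 * (1 - treated/control)` (a time-zero plate, when present, is
carried as metadata only; it does not enter the endpoint). Each cell line x
drug curve is fitted with the four-parameter logistic model

$$\mathrm{Inhibition\%}(x) = Bottom + \frac{Top - Bottom}
  {1 + 10^{(\log EC_{50} - x)\,HillSlope}},$$

with $x$ the log10 concentration. To absorb experimental error the asymptotes
are constrained to $Bottom \ge -20$ and $Top \le 120$. Fitting is bounded
nonlinear least squares (Levenberg-Marquardt, `minpack.lm`) with six starts
(asymptotes at the data range, $\log EC_{50}$ at the dose quartiles, slope
$\pm 1$), because 4PL likelihoods are multimodal on flat or noisy curves.
Fits with $Bottom > Top$ are re-expressed in the canonical orientation by
swapping asymptotes and negating the slope, which leaves the curve unchanged.

Fit quality is summarized by the relative standard error of EC50,
$\sigma_{EC50}/EC_{50}$. The standard error of $\log EC_{50}$ comes from the
delta-method covariance $\hat\sigma^2 (J^\top J)^{-1}$ at the optimum
($J$ the analytic Jacobian), and $\sigma_{EC50}/EC_{50} = \ln(10)\,
se(\log EC_{50})$. A fit is *acceptable* when it converged and this ratio is
below 40% (strict). Flat curves leave EC50 unidentifiable, the Jacobian
cross-product singular, and the ratio infinite, so they are flagged
unacceptable — but they still receive an AUC, because the AUC endpoint exists
precisely to summarize lines whose EC50 cannot be estimated.

The endpoint is the fitted area under the inhibition curve over a fixed
log-concentration window $[a, b] = [\log_{10} 1, \log_{10} 10^4] = [0, 4]$,
i.e. 1 nM - 10 uM. It has the closed form

$$AUC = Bottom\,(b-a) + \frac{Top-Bottom}{HillSlope \cdot \ln 10}
 \ln \frac{1 + 10^{HillSlope (b - \log EC_{50})}}
          {1 + 10^{HillSlope (a - \log EC_{50})}},$$

evaluated with a `log1p`-stabilized `log(1 + 10^z)` so that arbitrarily steep
slopes do not overflow. A zero slope degenerates to the flat-curve value
$(Top+Bottom)/2 \cdot (b-a)$ and is flagged. The closed form is verified
against composite-Simpson quadrature (worst relative error over 1,000 random
parameter draws inside the constraint box is ~1e-14, asserted at 1e-8).

## Sensitivity classes

Panel AUCs are standardized to z-scores with the sample (n-1) standard
deviation. Classes use strict thresholds: *sensitive* if $z < -0.5$,
*insensitive* if $z > 0.5$, *intermediate* otherwise; values exactly on the
boundary are intermediate. Classes are invariant under positive affine
transforms of the AUC vector, so the choice of n-1 versus n in the sd only
matters for exact-boundary cases. One convention to be aware of: the class
names follow the printed z-score rule as-is. With an endpoint that increases
with inhibition this maps low-inhibition lines to "sensitive"; the pipeline
is self-consistent (labels, informative-gene orientation and classifier all
share the convention), so every downstream quantity is unaffected by which
name is attached to which tail.

## Expression filtering and the correlation screen

Genes measured in log2(FPKM) are removed when more than 85% of cell lines
express them below 1 (both comparisons strict). Surviving genes are screened
by Spearman correlation against the AUC endpoint with average-rank tie
handling; the two-sided p-value uses the t approximation on n-2 degrees of
freedom, which at panel sizes of a few dozen lines is indistinguishable from
the exact null and is what `stats::cor.test(exact = FALSE)` computes (the
tests use `cor.test` as an independent oracle). Selection is a raw
$p < 0.001$ cut with no multiple-testing correction — the screen is a
candidate filter, not an inference; its null behaviour is checked by
Monte-Carlo (10,000 null genes yield a selected count inside the binomial
95% interval around 10). Constant genes have undefined rank correlation and
are excluded with a warning. A separate helper computes Pearson r with the
t-based p-value for single-gene versus IC50 comparisons.

## Signature selection (shadow features)

All-relevant gene selection is re-implemented from the shadow-feature idea:
each iteration augments the candidate matrix with a permuted copy ("shadow")
of every active gene, fits a 500-tree random forest (`ranger`) and records a
*hit* for every gene whose z-scored permutation importance exceeds the
maximum shadow importance. Hits accumulate and two one-sided binomial tests
(null probability 0.5) with Bonferroni correction over the candidates decide
confirmation or rejection; rejected genes leave the model, confirmed genes
stay in the ensemble, and the shadow pool is padded so at least five shadows
always anchor the bar. Genes undecided after `max_iter` (default 100)
iterations are tentative and, by default, not selected; the median rough-fix
(`tentative = "median"`) is available but lenient, for the reason below.

Two properties of this procedure deserve honesty. First, the bar a gene must
clear is the *maximum* shadow importance, which scales roughly like
$\sqrt{2 \ln k}$ in the number of shadows $k$; as rejection shrinks the pool
the bar drops, so late iterations are more permissive than early ones.
Second, with small panels (n around 28) and many genes, a few null genes
carry spurious in-sample correlation as strong as a weak true marker
(|t| > 3 is expected several times among 1,000 nulls), and no importance
measure computed on the same labels can separate them. Consequently the
selector recovers essentially all strongly planted markers but also confirms
a small number (typically 1-4) of spurious genes per run at that sample
size; simulations in the test suite quantify this. Selection stability
should always be judged with the decision attributes returned alongside the
gene list.

## LPS / Bayes classifier and cross-validation

For a signature $G$ the linear predictor score of a cell line is
$LPS(X) = \sum_{j \in G} a_j X_j$, where $a_j$ is the pooled-variance
two-sample t-statistic between the sensitive and insensitive training lines
(positive when sensitive lines express the gene more highly; Welch weights
are available via an argument). Group-wise Gaussians are fitted to the
training LPS values and a held-out line's posterior is

$$P(\text{sensitive} \mid LPS) =
  \frac{\phi(LPS;\, \mu_1, \sigma_1^2)}
       {\phi(LPS;\, \mu_1, \sigma_1^2) + \phi(LPS;\, \mu_2, \sigma_2^2)},$$

with implicit equal class priors, computed via log densities for numerical
stability. Posteriors are invariant to affine rescaling of the LPS with
correspondingly refitted group parameters.

Accuracy is estimated by repeated stratified k-fold cross-validation
(default 20 x 10-fold): folds are dealt round-robin within each class, the
weights and Gaussians are refitted on every training fold, and accuracy is
pooled over folds then averaged over repeats. Fold assignment is reseeded as
`seed + repeat`, making reports reproducible. By default the signature is a
fixed input — selection happens before cross-validation, matching the
original procedure — and the report carries an explicit leakage note, since
genes chosen on all lines inflate fold accuracy; `nested = TRUE` re-runs
selection inside each training fold instead. On synthetic panels whose LPS
separation is $d$ with equal variances the expected accuracy is
$\Phi(d/2)$; the test suite checks calibration at $d = 2$
($\Phi(1) \approx 0.841$) with 200 lines and chance behaviour under permuted
labels. The calibration construct plants four signature genes shifted by one
within-class standard deviation each, giving $d = 1 \cdot \sqrt{4} = 2$.

## HSA synergy scoring

Combination matrices are scored against the highest-single-agent null: for a
well with both doses positive, $\delta_{ij} = y_{ij} - \max(y_{i0}, y_{0j})$,
the observed excess over the better monotherapy at the same doses. The
summary score is the plain arithmetic mean of $\delta$ over combination
wells only — monotherapy and vehicle wells are excluded, and no
response-surface smoothing or interpolation is applied (tools built around
the same model add a curve-fitting layer; the plain per-well form keeps the
score exactly auditable). Negative inhibition (stimulation) is allowed, and
$\delta$ inherits the symmetries of the definition: dose permutation, drug
swap (transposition) and sign flip of the combination excess.

## Downstream assays

Relative qPCR expression uses the delta-delta-Ct method: replicate Cts are
averaged per sample, $\Delta Ct = Ct_{target} - Ct_{reference}$ (housekeeping
reference, e.g. GAPDH), $\Delta\Delta Ct$ subtracts the control-group mean,
and fold change is $2^{-\Delta\Delta Ct}$. Group-level fold changes use
$2^{-\overline{\Delta\Delta Ct}}$ so the control group is exactly 1 against
itself. No primer-efficiency correction is applied.

Comet-assay crosslinking is quantified from per-nucleus olive tail moments
(OTM) after an H2O2 challenge: crosslinks restrain DNA migration, so
$\%CL = 100\,(1 - \overline{OTM}_{treated}/\overline{OTM}_{control})$,
computed against the drug-free challenged control at the matched timepoint
and capped at 100. The mean is the default location (a median variant is
provided since OTM distributions are right-skewed); the result is invariant
to rescaling both conditions.

## Synthetic data: what it emulates and what it does not

`generate_panel()` emulates a 50-line panel of three tumour types
(10 colorectal / 31 liver / 9 pancreatic), treated along a nine-point
3.16-fold dilution series from 1 nM, which spans the AUC window 1-10,000 nM.
Each line's true 4PL parameters are drawn uniformly (bottom -10..10%, top
60..110%, logEC50 1..4.5 — deliberately extending beyond the top dose so
some lines lack an identifiable EC50, as real panels do — slope 0.7..2).
Observed inhibition adds Gaussian noise (sd 2%, duplicate wells) truncated
to [-20, 120] to mirror the fit constraints, and signals are reconstructed
as `vehicle * (1 - inhibition/100)` around a fixed vehicle level. The
expression matrix plants `n_informative` genes linear in the true AUC
(default slope 0.01 log2-FPKM per AUC unit against residual sd 1 — a
monotone association detectable but not trivial at panel size; Spearman only
requires monotonicity) among independent-noise genes with uniform baselines.
`generate_two_class_expression()` is the calibration construct for the
selector and classifier; `generate_synergy_matrix()` plants a constant HSA
excess on top of two 4PL monotherapies over the combination design
{0, 0.01, 0.02, 0.05, 0.1} x {0, 1, 2, 5, 10} uM; `generate_comet_samples()`
draws OTMs from a gamma distribution (shape 3 by default, `Inf` for
noise-free checks) because OTMs are positive and right-skewed; and
`generate_qpcr_table()` encodes known fold changes against a stable
reference gene.

Everything is deterministic given the spec and seed, and every generator
returns its planted truth for recovery tests. What the generators do *not*
emulate: read-level RNA-seq and FPKM quantification, batch and platform
effects, correlated co-expression modules, tumour-type-specific expression
structure, heteroscedastic plate effects, or edge artifacts. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated statistical structure, not robustness to every artifact of real
screens.

## Numerical choices and problem sizes

Optimizer tolerances are `ftol = ptol = 1e-14` with up to 500 iterations per
start; termination with a zero-residual orthogonality code counts as
converged. Quadrature checks use composite Simpson with 2e4-1e5 panels.
Posterior ties ($p = 0.5$ exactly) are reported as `undecided`. Degenerate
inputs error early with messages naming the violated precondition (zero
control signal, zero AUC variance, zero within-group LPS variance, missing
reference Cts, missing zero doses).

The shipped checks run at deliberately desk-sized problems: 100 curves for
recovery, 1,000 genes x 28 lines for selection, 200 lines for classifier
calibration, 10,000 null genes for screen calibration, 50-seed synergy
recovery, and a full 50-line end-to-end determinism run — sizes chosen so
the whole suite completes in minutes on one core while keeping Monte-Carlo
error well inside the asserted tolerances.

## Known limitations

* The selector's false-confirmation behaviour at small n is intrinsic to
  in-sample importance comparison (discussed above); treat selected genes as
  candidates for validation, not conclusions.
* Default accuracy estimation uses selection-outside-CV to mirror the
  original procedure; it is optimistic, and the nested mode is the honest
  alternative.
* The AUC window is fixed in log10-nM units; endpoints from differently
  scaled dose ranges are comparable only after the corresponding shift.
* HSA delta is reported without confidence intervals; replicate-level
  bootstrap is future work.
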