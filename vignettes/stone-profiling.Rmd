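---
title: "Methods: double cross-validated PLS-DA for urinary amino acid profiling"
author: "aastone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double cross-validated PLS-DA for urinary amino acid profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aastone)
```

# The problem

Urolithiasis — stone formation in the urinary tract — is common, recurrent
and mechanistically only partly understood. Targeted metabolomics of urine
offers a route to non-invasive fingerprints of the condition: a panel of 35
amino acids and derivatives can be quantified simultaneously (µmol/L), and a
pilot case-control comparison of recurrent stone formers (SF) against
healthy controls (CNT) asks whether the two groups carry distinguishable
amino acid profiles, and which analytes carry the distinction.

The setting is statistically hostile: ~27 subjects, 35 correlated,
strictly positive, right-skewed concentration variables, and a real risk of
optimistic bias if model selection touches the samples used to estimate
performance. `aastone` implements the full discovery pipeline for this
setting — classification, validation, biomarker selection, and significance
testing — together with a synthetic cohort generator so that every stage is
reproducible and testable without per-subject data, which for the motivating
study were never deposited (only group-level summary tables are public).

# The classifier

## PLS1 discriminant analysis

Partial Least Squares Discriminant Analysis regresses a class-coded
response on the concentration matrix and thresholds the prediction. With
two classes, a single response column suffices: we code CNT = 0, SF = 1
(SF is the positive class everywhere in the package) and fit PLS1 by
NIPALS. Writing $X$ for the column-scaled matrix and $y$ for the centered
response, each latent variable (LV) $a$ is extracted as

$$
w_a \propto X_{a-1}^{\mathsf T} y_{a-1}, \quad \lVert w_a \rVert = 1,
\qquad t_a = X_{a-1} w_a,
\qquad p_a = \frac{X_{a-1}^{\mathsf T} t_a}{t_a^{\mathsf T} t_a},
\qquad q_a = \frac{y_{a-1}^{\mathsf T} t_a}{t_a^{\mathsf T} t_a},
$$

followed by deflation $X_a = X_{a-1} - t_a p_a^{\mathsf T}$,
$y_a = y_{a-1} - q_a t_a$. For a single response the weight update has a
closed form, so the fit is deterministic — no iteration, no random start.
Regression coefficients for any truncation $A$ are assembled through
$R = W (P^{\mathsf T} W)^{-1}$ and $B_A = R_{\cdot,1:A}\, q_{1:A}$, giving
$\hat y = \bar y + X B_A$; the per-LV coefficient path is stored so one fit
serves all candidate complexities during model selection. At full rank the
fitted values coincide with ordinary least squares (a unit-test oracle).

A sample is assigned to SF iff its continuous score strictly exceeds 0.5
(the midpoint of the coding); a score exactly at the threshold goes to CNT.
The paper trail for these conventions: two-column dummy coding and PLS1 are
equivalent for binary problems, PLS1 is simpler to audit, and the
tie-break, while measure-zero on continuous data, must be fixed for
determinism.

## Scaling

The pipeline's default preprocessing is autoscaling (mean-center, unit SD,
$n-1$ denominator), because the panel spans two orders of magnitude (serine
averages ~354 µmol/L in controls, aminoadipic-type analytes under 10) and
unscaled PLS would be dominated by high-abundance analytes. `pareto`,
`center` and `none` are available through the same interface. Scaling
parameters are always fitted on training rows only and applied to held-out
rows — this is the leakage boundary, and the test suite verifies it by
refitting stored folds from scratch. Zero-variance training columns are
scaled to exactly zero (rather than erroring) so that label-permuted
replicates can never crash on a degenerate column.

# Double cross-validation

Model complexity (the LV count) must be chosen without contaminating the
performance estimate. The engine runs repeated stratified double
cross-validation:

* **Outer loop** (default 5 folds): each fold is held out in turn; the
  model never sees it during selection or fitting.
* **Inner loop** (default 5 folds, on the outer training set only):
  cross-validates LV $\in 1..10$ and selects the count minimizing the inner
  number of misclassifications, ties resolved toward fewer LVs (parsimony).
* **Repetitions** (default 20): the whole procedure repeats with fresh
  stratified splits; rates are reported as mean ± SEM over repetitions
  (SEM denominator = number of repetitions — the interpretation under which
  repeated validation cycles yield a standard error).

Stratification deals each class round-robin into folds, so every fold
contains both classes whenever sizes permit; fold counts shrink with a
warning when a class is too small, and an infeasible split (a class with a
single member) is an error naming the limiting class. Inner accuracy — the
model-selection rate — is the inner-CV accuracy at the selected LV,
averaged over outer folds; outer accuracy pools each repetition's held-out
predictions. On strongly separated data the selector stays small (the
acceptance suite checks $\le 3$ LVs in $\ge 90\%$ of outer fits), matching
the two-LV models typical of such panels.

The final interpretable model (for score plots and VIP) is refit on all
samples at the modal LV count across outer fits, with ties to the smaller
count.

# Biomarker selection

Two deliberately different selectors:

* **VIP** (variable importance in projection), from the final all-data
  model:
  $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a}$
  with $\mathrm{SSY}_a = q_a^2\, t_a^{\mathsf T} t_a$. The normalization
  identity $\overline{\mathrm{VIP}^2} = 1$ holds algebraically and is
  asserted to $10^{-10}$ on every fitted model in the tests.
* **Rank product (RP)**, across the DCV outer submodels: within each outer
  fit, analytes are ranked by decreasing $|B_j|$ (average ranks on ties);
  RP is the geometric mean of an analyte's ranks across all submodels.
  RP $\ge 1$, is 1 only for an analyte ranked first everywhere, and is
  invariant to monotone transformations of the importances.

Feeding RP with resampled coefficients while VIP comes from the single
all-data model makes the two genuinely complementary (resampling-based vs
model-based); the alternative of RP over per-submodel VIPs is available
(`importance = "vip"`). The reported biomarker set is the intersection of
the top-$k$ of both rankings (default $k = 9$), with a deterministic
alphabetical tie-break.

**What consensus recovery can and cannot show.** With 27 samples the
sample correlation of a truly null analyte with the class label has a
standard deviation near $1/\sqrt{n} \approx 0.2$; the maximum over 26 null
analytes is therefore regularly comparable to the population effect of the
weakest planted markers (point-biserial $r \approx 0.6$ under the default
generator). Exact recovery of all nine planted analytes on a single
simulated cohort is consequently not guaranteed — occasionally one
chance-correlated null analyte enters both top-9 lists in place of the
weakest true marker. This is a property of the sample size and panel, not
of the selectors: an oracle ranking by the true-label $t$-statistic shows
the same behaviour. The acceptance suite states the exact-recovery claim
at face value and records its outcome honestly.

# Permutation significance

Three figures of merit summarize the validated classification: the number
of misclassifications (NMC), the area under the ROC curve (AUROC, computed
as the normalized Mann-Whitney statistic with ties counted ½), and the
discriminant Q² (DQ2), in which residuals of predictions overshooting
their own class label ($y=1$, $\hat y > 1$ or $y=0$, $\hat y < 0$) are set
to zero before computing $1 - \sum e_i^2 / \sum (y_i - \bar y)^2$ — so a
confidently correct prediction is not penalized. DQ2 never falls below the
plain Q² (truncation only shrinks squared residuals; a tested invariant).

The null distribution of each statistic is built by shuffling the class
labels uniformly and re-running the *entire* double cross-validation —
scaling, LV selection and outer prediction all inside the permuted world —
so the null inherits every optimistic bias the observed statistic could
carry. Statistics are computed on the pooled outer predictions of a single
DCV pass per permutation (keeping 1000 permutations tractable), and the
observed statistics use the identical single-pass computation, preserving
exchangeability. Rows of $X$ are untouched, so the analyte correlation
structure survives under the null. P-values use the add-one estimator
$p = (\#\{\text{null at least as extreme}\} + 1)/(B + 1)$, with floor
$1/(B+1)$; NMC is extreme when small, AUROC and DQ2 when large.

# The synthetic cohort generator

## What it emulates

The generator reproduces the statistical skeleton the analysis assumes:
35 uniquely named analytes; 15 SF and 12 CNT samples; nine discriminant
analytes (alpha-aminobutyric acid, asparagine, ethanolamine, isoleucine,
methionine, phenylalanine, serine, tryptophan, valine) carrying the
published group means and SDs, all lower in stone formers; and 26 analytes
with identical group distributions at physiologically plausible urinary
levels (those defaults are package choices — no per-subject or
supplementary values were ever published — and are fully overridable).

Each analyte × group cell is drawn i.i.d. from a positive-support
distribution moment-matched to its (mean, SD):

* **Lognormal** (default): exact closed form,
  $\sigma^2 = \ln(1 + s^2/m^2)$, $\mu = \ln m - \sigma^2/2$. Guaranteed
  positivity and realistic right skew for urinary concentrations.
* **Zero-truncated normal**: offered because published tables report
  arithmetic mean ± SD of possibly near-normal data. Naive truncation of
  $N(m, s)$ biases low-mean, high-CV analytes upward by several percent,
  so the parent parameters are solved numerically — the truncated CV is a
  monotone function of $\alpha = -\mu/\sigma$ alone, so a root search in
  $\alpha$ followed by a scale factor matches both moments. The family's
  CV is bounded near 0.98; analytes whose target CV exceeds 0.95 (e.g. a
  2.7 ± 2.7 µmol/L case group) fall back to the lognormal marginal.

Reproducibility is structural: every analyte × group pair has its own
random stream derived by hashing the analyte name against the root seed,
so the same seed always yields the same table, and extending the panel
never perturbs existing columns. An optional equicorrelation `rho` on the
latent Gaussian scale (Gaussian copula over the moment-matched marginals)
emulates the correlated panels PLS is designed for; the default is
independence.

## What it does not emulate

No instrument drift, carryover, limit-of-detection censoring, batch
effects, creatinine normalization, or the age/BMI imbalance of the real
cohorts; analyte correlations are zero (or exchangeable, with `rho`)
rather than biochemical. Passing tests on this generator therefore
demonstrate the *pipeline's* correctness and the detectability of the
published effect sizes under clean conditions — not that the pipeline
would achieve the same rates on real urine data. Units are treated as
abstract concentration units (µmol/L labels follow the source tables,
which do not state whether values are creatinine-normalized).

# Univariate module

For the per-analyte summary table, the default protocol applies the
Mann-Whitney U test to every analyte (exact enumeration when the combined
n ≤ 12 and there are no ties, otherwise the tie-corrected normal
approximation with continuity correction); an alternative normality-gated
protocol routes analytes passing Shapiro-Wilk (α = 0.05 in both groups) to
the Welch unequal-variance t-test. The published protocol is ambiguous
between these two descriptions, hence both are implemented with
Mann-Whitney-everywhere as the default. Raw p-values are primary;
a Benjamini-Hochberg column is appended as a clearly supplementary aid.
Groups with zero variance and equal means return p = 1 by convention.

# Numerical choices and problem sizes

* Decision threshold 0.5; threshold ties to CNT.
* Inner-loop ties to fewer LVs; modal-LV ties to the smaller count.
* Ranking ties: average ranks inside RP; alphabetical tie-break for the
  reported 1..p rankings and consensus sets.
* NIPALS stops (truncating with a warning) when $X$ or $y$ deflates below
  $10^{-12}$ in norm.
* Seeds: a single root seed is fanned out per stage (cohort, DCV,
  permutation) by name-hashing, so stages can be re-run in isolation;
  per-repetition and per-permutation streams are derived the same way.
  All RNG use is wrapped so the caller's `.Random.seed` is never
  disturbed.
* Default problem sizes: 20 DCV repetitions for rate estimation; 1000
  permutations for significance; generator checks use 10,000 draws per
  analyte/group; the p-value uniformity property uses 50 signal-free
  cohorts with 39 permutations each — sizes chosen so each estimate's
  Monte-Carlo error is small relative to the tolerance it is tested at.

# Limitations

* The real study's per-subject data are unavailable; all quantitative
  targets are recovered on synthetic cohorts parameterized from the
  published group summaries, with the large published effect sizes the
  synthetic rates inherit.
* Exact top-9 selector recovery on a single 27-sample cohort is not
  guaranteed (see above) — a finite-sample identifiability limit, not a
  selector defect.
* Only binary PLS1-DA is implemented: no multi-class, OPLS or sparse
  variants, and no probability calibration of scores.

# Session info

```{r}
sessionInfo()
```
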