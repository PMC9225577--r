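---
title: "exoNiche: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{exoNiche: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoNiche)
```

# The problem

Soil bacteria compete for, and exchange, low-molecular-weight carbon
compounds. Growing a panel of isolates individually in a defined medium
(a mixture of common soil metabolites at equimolar concentration, on
the order of 89 compounds at 20 µM) and profiling the spent media by
LC-MS gives each isolate a *substrate-utilization profile*: which
fraction of each medium component it removes. `exoNiche` implements the
inference chain from those profiles to a directed interaction network:
overlap in substrate use predicts competition; sequential re-culture in
spent media measures it; untargeted features that rise and then fall
across spent and double-spent media reveal cross-feeding.

# Gated fold changes

For metabolite $m$ and isolate $i$, the relative fold change is

$$FC_{m,i} = \frac{\overline{h}_{m,i}}{\overline{h}_{m,\text{ctrl}}} - 1,$$

the ratio of replicate-mean peak heights in the isolate's spent medium
to its matched uninoculated-medium control. The fold change is only
reported when the difference is statistically significant; otherwise it
is set to exactly 0. This *gating* is what makes the downstream overlap
computation well-defined: a profile contains only depletion the data
actually support.

Significance is a one-way ANOVA with Dunnett's many-to-one post hoc
comparison. The family is formed **per control group and per
metabolite**: all isolates that were sampled against the same
uninoculated control (an *early* control for fast growers, a *late*
control for slow growers, mirroring how such experiments schedule their
sampling) enter one family, so the familywise error rate is controlled
across the isolates sharing that control. Families could alternatively
be formed per isolate across metabolites; we chose the per-metabolite
family because the shared control is the structural source of
dependence, and the choice is isolated in one internal function should
a user want to change it.

Tests run on raw peak heights by default; a `transform = "log10"`
switch tests $\log_{10}(h + 1)$ instead (fold changes are always
computed from raw means). Missing heights are `NA`, never zero; the
`naPolicy` is `"drop"` (flag the cell undefined) or `"halfmin"` (impute
half the metabolite's minimum observed height). Dropping is the
default because imputation invents signal precisely where the gating is
supposed to protect against it.

Two degenerate situations have explicit rules:

* a control mean of zero with non-zero spent signal leaves the ratio
  undefined; the cell is flagged, not forced;
* a family whose pooled variance is numerically zero (noise-free or
  duplicated replicates) falls back to exact equality: $p = 1$ if the
  group mean equals the control mean, $p = 0$ otherwise. This keeps the
  noiseless recovery identity exact.

## Dunnett probabilities

Dunnett's statistics against a shared control have the one-factor
correlation structure $R_{jl} = \lambda_j \lambda_l$ with
$\lambda_j = \sqrt{n_j/(n_j + n_0)}$, which factorises the joint
multivariate-$t$ CDF into a double integral over the shared control
variate and the studentising chi variable. We evaluate it with fixed
Gauss–Hermite × Gauss–Legendre quadrature (32 × 48 nodes). This is
deterministic — quasi-Monte-Carlo multivariate-$t$ integration is not,
which matters for byte-identical pipeline re-runs — and fast enough to
run one family per analyte across thousands of analytes. Agreement
with `multcomp`/`mvtnorm` is verified in the unit tests to well below
any decision threshold (differences around $10^{-4}$, dominated by the
Monte-Carlo error of the reference itself).

# Utilization profiles and metrics

The profile of isolate $r$ is $p_{m,r} = \max(0, -FC_{m,r})$: depletion
fractions in $[0, 1]$, with production and unchanged cells contributing
0. Three per-isolate summaries:

* **richness** — number of substrates with $p > 0$;
* **abundance** — $100 \sum_m p_{m,r}$, the sum of the percentages of
  depletion (one fully consumed substrate contributes 100);
* **diversity** — inverse Simpson index
  $D = 1/\sum_m \pi_m^2$ with $\pi_m = p_m / \sum_m p_m$ over the
  support. Proportions are normalised over the significant support;
  $D$ is the evenness-weighted effective number of substrates used,
  equal to richness for perfectly even use and undefined on an empty
  support.

# Predicted interactions and competitive rank

The directional niche-overlap score of influencer $i$ on recipient $r$:

$$PIS_{ri} = -\frac{\sum_m p_{m,r}\, p_{m,i}}{\sum_m p_{m,r}^2}.$$

Properties the implementation preserves exactly (and the tests assert):
$PIS \le 0$; $PIS = 0$ iff the supports are disjoint; $PIS = -1$ for
identical profiles; invariance under common positive rescaling, so
storing fractions rather than percentages is immaterial. Recipients
with empty support make the denominator zero; their rows are *flagged
undefined* rather than coerced to 0, because no-overlap and no-data are
different statements. This mirrors dropping isolates that grow too
poorly to profile.

The competitive rank
$R_r = \sum_i (PIS_{ri} - PIS_{ir})$ sums incoming minus outgoing
predicted suppression over the *other* isolates (diagonal excluded).
The summand is antisymmetric, so $\sum_r R_r = 0$ — a conservation law
the tests check to $10^{-10}$. The rank is reported unnormalised, as
defined; normalising by the number of partners would only rescale a
fixed-size community.

# Growth analysis and measured interactions

OD600 series are fit to the logistic model
$N(t) = K / (1 + ((K - N_0)/N_0) e^{-rt})$ with doubling time
$t_{dd} = \ln 2 / r$. Initialisation: $N_0$ from the first observation,
$K$ from the maximum, $r$ from a log-linear regression on readings
below half the plateau; optimisation is bounded Levenberg–Marquardt
(`minpack.lm`). Series whose rise above the first reading is below
`minGrowth` (default 0.02 OD) or that peak at the first point are
flagged *no-growth* and not fitted; non-convergence is reported in the
result, never silently replaced by defaults.

The growth metric *final OD* is the last reading minus the mean last
reading of the matched uninoculated-medium control, clamped at 0.
*Cumulative respiration* is the MicroResp indicator drop
$(A_{570,\text{initial}} - A_{570,\text{final}})$ baseline-corrected by
the mean drop over uninoculated controls, also clamped at 0 for ratio
purposes. Clamping keeps the measured interaction strength

$$MIS_{ri} = \frac{\text{Growth}_{r,i}}{\text{Growth}_{r,\text{SDM}}} - 1
\;\ge\; -1,$$

with $-1$ attained exactly when the recipient does not grow at all in
the influencer's spent medium. Whether blank correction uses per-well
or mean-control arithmetic is not uniquely determined by the assay
description; we use the mean over control wells, which is the lower
variance choice, and expose the blank correction as an argument.
Significance per entry comes from a per-recipient Dunnett family (its
seven spent media against its SDM reference, in the 8-isolate design);
insignificant entries are retained with their p-values so a network
view can dash rather than drop them.

# Untargeted features and cross-feeding

Features are first screened against extraction blanks: a feature is
kept when at least one sample group is significantly *higher* than the
blanks (Dunnett family over all sample groups versus the blanks; the
screen only needs the adjusted p of the largest positive statistic,
which makes it one quadrature per feature). Production calls then
compare each isolate's spent medium to the uninoculated medium control
(significant increase = produced), reported as the percentage of
retained features per isolate.

For each (influencer $i$, recipient $r$) pair, every retained feature
is classified from two legs: spent$_i$ vs. SDM control, and
double-spent$_{ri}$ vs. a spent$_i$ reference. The reference is the
abiotic (uninoculated, incubated) spent-medium control when present —
it absorbs abiotic degradation during the second incubation — falling
back to the spent$_i$ samples themselves. Classes:

| leg 1 (spent vs SDM) | leg 2 (double vs spent) | class |
|---|---|---|
| up | down | `cross_fed` |
| down | down | `sequentially_depleted` |
| any | up | `recipient_produced` |
| up | unchanged | `produced_not_consumed` |
| otherwise | | `unchanged` |

The taxonomy is an exhaustive closure around the two biologically named
patterns (cross-feeding: secreted then consumed; sequential depletion:
consumed by both, i.e. direct resource competition); the remaining
labels are bookkeeping so that per-pair percentages sum to 100. "Down"
on the second leg is any significant decrease — the feature need not
return to the SDM baseline, since partial consumption of a secretion is
still cross-feeding. Tests are two-sided with direction read from the
sign of the mean difference. Ionization modes are analysed as separate
tables and summarised jointly downstream.

# The synthetic generator

The generator exists so that every stage has a recovery test against
known ground truth. It emulates the *design* of the experiment, with
these fixed study conditions:

* triplicate measurements with multiplicative log-normal noise, default
  coefficient of variation 0.1 (a typical LC-MS peak-height replicate
  CV), mean-one so expectations stay interpretable;
* baseline peak heights log-normal across metabolites spanning roughly
  two orders of magnitude, to exercise heteroscedastic gating;
* half generalist isolates (supports of 45–70% of the medium, faster
  growth) and half specialists (10–25%, slower), each depleting at
  least one substrate by more than 97%;
* growth coupled linearly to total consumed substrate:
  $K = N_0 + \text{yield} \times \sum_m C_{i,m}$, sampled every 20 min
  (monoculture) or 30 min (sequential) for 48 h; respiration
  proportional to consumed substrate;
* spent-medium expectations follow mass balance:
  spent $= b_m (1 - C_{i,m})$, double-spent
  $= b_m (1 - C_{i,m})(1 - C_{r,m})$; secreted features rise above
  their background by a planted 2.5–5-fold amount and drop to 15% of
  the secreted amount when a consumer grows on the medium;
* the true measured interaction is
  $\text{avail}_{ri}/\text{avail}_{r,\text{SDM}} - 1$ where
  availability counts residual substrates plus consumable secretions.

What it does **not** emulate — and what passing recovery tests
therefore cannot show about real data: saturating (Monod) uptake
kinetics, diauxie and substrate preference ordering, pH- or
toxin-mediated interference competition, LC-MS peak-shape artefacts,
retention-time drift, censoring at the detection limit, and
between-batch effects. The generator is a stand-in for the study
design, not a claim about the organisms.

Test problem sizes are the package's own choices for a fast,
informative suite: 8 isolates × 60 metabolites for end-to-end runs
(seed 42 as the reference community), 10 seeds for median-based
recovery statements, 20 curves for logistic noise recovery.

# Numerical choices

* Dunnett probabilities by deterministic product-form quadrature
  (above); ties between classes are impossible by construction since
  classes are assigned by a fixed precedence (`cross_fed` before
  `recipient_produced`).
* Zero-variance families use the exact-equality rule; zero control
  means flag cells undefined.
* The logistic fit bounds all parameters positive and caps iterations
  at 200; the no-growth flag (rise < 0.02 OD) prevents fitting noise.
* Matrix CSVs write missing entries as empty cells and are
  byte-identical across repeated writes; GraphML/SIF exports sort edges
  by source then target for the same reason.
* Configuration files are YAML (paths, alpha, simulation block).

# Limitations

* The overlap score treats substrates as equally valuable and
  independent; weighting by substrate-specific growth value is a known
  extension and is out of scope here.
* Gating at $\alpha = 0.05$ trades sensitivity for specificity: weak
  depletion (fractions below ~0.1 at CV 0.1 with $n = 3$) is
  legitimately gated to zero and never reaches the overlap
  computation.
* Cross-feeding classification inherits the two-leg testing error
  rates; at $\alpha = 0.05$ a small fraction of unconsumed features
  will false-positive on one leg, which is the method's operating
  characteristic rather than a bug.
* Group-level inferential statistics on real study designs (ANCOVA,
  PERMANOVA, Tukey letters) are deliberately not re-implemented; the
  result tables are tidy inputs for those standard tools.
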