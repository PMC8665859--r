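---
title: "Models and methods in methrisk"
author: "methrisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in methrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrisk)
```

# Scope

`methrisk` analyses candidate-gene DNA methylation array data for the
molecular covariates of disease risk: sex, X-chromosome inactivation
(XCI), pre-existing respiratory disease, and controlled air-pollutant
exposure. This vignette documents the statistical models, the
parameters that matter, the numerical choices, and what the bundled
synthetic generator does and does not emulate. It is the package's
design record: nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The beta/M duality

Arrays report per-probe methylation as a fraction
$\beta \in [0, 1]$. Effect sizes are easiest to interpret on the
$\beta$ scale, but its variance shrinks toward the boundaries, so all
linear modelling is done on the logit scale,
$M = \log_2\!\big(\beta / (1 - \beta)\big)$, where Gaussian models are
a reasonable approximation. Both conventions coexist throughout the
package: models and test statistics live on $M$; the reported effect
size $\Delta\beta$ is always a *raw difference of group mean
$\beta$*, not a back-transformed model coefficient, because the dual
significance rules pair an FDR cut with a biologically interpretable
$\beta$-scale magnitude.

Synthetic data can produce $\beta$ of exactly 0 or 1 (real arrays do
not); before the logit, values are clipped into
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.001$
(`beta_clip_epsilon`), keeping $M$ finite at $\pm\log_2(999) \approx
\pm 9.96$. The inverse transform is exact on the clipped domain
(round-trip error below $10^{-12}$, tested).

# Sex-biased differential methylation

Per probe, ordinary least squares of $M$ on the main effect plus
covariates (default: sex, adjusted for age and disease). Two-level
factors are coded with the control level as baseline (F, `none`,
`negative`), so the main-effect coefficient's sign agrees with the
male-minus-female $\Delta\beta$ convention. Samples missing any model
covariate are dropped for that fit (complete-case, counted and
logged): the simplest defensible rule for the small candidate-gene
cohorts this package targets.

Residual variances are moderated by empirical Bayes, assuming
$s^2 \sim s_0^2 F(d, d_0)$: the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the t statistic is
recomputed on $d_0 + d$ degrees of freedom. $d_0$ and $s_0^2$ are
estimated by method of moments on $\log s^2$, using the inverse
trigamma (Newton iteration, relative tolerance $10^{-8}$). When the
observed spread of $\log s^2$ does not exceed its sampling spread,
$d_0 = \infty$ and all variances collapse to $s_0^2$. Moderation is
on by default — it is standard for array linear modelling — but the
unmoderated path is retained (`moderate = FALSE`, or `priorDf = 0`
which reproduces it exactly) and both are tested; the moderated fit
is cross-checked against an independent implementation in the test
suite.

Multiple testing uses the Benjamini–Hochberg step-up, implemented
directly (ordered $q_{(i)} = \min_{j \ge i} m\, p_{(j)}/j$, capped at
1, missing values propagated) and verified against `stats::p.adjust`
on a thousand random vectors. FDR families are one tissue × one probe
set (autosomal candidates, or X-linked candidates), mirroring
per-tissue reporting; whether a joint family across chromosome
classes would be preferable is a documented open choice, and per-family
adjustment is the package's position.

Dual significance thresholds by analysis family (all configurable via
`analysisConfig()`):

| family      | FDR    | \|Δβ\|  |
|-------------|--------|---------|
| autosomal   | 0.05   | 0.05    |
| X-linked    | 0.05   | 0.10    |
| exposure    | 0.10   | 0.025   |
| COPD-style  | 0.20   | 0.05    |

Supporting comparisons: cross-tissue concordance (significant in
$\ge k$ tissues with a shared $\Delta\beta$ sign), age-stratified
$\Delta\beta$ in left-closed bins $[0,20), [20,30), [30,40), [40,50),
[50,\infty)$ (a bin is reported only when both sexes are present), and
a sex-stratified case/control comparison at candidate probes (Welch t
on $M$, exploratory flag at unadjusted $p \le 0.05$ and
$|\Delta\beta| > 0.05$; an exploratory rule, hence no FDR
here — all values are reported regardless of the flag). The Welch
test was chosen for the stratified comparison because the status
groups are small and variance homogeneity is not defensible; this is
a documented interpretation where the original description names no
test.

# X-chromosome inactivation

The female X-linked array signal is a composite: at each probe,
roughly half the signal comes from the active X (approximated by the
male X) and half from the inactive X. Writing $r_j$ for the
tissue-matched male mean $\beta$ at probe $j$, the inactive-X estimate
for female $i$ is

$$\hat{xi}_{ij} = \mathrm{clamp}(2\beta_{ij} - r_j,\ 0,\ 1).$$

Clamping (rather than any probabilistic rounding) is the only
deterministic reading of keeping estimates inside $[0,1]$, and the
estimator is exact in expectation under the composite model. It is
monotone in $\beta_{ij}$ and anti-monotone in $r_j$; near-boundary
truth values incur a small clamp-induced bias (measured below 0.02 at
precision $\varphi = 400$ in the validation battery).

XCI status is called per gene from CpG-island promoter methylation,
using *measured* male and female $\beta$ (not the Xi estimate): the
printed classification rules reference both sexes' observed values,
and the Xi estimate is reserved for the linear-modelling arm. A
configurable alternative was considered and rejected to keep the
promoter rules exactly as stated. The decision order is:

1. **subject** — promoter mean $\Delta\beta$ (female − male) $> 0.10$
   *and* smallest promoter $q < 0.05$;
2. **escape** — both sex means $< 0.15$, *or* overlapping per-sex
   ranges of per-sample promoter-mean $\beta$, *or* disjoint ranges
   with $|\Delta\beta| < 0.10$;
3. otherwise **not evaluable** (`indeterminate`).

"Ranges" are per-sex $[\min, \max]$ of per-sample promoter-mean
$\beta$ — the simplest reading of overlapping $\beta$ ranges, and
robust to single-probe noise because probes are averaged within a
sample first. Exactly one branch fires per call and is recorded in
`rule_fired`. Only high- (HC) or intermediate-density (IC) CpG-island
promoters support calls; LC-only or promoter-less genes go to the
male-X vs inactive-X linear-modelling arm (`xDiffMeth()`), with the
X-linked dual rule (FDR < 0.05, $|\Delta\beta| > 0.10$, where
$\Delta\beta$ = mean female Xi − mean male $\beta$). When the
annotation lacks a promoter feature flag, probes within −1500..+500 bp
of the TSS are treated as promoter probes — a common array-annotation
convention; the window is configurable.

# Crossover exposure designs

Each participant receives all four conditions (filtered air + saline
FA+S; filtered air + allergen FA+A; diesel exhaust + allergen DE+A;
particle-depleted diesel exhaust + allergen PDDE+A). Per probe, a
Gaussian random-intercept model on $M$:

$$M_{ic} = x_{ic}^\top\gamma + u_i + e_{ic}, \qquad
u_i \sim N(0, \sigma_u^2),\ e_{ic} \sim N(0, \sigma_e^2),$$

with exposure, sex, asthma and age as fixed effects, fitted by
maximum likelihood (never REML: the likelihood-ratio test compares
models differing in fixed effects, which is invalid under REML, and
the LRT machinery refuses REML fits). The LRT statistic
$2(\ell_{\text{full}} - \ell_{\text{reduced}})$ is floored at zero
and referred to $\chi^2$ with df equal to the fixed-effect difference
(3 for the four-level exposure). Probes whose fit does not converge
are excluded from the FDR family with a logged count rather than
failing the run. Post-hoc many-to-one contrasts against FA+S use the
single-step Dunnett-style adjustment over the three correlated
contrasts (joint normal approximation of the estimator); Dunnett
rather than all-pairs because the scientific question is "which
exposure differs from control". An all-pairs comparison can be run by
calling `multcomp` directly on the returned fit. The exposure dual
rule is FDR < 0.10 with the largest per-contrast $|\Delta\beta|$
(raw mean $\beta$ difference vs FA+S) above 0.025. The same machinery
tests the asthma main effect (df = 1; $\Delta\beta$ then contrasts
asthma vs none).

With $\sigma_u = 0$ and a balanced design the ML fixed effects
coincide with OLS (tested to $10^{-6}$); note the $\sigma_u$
*estimate* under a true zero is positive sampling noise on any single
probe and only its average share of variance is near zero.

# The synthetic generator

`simulateMethylation()` draws
$\beta_{ij} \sim \mathrm{Beta}(\mu_{ij}\varphi, (1-\mu_{ij})\varphi)$:
the mean/precision parameterisation respects the $[0,1]$ support and
reproduces the variance shrinkage toward the boundaries seen on real
arrays. Defaults, chosen once as a realistic mid-size candidate-gene
cohort and not revisited:

- 50 samples per sex; probe baselines from a bimodal mixture (70%
  around $\beta = 0.1$, 30% around $0.85$, drawn with Beta precision
  20) mimicking array bimodality;
- noise precision $\varphi = 100$ (per-sample sd $\approx 0.03$ at
  $\beta = 0.1$), with $\varphi = 400$ as the low-noise setting for
  estimator-convergence checks;
- sex effects injected **on the β scale** at a 10% probe fraction
  with $|\Delta\beta| = 0.05$ and random sign, applied symmetrically
  around the baseline — so the recorded truth is directly comparable
  to the estimated $\Delta\beta$. Means pushed outside
  $(0.001, 0.999)$ are clipped, and the *realised* per-probe
  $\Delta\beta$ after clipping is what the truth table stores;
- X-linked genes: males at the active-X mean (0.05); females at the
  composite $(\text{Xa} + \text{Xi})/2$, with Xi = 0.80 for genes
  subject to XCI and 0.05 for escape genes — four HC-promoter and
  four gene-body probes per gene;
- exposure, batch and participant effects injected **on the M
  scale**, where the corresponding models operate (crossover
  defaults: 12 participants, $\sigma_u = 0.5$, $\sigma_e = 0.2$,
  exposure effect 0.3 on PDDE+A, asthma prevalence 0.3);
- COVID-status effects nested within sex on the β scale;
- QC injection: configurable fractions of failing detection-p cells
  and sub-3-bead cells.

Random draws use named substreams derived from the master seed
(sample covariates, probe effects, noise and QC each have their own
stream), so enlarging one component does not perturb the others, and
identical seeds give bitwise-identical data.

**What the generator does not emulate** — and hence what passing
tests do not show about real data: probe cross-hybridisation and SNP
artifacts, cell-composition heterogeneity, probe-type (Infinium
I/II) bias, spatial chip effects beyond a single M-scale batch
offset, and correlated neighbouring CpGs (probes are independent
given their means). Preprocessing itself (background correction,
BMIQ-style normalisation, batch correction) is out of scope: the
generator emits normalised β directly, as the analysis stages assume.

# Quality control

Boundary rules are strict inequalities exactly as printed: a sample
fails when *more than* 1% of its probes have detection $p > 0.01$ (or
fewer than 3 beads); a probe is dropped when failing in *more than*
5% of samples. The per-probe bead rule is stated in the source
methods without a sample fraction; the package applies the same >5%
fraction as the detection rule, so one failed cell cannot kill a
probe observed well elsewhere — a documented decision. Sex prediction
clusters per-sample mean X-chromosome β into two groups
(agglomerative, average linkage) and labels the higher-mean cluster
female (the composite inactive-X signal raises female X β); with all
samples identical the split is meaningless and the prediction
abstains. Y-chromosome confirmation is not implemented because the
generator emits no Y probes; on real data the X-based split is the
operative signal in the source method ("DNA methylation values" of
the sex chromosomes).

# Numerical choices and degenerate inputs

- logit clip $\varepsilon = 0.001$; round-trip exact to $10^{-12}$.
- Inverse trigamma by Newton iteration (50 iterations max, relative
  tolerance $10^{-8}$); `priorDf = 0` bypasses moderation exactly.
- Zero residual df or non-finite t → p reported missing, excluded
  from BH (which adjusts over non-missing values only).
- LRT statistic floored at 0; identical models give p = 1.
- Probes with equal group means and zero spread: Welch t undefined →
  missing, never 0/0.
- `classifyXci` is deterministic; ties in promoter density resolve
  HC > IC.
- Age bins are left-closed (age exactly 20 goes to [20, 30)); the
  last bin is unbounded.

# Validation battery sizes

The acceptance script and test suite validate with problem sizes
chosen to give tight Monte-Carlo error while remaining desk-scale:
40 X-linked genes at 50 + 50 samples for XCI recovery
($\varphi = 100$) and Xi estimator error ($\varphi = 400$); 20
replicates of 5,000 null probes for global-null FDR behaviour;
1,000 probes at 30 + 30 for $\Delta\beta$ recovery and dual-rule
sensitivity; 1,000 null probes on a 12 × 4 crossover for LRT
calibration; 20 crossover replicates of 100 probes for the
asthma-null mirror. On the global-null FDR check, note that the
any-discovery probability of BH over a replicate is itself
$\approx \alpha$, so the 20-replicate proportion has non-trivial
sampling noise; the logit-boundary probes of the bimodal baseline
also give the M-value t test slightly heavy far tails, a known
property of logit-transformed bounded data.

# Known limitations

Candidate-gene scale only: the per-probe OLS uses dense matrices and
is comfortable to ~$10^5$ probes but not optimised for
whole-epigenome scans. No region-level (DMR) analysis, cell-type
deconvolution, or surrogate-variable adjustment. The XCI promoter
rules presume the annotation's CpG-density classes (HC/IC/LC) are
given — the package never computes them from sequence. The
sex-stratified status comparison is exploratory by design (unadjusted
p), and the crossover machinery assumes a complete, balanced design;
moderately unbalanced data fit, but heavily unbalanced designs may
fail the identifiability checks.
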