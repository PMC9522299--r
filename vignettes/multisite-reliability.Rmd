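---
title: "Assessing multi-site reliability of imaging-derived phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing multi-site reliability of imaging-derived phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idprel)
```

## The problem

Multi-site MRI studies pool imaging-derived phenotypes (IDPs) — scalar
measurements such as regional volumes, cortical thicknesses, tract fractional
anisotropies — collected on scanners at different sites, often from different
manufacturers. Site differences in hardware and sequences shift the mean of
an IDP, change its scale, or both, inflating variance and eroding power. A
*travelling-heads* design, in which the same small group of subjects is
scanned at every site, lets between-site variance be separated from
between-subject variance and compared against a single-scanner test-retest
benchmark.

`idprel` implements that analysis as a reusable pipeline: per-IDP
repeated-measures ANOVA with sphericity and normality diagnostics, class-wise
false-discovery-rate control, consistency ICC(3,1) from variance components,
subsample-resampling benchmarks against a large test-retest reference cohort,
and the analytic power calculation for the design. A synthetic-cohort
generator with known variance components provides ground truth for
validating every step.

## The model

For one IDP, let $y_{ij}$ be the measurement of subject $i$ at session
(site) $j$. The working model is

$$y_{ij} = \mu + b_j + s_j\,(a_i + e_{ij}),
  \qquad a_i \sim N(0, \sigma_s^2),\quad e_{ij} \sim N(0, \sigma_e^2),$$

where $b_j$ is an additive site offset and $s_j > 0$ a multiplicative site
scale. Offsets move session means without touching the ranking of subjects;
scale factors additionally make the variances of pairwise session
differences unequal — a *sphericity* violation — while still preserving
within-site subject ranking. This is the minimal model in which "shift and
scale" site effects are separable from subject-level signal, and it is what
the generator simulates and the tests assume.

Three questions map onto three statistics:

* **Mean site effects.** The within-subject (repeated-measures) ANOVA tests
  $H_0: b_1 = \dots = b_k$ via
  $F = \mathrm{MS}_\text{sessions}/\mathrm{MS}_\text{error}$ on
  $(k-1, (n-1)(k-1))$ degrees of freedom. Effect size is partial
  $\eta^2 = \mathrm{SS}_\text{sessions}/(\mathrm{SS}_\text{sessions} +
  \mathrm{SS}_\text{error})$.
* **Scale site effects.** Mauchly's $W$ tests sphericity of the session
  covariance; a violation signals between-site differences in scale. When
  detected (Mauchly $p < 0.05$), the Greenhouse–Geisser
  $\varepsilon$ rescales the ANOVA degrees of freedom.
* **Reliability.** The consistency ICC(3,1),
  $\mathrm{ICC} = \sigma_s^2 / (\sigma_s^2 + \sigma_e^2)$, estimated from
  the two-way decomposition as
  $(\mathrm{MS}_\text{subjects} - \mathrm{MS}_\text{error}) /
   (\mathrm{MS}_\text{subjects} + (k-1)\mathrm{MS}_\text{error})$,
  treats site as a fixed effect: additive offsets do not count against it,
  scale changes do. Values of 0.5–0.8 are conventionally read as fair to
  good reliability, above 0.8–0.9 as good to very good.

```{r}
specs <- idp_specs_from_icc(6, 0.8, class_label = "volumes")
tbl <- generate_travelling_heads(
  sessions = travelling_sessions(ge_offset = 1, ge_scale = 1.5),
  specs = specs, seed = 42
)
m <- extract_matrix(tbl, "idp_0001")
rm_anova(m)
mauchly_test(m)
icc_consistency(m)
```

## Parameters that matter

| parameter | default | units / range | role |
|---|---|---|---|
| `n_subjects` | 8 | count | travelling-heads cohort size |
| sessions | 4 (3 Siemens + 1 GE) | — | site layout; drives all-sites vs Siemens-only contrasts |
| `sigma_subject`, `sigma_error` | 1, 1 | IDP units | variance components; implied ICC $\sigma_s^2/(\sigma_s^2+\sigma_e^2)$ |
| `offset`, `scale` | 0, 1 | IDP units, ratio | site effect injected per session |
| `missing_rate` | 0 | probability | per-(subject, session) completely-at-random loss |
| `q` | 0.05 | probability | FDR level, applied within each IDP class |
| `alpha_sphericity` | 0.05 | probability | Mauchly gate for the GG correction |
| `subset_size`, `n_resamples` | 8, 1000 | counts | benchmark resampling against the reference cohort |
| `rho`, `epsilon` (power) | 0.5, 1 | correlation, nonsphericity | assumptions of the design power calculation |

The default travelling-heads layout (`travelling_sessions()`) mirrors the
canonical multi-manufacturer pilot: three Siemens Prisma sites (Cambridge,
Oxford, Liverpool) and one GE MR750 site (KCL). The magnitude of a
GE-manufacturer effect is deliberately a free parameter (`ge_offset`,
`ge_scale`), not a calibrated value: no quantitative model of the
between-manufacturer effect is available, so analyses of the GE contrast
are qualitative-direction checks.

## Class-wise FDR

Site-effect p-values are corrected by Benjamini–Hochberg *within each IDP
class* (volumes, thicknesses, tract FA, …) at $q = 5\%$. Within-class
correction keeps a signal-dense class (e.g. tissue intensities under a
manufacturer effect) from dragging the rejection threshold of a
signal-sparse class, and vice versa; the per-IDP tests are approximately
independent across IDPs within the simulation model, the regime in which BH
control holds.

## Benchmarking against a reference cohort

An ICC estimated from 8 subjects is noisy, so the pipeline compares it to
the distribution of ICCs the *same estimator* produces on matched-size
subsamples of a large single-scanner test-retest cohort (by default 1000
draws of 8 subjects, without replacement within a draw, independently
across draws). The observed multi-site ICC gets an empirical two-sided
p-value with the add-one doubled-tail convention

$$p = \min\!\Big(1,\; 2\min\big[\tfrac{1 + \#\{icc^* \le icc\}}{B+1},
\tfrac{1 + \#\{icc^* \ge icc\}}{B+1}\big]\Big),$$

which can never return 0 from a finite number of draws. The doubled-tail
rule was chosen over a distance-from-median rule as the standard convention
for resampled null distributions; the two differ only in asymmetric tails.

## Design power

The design calculation for the site-effect test uses the noncentral F
distribution with noncentrality
$\lambda = f^2 n k \varepsilon / (1-\rho)$, $f^2 = \eta^2/(1-\eta^2)$ —
the convention of standard repeated-measures power software. Under the
conventional assumptions $\rho = 0.5$, $\varepsilon = 1$, $\alpha = 0.05$:

```{r}
rm_anova_power(8, 4, eta_squared = 0.2)
rm_anova_power(8, 4, eta_squared = 0.1)
```

so an 8-subject, 4-site design reliably detects large site effects
($\eta^2 = 0.2$, power $\approx 0.88$) but not medium ones
($\eta^2 = 0.1$, power $\approx 0.51$). These assumptions are defaults, not
estimates; `rho` and `epsilon` are exposed so the calculation can be
re-done under other choices.

## What the generator does and does not emulate

The generator reproduces the statistical skeleton of the designs — a
travelling-heads cohort (8 subjects × 4 sessions by default, shift/scale
site effects, a manufacturer label per session, completely-at-random
missing sessions) and a two-visit reference cohort (2,817 subjects by
default, no site effects). It deliberately omits: non-normal measurement
noise (normality testing is exercised through scale/offset contamination
instead), age/sex covariate structure, modality-specific artefacts, head
motion, and any drift between reference visits. Passing tests therefore
demonstrate that the statistical machinery is correct under its own
assumptions — not that real IDPs satisfy those assumptions; the Shapiro–Wilk
and Mauchly diagnostics exist precisely to check them on real data.

## Numerical choices and degenerate inputs

* **Complete-case rule.** Per analysed session subset, subjects missing any
  requested session are dropped; fewer than 3 surviving subjects makes the
  IDP "skipped" (below $n = 3$ the error degrees of freedom
  $(n-1)(k-1) < 4$ and every downstream test is uninformative). Skipped
  IDPs are reported with a reason, never silently dropped, and excluded
  from class denominators.
* **Ordering.** Subjects and sessions are sorted lexicographically
  everywhere, and resampling draws are integer-indexed against that order,
  so outputs are reproducible across platforms and input orderings.
* **Degenerate fits.** A perfectly additive matrix (zero residual) flags
  `degenerate`: the ANOVA reports $F = \infty, p = 0$; the ICC reports 1.
  Zero-variance residuals make Shapiro–Wilk "not estimable"; a singular
  contrast covariance makes Mauchly "not estimable" and pins
  $\varepsilon$ at its conservative lower bound $1/(k-1)$.
* **Negative ICCs.** The ANOVA estimator can be negative at $n = 8$; values
  are reported raw with a flag, because truncating at 0 biases class means
  upward. The REML estimator (closed form for the balanced one-random-factor
  model) truncates at the boundary, and equals the ANOVA estimator whenever
  the latter is non-negative.
* **Mauchly's p.** The chi-square approximation uses the first-order Box
  correction factor; base R's `mauchly.test()` adds a higher-order series
  term, so p-values agree to ~0.01 at $n = 8$ and converge with $n$.
* **Friedman test.** Implemented with mid-rank ties and the standard tie
  correction (the base-R statistic omits it); tie-free data reproduce
  `stats::friedman.test()` exactly.

## Open choices made here

* **Partial vs classical $\eta^2$:** partial is the default (the
  within-subject convention, and the one consistent with the power
  module); classical is computed alongside.
* **Normality testing target:** Shapiro–Wilk is applied to the
  doubly-centred residuals $y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j} +
  \bar y_{\cdot\cdot}$ — the assumption-relevant quantities — rather than
  raw per-site values.
* **Complete-case scope:** alignment across sites is complete-case per
  analysed session subset (a pair analysis keeps subjects missing only a
  third site), not global.
* **GG gating:** the correction is applied only when Mauchly rejects at
  0.05, matching the "correct if detected" policy; always-correct and
  Huynh–Feldt variants are out of scope.

## Simulation sizes

Validation simulations use 8 × 4 travelling-heads cohorts and a
2,817-subject reference cohort; calibration checks run 2000 null
replicates, parameter-recovery checks 2000 IDPs per true ICC (where the
Monte-Carlo error of the mean, ~0.004, is small against the ±0.05 recovery
band), FDR checks 3 × 500 mixed IDPs, and benchmark-calibration checks 500
empirical p-values against 1000 resamples. These sizes make each check's
Monte-Carlo error small relative to the property it asserts.

## Known limitations

* The ICC(3,1) estimator is biased downward by roughly 0.04 at mid-range
  ICC with $n = 8$; class means inherit that bias. The benchmark sidesteps
  it by comparing against the *same estimator* on matched-size reference
  subsamples.
* No confidence intervals for ICCs are produced, and no post-hoc pairwise
  site contrasts.
* No deconfounding for age, sex or head size; the travelling-heads design
  with $n = 8$ cannot support it.
* Harmonisation (e.g. COMBAT, additive-model adjustments) is downstream of
  this package's scope: the pipeline detects and quantifies site effects,
  it does not remove them.
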