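---
title: "Measuring non-random DNA strand segregation from burden moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring non-random DNA strand segregation from burden moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandseg)
```

## The model

Cairns' immortal strand hypothesis proposes that adult stem cells
preferentially retain the ancestral (template) DNA strand at division and
export replication errors with the differentiating daughter. `strandseg`
implements a minimal stochastic model of this process and the inference it
enables.

A homeostatic tissue is maintained by a constant pool of $N$ stem cells
dividing at a constant rate $\lambda$. At each division the cell carrying the
ancestral strand keeps stem-cell fate with probability $p$ (the non-random
strand segregation probability; $p = 0.5$ is a coin flip, $p = 1$ perfect
retention). A division that leaves the duplicated strand in the stem
compartment adds $\chi \sim \mathrm{Poisson}(\mu L)$ new mutations, where
$\mu$ is the per-bp per-division mutation rate and $L$ the surveyed genome
length. After $n$ divisions the number of "clean" divisions is
$k \sim \mathrm{Binomial}(n, p)$, so a cell's burden is a compound
Binomial–Poisson sum with

$$\tilde\mu = n\,(1-p)\,\mu L, \qquad
  \sigma^2 = n\,(1-p)\,\mu L + n\,p\,(1-p)\,(\mu L)^2 .$$

With $\Delta n = \lambda\,\Delta t$, both the mean and the variance of the
burden across cells grow **linearly with age**, but at rates that depend
*differently* on $p$ and $\mu L$. Their ratio,

$$\frac{\Delta\sigma^2}{\Delta\tilde\mu} = R = 1 + \mu L\, p,$$

is independent of time and of $\lambda$. Writing $m = \frac{1}{\lambda}
\frac{\Delta\tilde\mu}{\Delta t}$ for the per-division mean increment, the
parameters disentangle:

$$\hat p = \frac{R - 1}{(R - 1) + m}, \qquad
  \widehat{\mu L} = (R - 1) + m .$$

So two ordinary regressions — mean burden vs age and burden variance vs age,
over individuals with at least three sequenced cells each — identify both the
segregation probability and the per-division mutation rate, up to the assumed
division rate $\lambda$.

```{r}
colon <- load_tissue_summaries("colon")
infer_parameters(colon, division_rate = 52)
```

## Assumptions and what they buy

- **Homeostasis**: the pool size $N$ is constant; every retained lineage is
  statistically identical. Growing tissues (development, tumours) violate
  this; the lower segregation estimate in developing neurons is interpreted
  through the symmetric-division mechanism below rather than a different
  per-division fidelity.
- **Constant $\mu$ and $\lambda$**: both rates are time-invariant, which is
  what makes the age trends linear. Time-varying rates would bend the trends
  and are deliberately out of scope.
- **All mutations are division-linked**: division-independent damage is
  excluded from the estimators (its effect is quantified below).
- **A single $p$ for all cells**: no cell-to-cell heterogeneity in
  segregation fidelity.
- **Senescence and telomere attrition are not modelled.**

## Tunable parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `n_cells` | stem-cell pool size $N$ | cells | — |
| `p_seg` | strand-segregation probability $p$ | — | — |
| `mu_per_bp` / `mu_L` | mutation rate / per-division mean | per bp per division / per region per division | — |
| `genome_length` | surveyed length $L$ | bp | 6e9 (human WGS) |
| `division_rate` | $\lambda$ | divisions per time unit | 1 |
| `mu_background` | division-independent rate | mutations per region per time unit | 0 |
| `symmetric_fraction` | share of symmetric differentiation/self-renewal pairs | — | 0 |

Default division rates for the packaged tissues follow the published
convention: 52/year (one division per week) for adult tissues and 0.5/day
(one per 48 h) for developing neurons; both are assumptions, which is why
`scan_division_rate()` exists. The time unit is carried by the caller —
$\lambda$, slopes and ages must share one unit, validated only at the
inference layer, because adult tissues are naturally handled per year and
development per day.

## The simulator and the synthetic cohorts

`run_simulation()` uses synchronous discrete divisions: every stem cell
divides once per step and one step equals one division ($1/\lambda$ of wall
time). The closed-form moments are indexed by division count, so asynchronous
exponential waiting times would only add within-age dispersion in $n$ without
changing the quantities under study. Counts are totals per cell; no genome
positions or mutation identities are tracked, because every model quantity
depends on counts only.

Three kernels are available:

- **Asymmetric** (`step_asymmetric`): the default mechanism described above.
- **Symmetric mix** (`step_symmetric_mix`): with probability
  `symmetric_fraction` a division is a symmetric differentiation — the cell
  leaves the pool — compensated *within the same step* by a symmetric
  self-renewal of a uniformly chosen surviving cell, whose daughter inherits
  the parent burden plus one Poisson($\mu L$) increment. The mechanics of the
  pairing are not prescribed by the biology; this minimal scheduling (restore
  $N$ before the next snapshot, uniform choice of the renewing parent) is a
  design choice of this package, flagged as an interpretation.
- **Background** (`apply_background_mutations`): adds
  Poisson(`mu_background` · dt) to every cell each step, hitting both strands
  alike. Combining the symmetric kernel with background noise in one run is
  not supported.

`generate_cohort()` emulates the design of the single-cell / organoid
sequencing studies the estimators were built for: multiple individuals at
different ages, a handful of cells each, one independent population per
individual (its own RNG stream derived from the master seed, so individuals
are exchangeable), cells sampled uniformly without replacement. What the
synthetic cohorts deliberately do **not** emulate: sequencing error and
variable calling sensitivity, per-individual differences in $\mu$, $\lambda$
or $p$, shared developmental ancestry between cells of one individual, and
non-constant pool sizes. Passing recovery tests on these cohorts therefore
shows the estimator chain is correct *under the model*, not that real
tissues satisfy the model.

## Inference details and numerical choices

- **Regression**: unweighted OLS with free intercepts (`stats::lm`), mean and
  variance fitted independently. The free intercept absorbs in-utero and
  developmental burden present at age zero. Individuals need $\geq 3$ cells
  for an unbiased sample variance ($N-1$ denominator throughout); those below
  are dropped with a warning.
- **Dispersion ratio below 1** (variance slope smaller than mean slope) is
  inconsistent with the model and raises an error rather than silently
  clamping $\hat p$ to 0, so users see the violation.
- **Error bounds**: the slope standard errors are propagated by plug-in.
  The default (`bounds = "corners"`) evaluates the estimators at all four
  $(\text{d}\tilde\mu \pm \mathrm{SE}) \times (\sigma^2\text{-slope} \pm
  \mathrm{SE})$ combinations and reports the min/max — conservative, since it
  lets the two regression errors act in opposite directions.
  `bounds = "correlated"` uses only the two same-direction corners; this
  narrower convention is the one that reproduces the published per-tissue
  brackets digit-for-digit (e.g. colon $p$ (0.971; 0.974), $\mu$
  (4.26; 4.46)$\times 10^{-9}$), so it is exposed for comparability.
  `bounds = "bootstrap"` resamples individuals and reports percentile
  intervals. Corners that violate the model (ratio < 1) are skipped.
- **Reported precision** follows the field convention: $p$ to three decimals,
  $\mu$ to three significant figures.
- **Degenerate inputs**: all-newborn cohorts (single age) are rank-deficient
  and refused; $p = 1$ makes the dispersion ratio 0/0 and `var_mean_ratio()`
  errors explicitly.

## Known discrepancies in the published table

Recomputing the published point estimates from the published slopes
reproduces almost all of them exactly; three differ in the last printed
digit, consistent with the original analysis using unrounded regression
output: prefrontal-cortex $\mu$ recomputes to $7.70\times10^{-8}$ (printed
$7.68\times10^{-8}$), hippocampus $\mu$ to $1.15\times10^{-7}$ (printed
$1.14\times10^{-7}$), and early-development $p$ to 0.8755 (printed 0.876).
Skin is different in kind: the printed slopes are per 0.69 Mb, and dividing
the inferred $\widehat{\mu L} = 2.18$ by $0.69\times10^6$ bp gives
$3.2\times10^{-6}$ per bp, not the printed $1.57\times10^{-7}$ — the
effective target size behind the published skin rate is not recoverable from
the printed numbers (it implies roughly 14 Mb). The package therefore
exposes $L$ as an explicit parameter, reports skin as $\widehat{\mu L}$ per
0.69 Mb, and treats the printed skin per-bp rate as not reproducible from
the packaged inputs.

## Problem sizes used in the shipped analyses

The shipped analyses and tests run the simulator at the scales the original
experiments describe where that is the point of the check (N = 20000 cells
and 300 divisions for the recovery replica; N = 5000 and 30 replicates for
the division-mode comparison), and at reduced scales (pools of 50–2000
cells) where the quantity under test is scale-free, such as moment identities
and estimator round-trips. The background-bias grid {0, 0.5, 1, 2} mutations
per genome per division-time was chosen to span backgrounds well below and
well above the division-linked signal of $(1-p)\mu L = 0.3$ per division at
the true parameters $(p, \mu L) = (0.95, 6)$, the regime in which the
downward bias of $\hat p$ becomes visible and then dominant.

## Limitations

The estimates are conditional on $\lambda$ (hence the scan), assume burden
counts are exact (no calling-error model), and collapse each individual to
two numbers — a mixed-effects or joint Bayesian treatment of
$(p, \mu, \lambda)$ is out of scope. The symmetric-division diagnostic (the
growing spread of the variance-to-mean ratio) needs far more individuals
than current datasets offer and is provided as a simulation result, not an
estimator.
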