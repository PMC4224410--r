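---
title: "Tree complexity in mental arithmetic: models, fitting and recovery"
author: "domarith"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree complexity in mental arithmetic: models, fitting and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domarith)
```

## The scientific problem

Mental arithmetic on number sequences can be described by rooted
calculation trees: every elementary operation (a binary *Merge*) combines
two digits into a new one, and nested operations build hierarchy. The
**Degree of Merger (DoM)** — the maximum node depth of the tree, with the
top node as reference zero — measures that hierarchy. A competing view
holds that people covertly verbalize each elementary calculation
separately; then the process is a sequence of independent depth-1 trees
(the *flat* representation) and every trial has DoM 1 (0 when nothing is
computed).

This package implements the full desk-side analysis pipeline around that
question for a five-digit sequence task with four conditions:

* **Simple** — add and subtract the upper two digits
  (e.g. 3 + 7 = 10, |3 − 7| = 4); store the last digit of the sum and the
  difference.
* **Linear** — treat the upper pair as the start of an increasing
  arithmetic progression and compute its third term
  ([|3 − 7| + 7] = 11); store the common difference and the last digit of
  the answer.
* **Quad** — treat the lower triple as the start of an increasing
  quadratic sequence; two subtractions give the subordinate (first
  difference) linear sequence, whose third term is the answer
  ([||2 − 4| − |4 − 9|| + 5] = 8); store the subordinate common
  difference and the last digit of the answer.
* **Match** — store all five digits.

A white probe digit follows each trial; the participant judges whether it
matches a stored digit. The conditions are designed so that the
hierarchical DoM rises linearly (1, 2, 3, with Match at 0) while
competing complexity factors move differently, which is what makes a
parametric model comparison on region-level activation data informative.

```{r trees}
quad <- build_quad(2, 4, 9)
quad
degree_of_merger(quad)       # hierarchical depth: 3
count_nodes(quad)            # digit tokens, incl. the reused 5: 9
degree_of_merger(flatten(quad))  # flat representation: 1
```

## The eight complexity factors

`estimates_table()` computes, for every factor and condition, the largest
per-trial value over the valid stimulus space (in this design the
per-trial metrics are constant over the space, so the maximum equals the
common value; the tests verify this by exhaustive enumeration):

```{r estimates}
estimates_table()
```

* `dom_hier`, `nodes_hier` — depth and token count of the hierarchical
  forest;
* `dom_flat`, `nodes_flat` — the same for the flat representation, where
  every elementary calculation re-lists its operands and result as fresh
  tokens;
* `verbal_encoding` — everything verbalized when speaking the flat
  calculations: `nodes_flat + n_operations`;
* `n_operations` — the number of Merge (binary branches), identical in
  both representations;
* `n_generated` — occurrences of temporarily generated digits re-entering
  later calculations, counted on the hierarchical process. Occurrences,
  not distinct values: the Quad worked example uses its subordinate
  second term twice and counts it twice;
* `n_stored` — digits stored for the matching probe (2 arithmetic,
  5 Match).

Conventions fixed here (all validated against the published node counts
6, 5, 9, 5 and DoM values 1, 2, 3, 0): the Simple condition's two
independent calculations form one two-root forest; a reused generated
digit enters the hierarchical tree as one additional terminal carrying a
reuse link; a two-figure result occupies a single node holding the full
value, the mod-10 rule applying only to stored digits.

Condition contrasts are plain componentwise differences
(`contrast_estimates()`), so the three activation contrasts against the
Match baseline have factor predictions with a meaningful zero: no load
relative to Match predicts no signal change.

## Stimuli and schedules

Valid upper pairs exclude difference-one progressions and the ubiquitous
doubling pairs, formalized as `b − a >= 2` and `b != 2a` — the minimal
rule reproducing all printed exclusions. Valid lower triples are
increasing, disjoint from the upper pair, and have a second difference of
at least two, so the subordinate sequence is never trivial (this also
implies the subordinate sequence is increasing). The full valid space has
`r length(all_valid_stimuli())` arrangements; the study set samples 48
arithmetic arrangements (shared verbatim across the three arithmetic
cues) inside 72 Match arrangements.

`build_sessions()` produces eight 36-trial sessions: arithmetic and Match
trials alternate; each session carries 6 trials per arithmetic condition
and 18 Match trials; exactly half of each condition's trials are probe
matches; no arithmetic stimulus repeats and every Match arrangement
appears twice. "Pseudorandomized" is operationalized as a
constrained shuffle with no arithmetic condition more than twice in a
row — the source design states only pseudorandomization, so the maximum
run length of two is this package's stated rule. Mismatch probes are
drawn uniformly from the digits outside the stored set; no further
exclusions are imposed.

## Synthetic data

No human recordings ship with the package; the synthetic module generates
data with exactly the statistical structure the analyses assume, which is
what makes the recovery tests meaningful — and is also their limit.
Passing tests show the machinery is correct and well calibrated under its
own assumptions, not that real BOLD data satisfy those assumptions
(no physiological noise spectrum, no hemodynamic variability across
regions or participants, no head motion, no error trials).

**Activations.** `simulate_activations()` draws
`psc(p, region, contrast) = scale_region * x(factor, contrast) + b_p + e`
with participant intercepts `b_p ~ N(0, participant_sd^2)` (per region,
matching the region-wise analysis) and residual `e ~ N(0, noise_sd^2)`.
This is the minimal generative model under which the mixed-effects
comparison below is well posed. Defaults: 20 participants,
`participant_sd = noise_sd = 0.05` percent signal change, and the winning
model's published per-region fitted scales (0.21, 0.21, 0.17, 0.13,
0.22) as region scales.

**Time series.** `simulate_bold()` integrates the bilinear neural model
(below) over the session design — repetition time 4.1 s, 72 volumes and
36 trials of 8.2 s per session, 8 sessions — convolves each region's
state with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
ratio 1/6, unit peak), samples at the scan times and adds iid Gaussian
noise. States restart at rest at session boundaries, mirroring session
concatenation. The driving regressor is a unit boxcar over the 1–3 s
window of every Linear and Quad trial; the modulatory regressor covers
the Quad trials only, so its support is nested in the driving support.

**Behavior.** `simulate_behavior()` draws per-participant accuracy and
reaction times from truncated normal distributions with the published
group means and standard deviations as defaults (accuracy clamped to
0–100%, reaction times floored at 200 ms).

## Factor-model fitting

The three contrasts against Match predict exactly zero signal when a
factor carries no differential load, so each factor is fitted with a
**no-intercept model**: one scale parameter multiplying the subtracted
estimates. On the participant-averaged contrast values this gives the
closed-form scale `sum(x y) / sum(x^2)`, the residual sum of squares, and
the no-intercept coefficient of determination
`r^2 = 1 − sum((y − ŷ)^2) / sum(y^2)` (total variation about zero, not
about the mean; it can be negative for bad models). Goodness of fit is
additionally probed by two-sided one-sample t-tests of the individual
activations against each fitted value, at a Bonferroni-corrected level
(`0.05 / 3 ≈ 0.0167` over the three contrasts by default; 0.0083 and
0.0125 are the corresponding presets for 6- and 4-member families used
elsewhere in the analyses).

Individual variability enters through a **random-intercept mixed model**
`y = scale * x + b_participant + e`, fitted by profiling the likelihood
over the variance ratio `rho = sigma_b^2 / sigma_e^2`: for fixed `rho`
the GLS scale and the residual variance have closed forms, leaving a
one-dimensional maximization. This direct implementation exists because
the model comparison needs likelihood evaluation at a *fixed* ratio
(notably the forced zero-variance boundary, which reproduces the
closed-form OLS likelihood exactly); the test suite cross-checks it
against `nlme::lme` to machine precision under both ML and REML.
Boundary solutions at zero random variance are reported, not raised.

`compare_factor_models()` fits all eight factors for a region, ranks them
by log-likelihood, and reports each model's likelihood ratio relative to
the best. **ML is the default ranking criterion**: REML likelihoods are
available (the original fits used REML) but comparing REML likelihoods
across models with different regressors is questionable, since the REML
contrast depends on the fixed-effects design; with a single scale
parameter per model the practical difference is small. Factors whose
subtracted estimates are all zero have no likelihood and are reported as
degenerate (n/a). An optional per-participant covariate (e.g. error
rates) can be residualized out of the activations before fitting —
centered within contrast so group means are preserved; off by default
for synthetic data.

## Effective connectivity

Three regions — L_IFG, L_IPS, R_IPS — with a fixed intrinsic skeleton of
bidirectional L_IFG–L_IPS and L_IPS–R_IPS connections and no direct
L_IFG–R_IPS edge. The neural dynamics are bilinear:

    dz/dt = (A + u_m(t) B) z + C u_d(t)

with `u_d` the driving input (Linear + Quad trials) and `u_m` the
modulatory input (Quad trials). The 18-model space crosses the three
possible driving-input regions with six modulation configurations (each
single directed connection, or either bidirectional pair); model 1 has
modulation on L_IPS→L_IFG and input into L_IFG. Self-connections are
fixed at −1 s⁻¹, the standard convention, and are not free parameters —
with three regions and a 4.1 s repetition time the self-decay is not
separately identifiable. Regressors are unit-height, so coupling
magnitudes are meaningful only under this input scaling; the recovery
study uses the same convention for generation and fitting, which is the
meaningful test.

**Inversion.** `fit_dcm()` maximizes the Gaussian likelihood of the
observed volumes through the full forward model (dynamics → HRF →
sampling). The driving weight enters the prediction linearly and is
profiled out analytically; the remaining four intrinsic and one or two
modulatory parameters are optimized by Nelder-Mead from zero with one
restart. Model evidence is summarized by BIC
(`−2 loglik + k log N`, `k` counting couplings, the driving weight and
the noise variance). This maximum-likelihood/BIC scheme and the
canonical-HRF observation model replace a variational inversion with a
biophysical hemodynamic model — a deliberate, desk-scale design: the
package's claims are about parameter and model *recovery* within its own
forward model, not equivalence with any neuroimaging suite's estimates.

**Numerics.** Fixed-step integration at `dt = 0.1 s`. Because the inputs
are piecewise-constant, the classic RK4 update with inputs frozen over a
step is a fixed linear map per input level; the integrator precomputes
one propagator pair per distinct modulatory level and applies one 3×3
matrix–vector update per step (arithmetically identical to stepwise RK4,
and falling back to it for continuously varying inputs). Intrinsic
matrices with any eigenvalue real part ≥ 0 are rejected before
simulation and given a penalty likelihood during fitting; diverging
trajectories (from transiently unstable modulated dynamics) are caught
and penalized likewise.

**Model selection.** `bms_rfx()` implements random-effects Bayesian model
selection: a variational Dirichlet posterior over model frequencies
(uniform prior, concentration 1), giving expected probabilities
`alpha / sum(alpha)`; exceedance probabilities — the probability that a
model is the most frequent in the population — by seeded Monte-Carlo
sampling of the Dirichlet posterior (10⁶ draws by default, accurate to
well under 0.005; an independently coded sampler in the tests agrees to
that tolerance). Group-level inference on the winning model's parameters
uses one-sample t-tests, Bonferroni-corrected within parameter class
(0.05 / 4 = 0.0125 for the four intrinsic connections).

**Recovery study.** `run_recovery_study()` simulates 20 participants from
model 1 with the published group-mean estimates as ground truth —
intrinsic (1.02, −0.82, 0.62, −0.55) for (L_IFG→L_IPS, L_IPS→L_IFG,
L_IPS→R_IPS, R_IPS→L_IPS), modulation 1.03, driving 0.71 — plus
between-participant variation (sd 0.1, redrawn until each participant's
intrinsic matrix is stable) and observation noise sd 0.05, roughly a
tenth of the stimulus-driven signal's standard deviation ("low noise").
Published values serve as *generative truth* for recovery, not as
quantities re-estimable from the unavailable human data. With all 18
models fitted per participant, model 1 wins the exceedance probability
and the recovered group means match the truth well within ±0.2.

## Problem sizes and reproducibility

The shipped tests run the recovery study at its full design size
(20 participants × 18 models × 8 sessions, a few minutes of CPU) and the
factor-model recovery at 100 replicates; unit tests use single-session
designs with the same per-session structure (6/6/6/18 trials), which the
stimulus generator supports at any session count. Every random step takes
an explicit seed, and seeded runs are bit-reproducible; `run_pipeline()`
writes byte-identical outputs for a fixed configuration.

## Known limitations

* Region-level only: no voxel data, no spatial inference, no
  preprocessing — upstream steps of the original analyses are out of
  scope by design.
* The generative models are the assumed ones; none of the recovery
  results certify behavior under model misspecification.
* The published full factor table may contain rows beyond the eight
  implemented here; only values confirmable from the available material
  are asserted.
* REML likelihood ratios across factor models carry the caveat above;
  use the ML criterion (default) for ranking.
* DCM coupling estimates are comparable across this package's runs, but
  not numerically with variational inversions of the same data under
  different priors and hemodynamics.
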