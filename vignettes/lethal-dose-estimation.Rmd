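---
title: "Lethal-dose estimation from colony counts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lethal-dose estimation from colony counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethaldose)
```

## The problem

Stress-tolerance assays for bacteria expose washed cell suspensions to a
graded stressor — UV or ionizing radiation, a DNA-damaging antibiotic such
as mitomycin C, hydrogen peroxide, or desiccation — and recover viable
counts (c.f.u.·mL⁻¹) by dilution plating after each exposure dose. The
quantities of interest are the median lethal dose LD50 and the decile
lethal dose LD10: the dose at which expected survival falls to 50% or 10%
of the unexposed baseline, plus whether two strains (typically a new
isolate and a well-characterised resistant control) differ in these.

The obstacle is that the number of cells at the start of each experiment is
unknown: plated counts are proportional to an unobserved inoculum that
varies between experiments. Survival *rates* therefore cannot be computed
directly, and classical logistic dose-response models do not apply. The
model used here treats the counts themselves as the response and absorbs
the inoculum into free intercept terms.

## The count model

For observation $i$ with strain $s(i)$, experiment $e(i)$ and dose $d_i$,

$$y_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\log \mu_i = \beta_0 + \alpha_{s(i)} + \gamma_{s(i),e(i)} + f_{s(i)}(\sqrt{d_i}),$$

where $\mathrm{NB}(\mu, \theta)$ has variance $\mu + \mu^2/\theta$ (Poisson
as $\theta \to \infty$), $\alpha$ is a strain main effect,
$\gamma$ is an experiment effect nested within strain (each repetition is
an independent batch with its own inoculum), and $f_s$ is a penalized
B-spline (P-spline) of square-root dose, one per strain. The square-root
transform spreads out the low-dose region of typical designs, which sample
densely at small doses and sparsely at large ones, and stabilises the
basis. A single dispersion $\theta$ is shared by all strains and
experiments, as in a standard negative binomial GAM.

Each smooth uses a cubic B-spline basis with (by default) 8 basis
functions on equidistant knots spanning that strain's observed
$\sqrt{\text{dose}}$ range, and a second-order difference penalty
$\lambda_s \sum_k (\Delta^2 c_k)^2$ on its coefficients. Smooths are
constrained to sum to zero over the strain's observed design rows (via a
QR null-space reparameterisation), so level differences live entirely in
the parametric terms; this makes the model identifiable with reference
coding for the categorical effects.

Counts are rounded to the nearest integer for the likelihood:
c.f.u.·mL⁻¹ values back-calculated from dilution plating may be
non-integral (e.g. averaged duplicates), and the NB likelihood requires
integers.

### Fitting

Coefficients maximise the penalized log-likelihood by Fisher-scoring IRLS
with step halving, so the penalized deviance never increases within an
IRLS run. The dispersion is profiled by damped Newton ascent on the NB
profile likelihood, one step interleaved with each short IRLS burst, so
$\beta$ and $\theta$ converge jointly; convergence is declared when the
relative change in penalized deviance falls below $10^{-8}$ (at most 200
iterations; a non-converged fit is returned with a warning and
`converged = FALSE`). Underdispersed data drive $\theta$ up a likelihood
plateau that is flat to machine precision; once the ascent passes
$10^7$ the dispersion is pinned at the upper bound $10^9$, which is the
Poisson limit for all practical purposes. The core iteration is
implemented in C++ (RcppArmadillo): the parametric bootstrap below refits
the model tens of thousands of times, and the per-fit cost is what makes
desk-scale inference practical.

### Smoothing selection

One $\lambda_s$ per strain is chosen by minimising the corrected AIC
$-2\ell + 2\,\mathrm{edf}\,n/(n - \mathrm{edf} - 1)$, where
$\mathrm{edf}$ is the trace of the hat matrix of the penalized fit, over a
log₁₀ grid from $10^{-4}$ to $10^{6}$ (11 points), by coordinate descent
across strains (two sweeps, candidates warm-started from the incumbent
fit). The criterion uses $-2\ell$ rather than the deviance because
$\theta$ is re-profiled at each candidate and the NB deviance's saturated
term depends on $\theta$, which would make raw deviances incomparable
across candidates. Grid search with coordinate descent was chosen over
gradient-based REML because it is simple, derivative-free and exactly
reproducible: the same data always select the same $\lambda$.

## Lethal doses

The model-based survival fraction of strain $s$ is
$S_s(d) = \exp(f_s(\sqrt d) - f_s(0))$ — predicted mean at dose $d$
divided by the predicted mean at dose 0, with all parametric terms
(including the unknown inoculum) cancelling in the ratio, so
$S_s(0) = 1$ exactly. The model baseline is used rather than the observed
dose-0 mean because the intercept absorbs the inoculum; designs without an
untreated point (desiccation series often start at 20 days) extrapolate
the linear predictor linearly from the boundary of the observed
$\sqrt{\text{dose}}$ range, the stable alternative to raw B-spline
extrapolation.

LD$p$ is the smallest dose with $S_s(d) \le p$, located by a 512-point
scan on a uniform grid in $\sqrt{\text{dose}}$ followed by interval
bisection to $|\Delta d| < d_{\max} \cdot 10^{-6}$. When the fitted curve
never reaches $p$ within the tested dose range the estimate is reported as
right-censored at the strain's maximum tested dose ("LD$p$ > $d_{\max}$")
rather than extrapolated: lethal doses outside the sampled design are
statements the data cannot support.

### Parametric bootstrap

Confidence intervals come from a parametric bootstrap: each replicate
draws new counts from $\mathrm{NB}(\hat\mu_i, \hat\theta)$ at the original
design points, refits the **full** model — including re-selection of the
smoothing parameters and re-estimation of $\theta$, so the intervals
reflect smoothing uncertainty — and records every strain's LD$p$.
Percentile intervals (2.5th/97.5th percentiles of the replicate draws) are
used as the simplest defensible choice; censored replicate draws enter the
order statistics at $d_{\max}$ and a bound landing on such a value is
flagged. Replicates that fail to converge are counted and excluded, with a
warning above 5% failures and a hard error above 50%. Between-strain
contrasts use the per-replicate difference LD$p$(a) − LD$p$(b) over
replicates uncensored for both strains; a 95% interval excluding zero is
reported as a significant strain difference. The default is 1000
replicates for analyses (199 in the package's own test runs), and the
whole draw sequence is reproducible from a single seed.

## The synthetic assay generator

Because raw colony-count data for such assays are rarely deposited, the
package includes a generator whose ground truth is known exactly.
Radiation-resistant bacteria characteristically show a *shoulder of
resistance* — survival near 1 up to a threshold dose, then exponential
decline — so the generator's curve family is

$$\log S(d) = -k\,\mathrm{sp}_s(d - D_0) + k\,\mathrm{sp}_s(-D_0),
\qquad \mathrm{sp}_s(x) = s \log(1 + e^{x/s}),$$

a softplus-smoothed hinge: $S(0) = 1$ exactly, $S$ is smooth and strictly
decreasing, pure exponential decay is the special case $D_0 = 0$, and in
the sharp-transition limit $s \to 0$ the true lethal dose has the closed
form $\mathrm{LD}_p = D_0 + \log(1/p)/k$ (in general `true_ld()` inverts
the curve numerically to $10^{-10}$). Counts are drawn as
$\mathrm{NB}(\text{baseline} \cdot e^{Z_e} \cdot S(d), \theta)$ with
log-normal experiment shifts $Z_e \sim N(0, \sigma_e)$ — multiplicative
batch effects matching the model's log link, and the mechanism that makes
the unknown-inoculum problem real in the synthetic data too.

Defaults emulate a two-strain assay (test strain and resistant control):
two independent experiment repetitions, duplicate plates, an expected
untreated count of $10^4$ c.f.u.·mL⁻¹, dispersion $\theta = 5$
(moderate plate-to-plate overdispersion), $\sigma_e = 0.2$ (batch effects
of roughly ±20%), and dose grids mirroring common designs: sampling times
$\{0, 1, 5, 10, 20, 40, 60, 120\}$ min for chemical stressors,
$\{0, 20, 40, 60, 80, 100\}$ days for desiccation, and a
$\{0, 2.5, \ldots, 12.5\}$ kGy-style radiation ladder. The default strain
curves (shoulders 2 and 0.5 dose units, decay rates 0.08 and 0.12,
transition width 1) were picked so both strains' LD50 and LD10 fall inside
the chemical-stressor grid.

What the generator does *not* emulate: real dose-measurement error,
between-plate spatial effects, counting error at high colony densities,
and any mechanistic damage-repair kinetics. Passing tests on synthetic
data therefore demonstrate statistical correctness of the estimation
machinery under the stated model, not biological validity of any
particular assay.

## Reporting

`run_ld_analysis()` drives the whole pipeline for one stressor and one or
two strains (two is the maximum, matching the one-test-strain-versus-
control design these assays use), writes the results CSVs, a
truth-comparison table when simulator ground truth is supplied, a manifest
JSON recording seed, $\lambda$, $\theta$, effective degrees of freedom and
failure counts, and the standard two-panel figure: observed mean counts
with fitted curves and LD markers on a log (or square-root) y-axis above,
and LD values plus strain differences as 95% intervals against a dashed
zero line below.

## Numerical choices, in one place

* IRLS tolerance $10^{-8}$ (relative penalized deviance), 200-iteration
  cap; step halving up to 40 times per update.
* $\theta \in [10^{-4}, 10^9]$; Newton steps damped to a factor of $e^2$
  per update; plateau snap above $10^7$.
* Smoothing grid $10^{-4} \ldots 10^6$, 11 points, 2 coordinate-descent
  sweeps, mid-grid start; ties resolved toward the first (smallest)
  candidate scanned.
* Basis auto-reduction: fewer distinct doses than basis functions reduces
  the basis to the number of distinct doses (warning), never below
  degree + 1; the penalty order is capped at the reduced dimension − 1.
* LD inversion: 512-point $\sqrt{\text{dose}}$ grid scan, then 64-ary
  interval refinement to $|\Delta d| < d_{\max} \cdot 10^{-6}$.
* A tiny ridge ($10^{-10}$) stabilises each weighted least-squares solve.

## Known limitations

**Dose-grid resolution bounds the accuracy of LD estimates.** When an LD
value falls inside a wide gap of the dose design (for the default chemical
grid, e.g. between 10 and 20 min), the spline can only interpolate across
the gap, and for convex (shouldered) survival curves that interpolation
systematically anticipates the crossing: LD point estimates in gaps are
biased toward the lower gap edge, with bias of the order of the gap width.
The parametric bootstrap resamples from the *fitted* smooth, so it
reproduces sampling variance faithfully but cannot see this bias;
coverage of bootstrap intervals for LD values inside wide gaps falls below
nominal (the package's own simulations at a sharp-shoulder curve with
LD50 between grid points 1 and 5 measure roughly 75% instead of 95%; the
same simulations with the LD near a sampled dose are close to nominal, and
between-strain *differences*, whose biases largely cancel for strains
measured on the same grid, hold their nominal type-I error). The practical
advice is the classical one: place doses so that the anticipated LD50 and
LD10 are bracketed tightly.

**Scaled counts are not NB-preserved.** Multiplying all counts by a
constant $k$ (a change of recorded units) is only distribution-preserving
in the Poisson limit; with moderate $\theta$, refitted fractions can move
by a few percent at $k = 8$. Inoculum size itself (a change in the
generating mean) is absorbed exactly by the intercept.

**No mixed-effects formulation.** Experiments enter as fixed effects; with
only two repetitions per strain a variance component would be poorly
identified, but designs with many repetitions would be better served by a
random effect.

**Problem sizes in the package's tests.** The automated suite runs the
coverage study at 60 datasets × 199 bootstrap replicates, type-I error at
100 datasets × 99 replicates, and parameter recovery at 100 datasets, with
Monte-Carlo bands computed from those sizes; `scripts/acceptance.R` runs
the full 200-dataset coverage study.
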