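---
title: "Bracketing deltas and two-tier uncertainty evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bracketing deltas and two-tier uncertainty evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbmc)
```

## The measurement model

In a standard–sample bracketing (SSB) run the instrument alternates between
an isotopic standard and the samples: every sample acquisition sits between
two standard acquisitions, and adjacent brackets share a standard. Each
acquisition integrates many cycles and is summarized by a mean isotope
ratio and the standard error of that mean. The delta value of one bracket
is

$$\delta = \left(\frac{\mu_s}{(\mu_{b1}+\mu_{b2})/2} - 1\right)\times 1000\ \text{‰},$$

the sample ratio against the unweighted arithmetic mean of the two
bracketing standard ratios. The rationale for the bracket mean is drift
cancellation: if the instrumental mass-bias factor varies linearly in time
and the sample acquisition sits midway between its brackets, the factor
cancels exactly; slow non-linear drift cancels to first order. A
multiplicative bias common to all three acquisitions cancels identically,
which `compute_delta` preserves to floating-point accuracy.

`pair_brackets` enforces the strict standard–sample–standard scheme: a run
must start and end on a standard, two consecutive standards simply hand the
bracket over, and two consecutive samples are rejected rather than averaged
— the delta of a bracket is defined for exactly one sample acquisition.

## Propagating acquisition precision into a delta

Writing $B = (\mu_{b1}+\mu_{b2})/2$, first-order propagation
(differentiation of the delta formula, equivalently a first-order Taylor
expansion in the three ratios) gives the per-delta standard error in per
mil:

$$SD_\delta = \frac{1000}{B}\sqrt{\sigma_s^2 +
  \frac{\mu_s^2}{4B^2}\left(\sigma_{b1}^2+\sigma_{b2}^2\right)}.$$

The derivation is checked two independent ways in the test suite: against a
central-finite-difference gradient combined in quadrature (agreement to
1e-6 relative), and against a brute-force sampler that draws the three
ratios from their error distributions and takes the empirical SD of the
resulting deltas (agreement within 1% at $10^6$ draws). First-order
propagation is adequate because relative acquisition errors in this setting
are of order $10^{-5}$–$10^{-3}$; second-order corrections enter at the
square of that and are far below the reported precision.

## Deviations, validation tests and the classical bound

For a sample with an accepted value $\delta^{true}$ the deviation of the
$i$-th measurement is $\Delta_i = \delta_i - \delta^{true}$. Deviations are
computed per sample and pooled across samples; the pooled population is
what a laboratory uses to state an uncertainty applicable to a future
sample of unknown true value. Two checks validate the pooled population:
a Shapiro–Wilk test of normality and a two-sided one-sample Student t-test
of zero mean (poor trueness shows up as a small t-test p-value). Both
return an explicit `NA` marker outside their validity range (fewer than 3
or more than 5000 observations for Shapiro–Wilk, degenerate variance for
either) rather than a silent default.

When no accepted value exists, the series' own mean delta substitutes for
the reference (`reference_source = "sample_mean"`). The consequences are
deliberate and exact: the average deviation is zero and the t-test p-value
is 1 by construction, while the spread of the series still contributes
genuine reproducibility information to the pooled SD. Report renderings
print `n.d.` in the reference column for such rows.

The classical expanded uncertainty is
$U_\Delta = z_{0.975}\,SD_\Delta$ with $z_{0.975} =$
`qnorm(0.975)` $= 1.959964\ldots$ — the exact quantile, not the rounded
1.96; the two agree at the two-decimal precision of the printed reports.
The SD convention is the sample standard deviation (n−1 denominator)
throughout, the usual choice for reproducibility estimates from limited
replicates.

## The Monte Carlo tier

$SD_\Delta$ ignores how precisely each individual delta was measured. The
Monte Carlo tier injects exactly that information: in run $r$ each
deviation is disturbed as $\Delta_i + \varepsilon_i^r$ with
$\varepsilon_i^r \sim N(0, SD_{\delta,i})$ drawn independently per
observation and per run, the sample SD of the disturbed set is recomputed
(per sample and pooled), and the reported $SD_\Delta^{MC}$ is the
arithmetic mean of the per-run SDs over all runs — the literal "average SD
over runs", which differs slightly (by Jensen's inequality) from the
root-mean-square alternative; the mean was chosen because it is the plainer
reading of "average" and the discrepancy is far below print precision at
these noise levels. The default is $10^6$ runs; the estimator is already
stable well below that (the suite checks $10^5$ vs $10^6$ agree within
0.5% relative on a fixed dataset).

Implementation notes, all of which are tested contracts:

* Noise is drawn observation-major within each run from one seeded
  generator, and per-run SDs are stored and averaged in a single pass, so
  the result is bit-identical for a given `(data, runs, seed)` and exactly
  independent of the internal chunk size (chunks exist only to bound
  memory).
* If every propagated SE is zero the disturbed set equals the original in
  every run, so the code returns the plain SD directly — an algebraic
  identity, making $SD_\Delta^{MC} = SD_\Delta$ exact at any run count.
* In expectation $({SD_\Delta^{MC}})^2 \approx SD_\Delta^2 +
  \overline{SD_\delta^2}$; the constant-SE variance-addition limit
  $\sqrt{SD_\Delta^2+\sigma^2}$ is verified within 2% at $n=500$,
  $10^4$ runs.
* Scale equivariance: scaling all deltas, references and SEs by $c>0$
  scales every reported SD and U by $c$ (checked with matched seeds).

The per-row diagnostic compares the two tiers: if
$SD_\Delta^{MC}/SD_\Delta$ stays below a threshold (default 1.5) the
uncertainty is dominated by reproducibility between deltas; a large ratio
(tight repeatability but large per-delta SEs) flags that the absolute
ratios were measured with comparatively low precision —
`"measurement-precision-dominated"` in the report.

## What the simulator emulates — and what it does not

`simulate_run` generates ratio-level acquisitions directly: a standard of
true ratio $R_0$ (default $8.731/23.772$, the 82/78 natural-abundance
ratio), samples at $R_0(1+\delta^{true}/1000)$, a multiplicative drift
factor per position, and relative noise with SD
`cycle_rsd/sqrt(n_cycles)` per acquisition mean, with the matching nominal
`std_error` column. Noise is placed on ratios, not on per-isotope
intensities: every downstream computation starts from ratio-level means
and standard errors, so intensity-level simulation would add surface
without adding testable behavior. Blank correction, interference physics
and plasma chemistry are likewise out of scope — the simulator validates
the statistics, not the spectrometry.

Drift models: `"none"`; `"linear"` ($1 + \text{rate}\cdot t$, with
acquisition time equal to sequence position, so each sample sits exactly
midway between its brackets and the cancellation is exact — the suite
requires recovery of $\delta^{true}$ to 1e-9 ‰); and `"random_walk"`, a
geometric random walk with per-step relative SD equal to the rate. The
random walk is the interesting one: bracketing does not fully cancel it,
and the residual per-bracket delta scatter is approximately
$1000\cdot\text{rate}\cdot\sqrt{2}/2$ ‰, which acts as the run's
reproducibility component.

Default magnitudes were fixed once, from the scales a selenium
hydride-generation MC-ICP-MS campaign actually exhibits: drift rate
$10^{-4}$ per acquisition (per-bracket scatter ≈ 0.07 ‰, the typical joint
reproducibility SD), and `cycle_rsd` $5\times10^{-4}$ over 60 cycles
(propagated per-delta SEs ≈ 0.08 ‰, within the 0.05–0.15 ‰ range seen on
real error bars). They are configuration, not claims, and are overridable.

Passing simulator-based tests shows the estimators behave correctly under
the stated model — independent near-normal noise, stationary drift, honest
`std_error` columns. Real runs can violate all three (correlated
plasma fluctuations across a bracket, session boundaries, SE estimates
that are themselves noisy), so simulated coverage does not certify
real-data coverage; the validation tests on pooled real deviations are the
field check.

## The coverage experiment

`coverage_experiment` makes the 95% claim falsifiable within the model:
for each replicate it simulates an independent campaign, computes the
pooled $U_\Delta^{MC}$ from a calibration subset of the deltas (deviations
taken against the known true values), and counts how often the held-out
deltas of the same campaign fall within $U$ of truth.

One structural point decided the default configuration. The Monte Carlo
bound treats deviation spread and per-delta SE as independent components to
be added, but measured deltas already contain their measurement noise —
so when per-delta SEs are comparable to the total scatter the bound
double-counts and intentionally over-covers. That conservatism is the
point of the method (it guards against understating uncertainty), but it
means the bound is *nominally* calibrated only in the regime where
per-delta SE is a minor variance component. The nominal-coverage check
therefore uses a drift-dominated configuration (random-walk scatter
≈ 0.07 ‰, propagated SEs ≈ 0.02 ‰), for which predicted coverage is just
above 0.95; the suite requires the empirical fraction over 1000 held-out
deltas to land in [0.93, 0.97]. With zero noise the bound degenerates to
zero width and coverage is exactly 1 (a 1e-9 ‰ absolute guard in the
comparison absorbs the floating-point residue of noiseless delta
recovery).

A robustness probe replaces the noise with a variance-matched Student t
(3 degrees of freedom). Two effects compete: a unit-variance $t_3$ has a
*smaller* 0.975 quantile than the normal (1.84 vs 1.96), which alone would
make the bound conservative, but finite-sample SD estimates from
heavy-tailed data are volatile, and coverage is concave in the estimated
SD, which drags the average down. Empirically the second effect wins at
the calibration sizes used here: coverage falls to ≈ 0.94, below nominal —
the documented model-violation behavior the suite asserts.

## Numerical and design choices

* Delta values are dimensionless ratios scaled to ‰; reports round to two
  decimals for display while machine-readable key-value output retains
  full double precision and round-trips bit-exactly.
* Reference tables may list several literature values per material; the
  working reference is their mean (the same convention used when a cited
  source itself reports repeated values), with the individual values and
  citations retained.
* Degenerate inputs are contracts, not corner cases: zero-variance series
  yield zero SDs and U's with `NA` test markers; single-observation series
  have no SD and propagate `NA`; empty runs, unbracketed samples and
  malformed files fail with located errors.
* Pooled ("jointly") statistics concatenate the per-sample deviations;
  the joint `n` is the sum of per-sample counts, and the joint tests run
  on the concatenated set.
* Problem sizes in the shipped tests were chosen to exercise the
  asymptotics the claims rely on while keeping the suite quick: $10^6$
  draws for the propagation oracle, $10^4$–$10^6$ Monte Carlo runs, 100–300
  replicate campaigns with 1000+ held-out deltas for coverage.

## Limitations

* The uncertainty budget covers ratio-measurement statistics only — no
  weighing, dilution, blank or digestion terms (no full GUM budget), and
  no outlier rejection.
* The propagated-SE formula assumes independent errors across the three
  acquisitions of a bracket; shared short-term plasma fluctuations violate
  this and push the Monte Carlo tier further toward conservatism.
* Mean substitution makes a sample's own trueness untestable (its t-test
  is 1 by construction); only samples with literature values inform
  trueness.
* The simulator's drift and noise families are stationary; it does not
  emulate session boundaries, memory effects, or blank drift.
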