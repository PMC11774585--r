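---
title: "Methods: quantifying the replicability of microbial growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the replicability of microbial growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthvar)
```

## The question and the measure

Replicate wells of a microplate growth experiment never grow identically.
`growthvar` quantifies that well-to-well variability per *experiment* (all
replicate curves of one strain under one condition) and tests whether a
paired condition — here, trace-element supplementation of a defined
medium — changes it. Variability is measured by the coefficient of
variation, CoV = σ/μ, of a growth characteristic across replicate wells.
A ranked (robust) alternative is deliberately not offered: trace-element
contamination is expected to produce *meaningful* outliers, and a robust
statistic would discard exactly the signal of interest.

Two characteristics are extracted per well:

* **Yield**: the 98th percentile of baseline-subtracted OD inside a time
  window shared by the whole experiment.
* **Growth rate**: the low-density exponential rate $r$ of a logistic fit
  inside an OD window shared by the whole experiment, reported in
  h$^{-1}$.

Percentiles use the linear-interpolation convention with fraction
$(n-1)q$ (R's `type = 7`) everywhere — one convention for the yield, the
preliminary yield, and the outlier-flag threshold.

## Preprocessing

1. **Baseline**: the expected OD of the sterile medium is estimated as
   the median over curves of each curve's minimum OD and subtracted from
   every measurement of the experiment. The median is robust against
   individual wells with condensation or early growth.
2. **Condensation trimming**: points before a curve's *first local
   minimum* are removed; early OD bumps come from lid condensation, not
   growth. The first local minimum is defined as the smallest index $i$
   with $\mathrm{od}_i \le \mathrm{od}_j$ for every $j \le i+1$: the
   point is the minimum of its whole prefix and not above its successor.
   This rule is deterministic, returns index 0 for monotone curves, and
   keeps the first point of a tied plateau. Trimming runs on raw values;
   the length-5 running median of `median_filter()` is display-only.
3. **Candidate flags**: wells whose pre-trim, baseline-subtracted
   minimum OD exceeds 0.01 are condensation candidates; wells whose
   preliminary yield (98th percentile of the full trimmed trace) exceeds
   1.5 times the experiment's 90th percentile of preliminary yields are
   biological-contamination candidates. Applying the condensation
   criterion after baseline subtraction is a choice — the narrative
   order of the underlying protocol suggests it, but it is not explicit —
   and the threshold is configurable. Flags are candidates: the
   reference workflow reviewed them manually (excluding most), which no
   algorithm can replicate, so `preprocess_experiment()` defaults to
   reporting them and `auto_exclude = TRUE` (the `run_analysis()`
   default, where no human is in the loop) excludes them all.

## Window selection

Fixing one analysis window per experiment, rather than per well, removes
a per-well selection freedom that would otherwise leak into the
variability estimate. Each window is chosen by minimizing an objective
that combines low variability with a structural criterion:

* **Yield window** (time interval): minimize
  $\mathrm{CoV}(\text{yields}) \cdot \overline{r^2}$, where
  $\overline{r^2}$ is the squared Pearson correlation of OD with time,
  averaged over curves. Low $\overline{r^2}$ favours stagnant growth,
  i.e. saturation. Constraints: the window must not begin before the
  median time at which curves exceed 0.7 of their preliminary yield, and
  the start must lie between 0.5 and 0.9 of the end (time counted from
  the observation start, which makes the selection invariant under time
  shifts).
* **Rate window** (OD interval, searched in $\log_{10}$ OD): minimize
  $\mathrm{CoV}(\text{rates}) \cdot \overline{1 - r^2}$, where $r^2$ is
  the coefficient of determination of each curve's fit — the badness of
  fit. Constraints: the lower edge between 0.001 and 0.1 of the
  experiment's median yield, the upper edge at most the median yield,
  and a span of 0.7 to 3 decades.

The printed expression for the rate objective is typographically
ambiguous between $\mathrm{CoV}\cdot(1-\overline{r^2})$ and
$\mathrm{CoV}\cdot\sqrt{1-\overline{r^2}}$; the package implements the
product with the mean badness (`badness_transform = "identity"`) and
offers the square-root reading as a configuration option. "The yield"
bounding the upper edge is read as the experiment's *median* yield,
since a single window is shared by all curves.

Both searches evaluate the objective exhaustively on a
`grid_steps`² lattice (default 100, the reference procedure's value) and
then refine with a Powell-style direction-set minimizer under a
quadratic constraint penalty (tolerance $10^{-6}$ relative, at most 500
line minimizations, result clipped to the feasible region). The finisher
is accepted only if it improves on the lattice optimum, so it can never
make things worse. Infeasible windows — fewer than 2 points of a curve
(yield) or 4 points (rate), or fewer than two surviving curves — carry
an infinite objective.

**Tie-breaking.** Exact objective ties arise only in the degenerate
zero-variability limit (identical curves ⇒ CoV = 0 ⇒ objective 0 on
every feasible window). Ties are broken toward the latest, then longest
yield window (the stagnation region) and toward the highest rate window
(largest lower edge, then largest upper edge), where the signal is
strongest and the baseline estimate matters least. A smallest-first rule
would select pre-saturation times and the noise-dominated lowest OD
decade in exactly the situation where the data give no other guidance.
On noisy data, ties do not occur and the rule is irrelevant.

## The logistic fit

The model is the standard logistic
$N(t) = K N_0 e^{rt} / (K + N_0 (e^{rt} - 1))$, with $r$ the low-density
exponential rate. The fit minimizes squared residuals of $\log$ OD —
growth spans decades, and the window search operates in log OD space —
reparameterized as $\log N(t) = \log K - \log(1 + e^{-r(t - t_m)})$ with
$t_m$ the half-saturation time. For fixed $(r, t_m)$ the optimal
$\log K$ has a closed form and is profiled out, capped at
`k_cap_factor` (default 1000) times the curve's maximum OD. The cap is
deliberately liberal: as $K \to \infty$ the logistic degenerates to pure
exponential growth, so exponential curves are a special case rather than
a failure. The remaining two-parameter problem is solved by a compiled
Nelder–Mead (absolute SSE floor $10^{-22}$ so that machine-precision
fits terminate), restarted from two half-saturation-time guesses plus a
polish step — the window search performs tens of thousands of fits, so
the inner loop is the performance-critical primitive and results are
memoized per curve and point subset during the search. Non-convergence
(optimizer failure, non-finite values, rate below $10^{-8}$, or a
zero-variance log-OD segment) falls back to a straight-line regression
of log OD on time (`fit_type = "exponential_fallback"`). $r^2$ is
computed in the fitting space; a zero-variance segment reports
$r^2 = 0$, the same convention the yield objective uses for
zero-variance OD. A linear-OD-space fit (`fit_space = "linear"`) is
available for comparison.

**Accuracy floor from the baseline.** The baseline estimate (median of
per-curve minima) inevitably absorbs the inoculum OD $N_0$: on
noise-free data the analysed signal is $N(t) - N_0$, which is not
exactly logistic. A window scan on noise-free curves
($r = 0.6\,h^{-1}$, $K = 0.8$, $N_0 = 0.001$) shows no feasible rate
window recovers $r$ better than about 0.4%. The package therefore
documents recovery of the *full pipeline* (preprocessing included) to
within 1% of truth, of order $N_0/\mathrm{OD}_{\text{window}}$, while
the fit itself recovers exactly-logistic input to 0.1% and better.

## Statistics

* **Per strain**: the two experiments (with/without supplement) are
  compared by a permutation test: each group is divided by its own mean
  (so only relative spread matters), pooled, and re-split at the
  original sizes 10 000 times; the statistic is the CoV difference
  "without minus with". The reference procedure names no statistic; the
  difference is the standard exchangeability-compatible choice, and the
  ratio is left out because its permutation null is equivalent. P-values
  use the add-one convention (never exactly 0); an exhaustive option
  enumerates all splits for small groups. The CoV ratio
  $\kappa = (\sigma_w/\mu_w)/(\sigma_o/\mu_o)$ summarizes the effect
  ($\kappa < 1$: supplementation reduces variability).
* **Per study**: Wilcoxon's signed-rank test of the null that the
  median of $\log \kappa$ is zero — the log makes the null distribution
  symmetric, as the test requires. $\kappa = 1$ entries are dropped; the
  exact distribution is used up to 25 strains (sign-assignment
  enumeration when absolute log ratios tie), the continuity-corrected
  normal approximation beyond. Yield and growth rate are tested
  separately — pooling them would pseudoreplicate. Per-strain
  permutation p-values are reported raw with α = 0.05 decisions; the
  study-level claim rests on the single Wilcoxon test per measure.
* **Mean–variability correlation**: Pearson's r between the per-
  experiment means and CoVs, tested by re-pairing permutations instead
  of the t-distribution, whose normality assumption these small samples
  do not support.
* **Element panel**: per element, a Mann–Whitney U test of procedure
  samples against negative controls — exact by full enumeration of rank-
  sum splits (mid-ranks for ties) up to a combined n of 20, one-sided by
  default since the hypothesis is directional (the procedure *adds*
  contamination; sidedness is configurable as the reference does not
  state it). Fold changes are ratios of group medians (robust at n = 4;
  configurable to means; a mean-based reading of the reference values
  cannot be excluded). Elements entirely below the detection limit are
  "not evaluable", not p = 1. P-values are combined by the
  Mudholkar–George logit method,
  $t = -\sqrt{\tfrac{15k+12}{(5k+4)k\pi^2}} \sum_i \log\tfrac{p_i}{1-p_i}$
  against Student-t with $5k+4$ degrees of freedom, separately for
  supplement and additional elements; lead isotopes are combined the
  same way first. This is the standard continuous combination; a
  discreteness-aware variant of the underlying exact tests exists but
  its corrections are not reproducible from the available description.

## The synthetic-data generator

`generate_experiment_pair()` realizes the mechanism the analysis is
built to detect: every well draws a log-normal (heavy-tailed)
trace-element contamination $c_w$; the effective concentration
$s + c_w$ (supplement $s$, 0 in the unsupplemented condition) sets the
well's rate and carrying capacity through the saturating dose-response
$v_{\min} + (v_{\max}-v_{\min})\,c/(c + h)$. Because the dose-response
derivative falls with concentration, the same contamination spread
produces more variability at $s = 0$ — classical error propagation. The
contamination vector is shared between the two conditions (matched
pairs), so the comparison isolates the supplement effect. On top:
Gaussian OD noise, a baseline offset, sporadic condensation wells (a
decaying initial OD bump) and sporadic biologically contaminated wells
(carrying capacity multiplied by `bio_contam_factor`).

Defaults are the emulated study's conditions: 80 wells per condition,
20-min sampling over 48 h, $N_0 = 0.001$, baseline OD 0.08. The
dose-response scale is arbitrary, so concentrations are expressed in
units of the half-saturation ($h = 1$); the contamination distribution
LogNormal(log 0.2, 0.8), value span ratio $v_{\min}/v_{\max} = 1/3$
(rates 0.2–0.6 h$^{-1}$, capacities 0.2–0.6 OD) and supplement
$s = 0.19$ were fixed once, by Monte-Carlo on the generator's
closed-form truth (2×10⁶ draws, before any pipeline code ran), to give a
true unsupplemented CoV near 17% and a true with/without CoV ratio near
2/3 for both measures — the variability scale and reduction the emulated
study reports. `generate_study()` scales each strain's rate and
capacity ranges by independent log-normal factors (SD 0.15); since both
dose-response limits scale jointly, the true CoV ratio is the same for
every strain.

What the generator does *not* emulate: plate-position (edge) effects,
nutrient-depletion dynamics or multi-element interactions, lag phases,
instrument drift, and any correlation of contamination across wells.
Passing tests therefore demonstrate that the pipeline recovers the
statistics of *this* mechanism, not that real plates are free of other
structure.

## Validation problem sizes

The test suite validates at desk scale: window-search oracle agreement
on 12×12 lattices over twenty 8-curve, 30-point experiments; fit
recovery on 8-curve, 145-point noise-free experiments; permutation-test
calibration with 500 null replicates of 40-vs-40 at 1000 permutations;
and one full 11-strain, 80-well study analysed on a 10-step lattice with
200 permutations per test. The acceptance script
(`scripts/acceptance.R`) re-runs the 11-strain study at 2000
permutations. The lattice default of 100 steps is retained for real
analyses; the coarser lattices used in the examples change the selected
windows only marginally because the objectives are piecewise constant in
the window bounds.

## Known limitations

* The baseline rule bounds rate accuracy at roughly
  $N_0/\mathrm{OD}_{\text{window}}$ (see above); with realistic noise
  this is far below the measurement floor, but it is visible in
  noise-free simulations.
* Automatic exclusion applies *all* candidate flags; a manual-review
  step can retain flagged wells that an expert would keep.
* The Mann–Whitney normal approximation (combined n > 20) is never
  exercised by the default 4-vs-4 design.
* $\kappa$ is undefined for zero-variance groups (noise-free synthetic
  data); such strains are dropped from the study-level test, which then
  reports p = 1 when nothing remains.
* The generator's contamination distribution is illustrative — it
  realizes a heavy tail of plausible scale, not an estimate of any
  particular laboratory's labware.
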