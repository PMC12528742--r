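---
title: "Interval estimation of insect thermal summation parameters with Weibull mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval estimation of insect thermal summation parameters with Weibull mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermomix)
```

## The model

Insect development under constant temperature is classically summarized by the
law of total effective temperature: an individual completes development when
the accumulated degree-days above its lower developmental threshold reach the
thermal constant,

$$k = D\,(T - t_0),$$

with $D$ the development time (days), $T$ the rearing temperature (°C) and
$t_0$ the threshold below which development pauses. In forensic entomology $k$
and $t_0$ are the quantities that turn a beetle or fly found on remains into a
minimum post-mortem interval, so the question "how precisely do we know $k$?"
matters directly in casework.

`thermomix` treats $K$ as a **random variable**, not a constant: individuals
vary, rearing cohorts are heterogeneous (large vs. small individuals, regular
results vs. outliers), and a point estimate of $k$ hides all of that. The model
is a finite mixture of Weibull distributions,

$$K \sim \sum_{l=1}^{L} w_l \,\mathrm{Weibull}(\kappa_l, \lambda_l),
\qquad k_i = D_i\,(T_i - t_0^{(l)}),$$

where each component $l$ carries its own weight $w_l$, shape $\kappa_l$, scale
$\lambda_l$ (degree-days) and — unusually — its own threshold $t_0^{(l)}$,
treated as a parameter of the probability distribution and estimated jointly
with the rest. Because the data are observed as $(D_i, T_i)$ pairs rather than
$k_i$ values, the likelihood for one record is a mixture of transformed Weibull
densities,

$$f(D_i \mid T_i) = \sum_l w_l\, f_W\!\big(D_i (T_i - t_0^{(l)});\,
\kappa_l, \lambda_l\big)\,(T_i - t_0^{(l)}),$$

where the factor $(T_i - t_0^{(l)})$ is the Jacobian of the change of variables
from $K$ to $D$. It is easy to drop this factor by accident — one then fits
$k$-values computed at a fixed provisional threshold instead of the full
change-of-variables likelihood — and the two are not equivalent when
thresholds differ across components; `thermomix` always includes it.
Temperature is conditioned on as a fixed covariate: under a randomized
temperature design $T$ carries no information about the mixture parameters, so
conditioning loses nothing while keeping the likelihood simple.

Two kinds of interval follow from a fitted model, and they answer different
questions:

* an **interval estimate** of realizations, $[Q(\tfrac{1-\gamma}{2}),
  Q(\tfrac{1+\gamma}{2})]$ with $Q$ the (mixture or component) quantile
  function, brackets a stated fraction $\gamma$ of actual individuals and does
  **not** shrink as data accumulate — this is the object to use when
  estimating an insect's age from remains;
* a **confidence interval** for $\mathrm{E}[K] = \sum_l w_l \lambda_l
  \Gamma(1 + 1/\kappa_l)$ describes the precision of the estimator and shrinks
  like $1/\sqrt n$.

Conflating the two is exactly the mistake the package's baseline comparison
quantifies: taking the classical Ikemoto–Takai point estimate of $k$ ±1.96
standard errors produces an interval of the second kind and then uses it as if
it were of the first kind. Its empirical coverage of real individuals falls
far below the nominal 95% — and falls further the larger the dataset.

## Fitting: EM with a threshold parameter

`em_fit()` maximizes the mixture likelihood by
expectation–maximization. The E-step computes responsibilities in log space
(densities are floored at $10^{-300}$ so a single far-tail record cannot zero
out a responsibility row). The
M-step for each component profiles the weighted Weibull likelihood: for fixed
$t_0$ the transformed values $k_i = D_i (T_i - t_0)$ admit the standard
weighted Weibull MLE (a one-dimensional root for $\kappa$ on its score
equation, then $\lambda$ in closed form), and the resulting profile is
maximized over $t_0$ by bounded one-dimensional search. If the numeric search
ever fails to improve a component's weighted objective, the incoming
parameters are kept, which guarantees the EM ascent property; the per-restart
log-likelihood trajectories are stored on the fitted object and asserted
non-decreasing in the test suite.

Choices a user can tune (`fit_config()`), with their defaults and reasons:

* `n_components = 2` — the typical finding for the carrion beetle datasets
  this model was developed on; `select_n_components()` offers BIC selection
  with $p = 4L - 1$ free parameters when the count is genuinely unknown.
* `n_restarts = 10` — the likelihood is low-dimensional but multimodal in the
  component split; the first restart is deterministic (quantile slices of
  provisional $k$-values, method-of-moments Weibull parameters, provisional
  $t_0$ from the linear degree-day fit) and later restarts jitter $t_0$ within
  ±2 °C and reshuffle group assignments under the configured seed.
* `tol = 1e-8` (absolute log-likelihood change), `max_iter = 500` —
  conservative for a smooth 7-parameter model; with warm starts (bootstrap
  refits) far fewer iterations are needed and a looser `tol` is sensible.
* `t0_margin = 0.5` °C — the likelihood requires $T > t_0^{(l)}$ for every
  record, so thresholds are searched in $[\min T - 30, \min T - 0.5]$ °C.
  Published fits sit 3–5 °C below the lowest viable rearing temperature, well
  inside this box.
* shapes are constrained to $[0.5, 200]$ — outside that range the Weibull is
  either implausibly heavy-tailed or numerically degenerate for these data.

Components are reported sorted by expected K ascending, with the original EM
labels kept in an `em_label` column, so that "component 1" is stable across
runs and tests.

## Labeling components

`label_components()` encodes two published decision rules. If one component
dominates (weight ratio ≥ `dominance_ratio`, default 3 — chosen so that a
0.87/0.13 split fires the rule and a 0.59/0.41 split does not) **and** neither
body length (two-sided Mann–Whitney U) nor sex ratio (2×2 chi-squared without
continuity correction) differs significantly at `alpha` (default 0.05), the
dominant component is labeled *regular* and the rest *outlier*. Otherwise a
significant size difference labels the smaller-mean-length component
*small_insect* and the other *large_insect*. Everything else stays
*unlabeled*, with all test evidence recorded. Records missing length are
dropped pairwise from the U-test; weight is deliberately not used (published
population summaries report length). The weighted midpoint of component mean
lengths is recorded as information only — any fixed large/small cut-off is
likely laboratory-specific.

## Intervals

`k_interval()` uses equal-tailed central quantiles: the closed-form Weibull
quantile for a single component, and bisection on the monotone mixture CDF
(bracket $[0, 10\lambda_{\max}]$, relative tolerance $10^{-9}$) for the
combined population. Central intervals — rather than highest-density regions —
reproduce the published reference intervals for both species to the printed
integer, e.g. [315, 461] degree-days for the combined *Necrodes littoralis*
population.

`age_interval()` converts to days. For one component the k-endpoints are
divided by $(T - t_0^{(l)})$. For the combined scope the components have
different thresholds, so the package inverts the development-time mixture CDF
$F_D(d \mid T) = \sum_l w_l F_W(d(T - t_0^{(l)}))$ directly; dividing combined
k-quantiles by any single temperature excess would be wrong whenever the
thresholds differ. The reference-table ambiguity of quoting one $t_0$ next to
a combined-population interval is resolved by carrying every component's
threshold in an annotation column of `interval_table()`.

`mean_k_ci()` is a parametric bootstrap: refit the model on `n_boot` datasets
sampled from the fitted mixture under the same $n$ and temperature design and
take percentile intervals of the replicate mixture means. Replicate refits are
warm-started at the point fit with a single restart — replicates are small
perturbations of the fitted model, so cold multi-restart refits would add cost
but not coverage. More than 20% failed replicates aborts with an error rather
than returning a quietly biased interval.

## The synthetic-data generator

The original rearing datasets (174 *Creophilus maxillosus* and 954 *Necrodes
littoralis* individuals) are not publicly available, so `sample_dataset()`
emulates their structure: a component is drawn by weight, a temperature from
the rearing design, $K$ from the component's Weibull law, and the development
time is set to $D = K/(T - t_0^{(l)})$; body length is normal per component
(truncated at zero) and sex is balanced Bernoulli. `species_preset()` ships
both species' published mixture coefficients, mean lengths and rearing
designs (the three extreme *C. maxillosus* temperatures with near-total
mortality are excluded, as in the source analyses). Per-temperature cohort
sizes and length SDs were never published; the presets default to uniform
temperature allocation and a 0.8 mm length SD, values typical of laboratory
rearing tables, and both are adjustable.

What the generator deliberately does **not** emulate: mortality and censoring
(individuals that died simply never appear, as in the source data), within-
stage sub-models, fluctuating temperature histories, and any dependence of
sex or size on temperature. Tests that pass on this generator therefore
demonstrate correctness of the estimation machinery under the model's own
assumptions — not robustness to field data that violate them.

## Numerical and scale choices in the test suite

The suite sizes its simulations to run in minutes on one CPU while leaving no
property untested at a meaningful scale: parameter recovery uses $n = 2000$
records from the *N. littoralis* preset (weights recovered within ±0.05,
scales ±3%, shapes ±20%, thresholds ±0.7 °C); calibration checks 10,000 fresh
records against the generating model's 95% age intervals (coverage 0.95 ±
0.01); the EM ascent property is asserted on 100 random two-component
instances of $n = 120$; the method comparison uses $n = 2000$, where the
SE-based baseline's under-coverage is already decisive. Bootstrap tests use a
looser convergence tolerance (`tol = 1e-5`) and small `n_boot`, which affects
interval wobble but not the contracts being tested.

One property worth flagging honestly: even on single-population data the
SE-based baseline does not approach the mixture method's coverage — at
$n = 2000$ its interval covers only a few percent of realizations, because a
shrinking confidence interval can never track the non-shrinking spread of
individual development times. The two approaches agree only in the
small-sample regime where the SE interval happens to be as wide as the
realization spread.

## Known limitations

* Component labels are probabilistic; individual records near the component
  overlap can be hard-assigned to the wrong population. Aggregate conclusions
  are robust to rare misclassification, individual ones are not.
* The EM initialization and selection defaults are this package's documented
  choices; other reasonable choices could reach different local optima on
  pathological data (hence the restart mechanism and ascent assertions).
* Datasets truncated to the fastest developers (common in dipteran studies)
  can be fitted, but the resulting intervals then describe the fastest
  fraction, not the population.
* No handling of fluctuating temperatures: the thermal constant is applied to
  constant-temperature rearing only.
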