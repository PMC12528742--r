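# thermomix

Interval estimation of insect thermal summation parameters by finite Weibull
mixture models, for forensic entomology and insect development modelling.

## The problem

Under constant temperature, an insect completes development when its
accumulated degree-days above a lower developmental threshold reach the
thermal constant:

    k = D (T − t0)

with `D` the development time (days), `T` the rearing temperature (°C) and
`t0` the threshold (°C). Post-mortem interval estimation from carrion insects
rests on these parameters, yet the classical estimators (the linear degree-day
regression and the Ikemoto–Takai linearization `DT = t0·D + k` fitted by
reduced major axis regression) produce point estimates — and the common
practice of quoting `k̂ ± 1.96 SE` produces a *confidence interval for the
estimator*, which shrinks with sample size and therefore covers far fewer
than 95% of actual individuals.

`thermomix` instead treats the thermal constant `K` as a random variable
following a finite mixture of Weibull distributions, each component with its
own weight `w_l`, shape `κ_l`, scale `λ_l` and threshold `t0^(l)` — the
threshold being a parameter of the distribution, estimated by an EM algorithm
with a profiled M-step. A fitted model yields:

* **interval estimates** of `k` capturing a chosen fraction of individuals
  (`k_interval`), per component or for the combined mixture;
* **development-time (age) intervals** at any temperature (`age_interval`);
* **component population labels** — regular vs. outlier, large- vs.
  small-insect — via published decision rules backed by Mann–Whitney and
  chi-squared evidence (`label_components`);
* **bootstrap confidence intervals** for `E[K]` (`mean_k_ci`);
* **empirical coverage comparisons** against the classical baselines
  (`compare_methods`).

A synthetic-data generator (`species_preset`, `sample_dataset`) replicates
the statistical structure of the two published carrion beetle datasets
(*Creophilus maxillosus*, *Necrodes littoralis*), whose raw data are not
publicly available.

## Worked example

```r
library(thermomix)

design <- species_preset("necrodes_littoralis", n = 954, seed = 42)
d      <- sample_dataset(design)                    # synthetic rearing data
fit    <- em_fit(d, fit_config(n_components = 2, n_restarts = 3, seed = 42))
fit
#> Weibull mixture for the thermal constant K (2 components)
#>    weight  shape  scale      t0 em_label mean_K
#> 1 0.38175 14.733 400.85  9.3648        1 386.86
#> 2 0.61825 13.357 423.71 10.1876        2 407.60
#> loglik -2922.9685 on 954 obs, 158 EM iterations, converged: TRUE
```

The generating preset has weights 0.41/0.59, shapes 14.57/13.67, scales
394.44/423.95 and thresholds 9.52/10.21 °C — recovered here from 954
simulated individuals. Intervals follow directly from the fit:

```r
k_interval(fit, 0.95)
#> 95% interval (combined): [317.4324, 462.3899] degree-days
age_interval(fit, temp = 18, level = 0.95)
#> 95% development-time interval at 18.00 C (combined): [38.021, 59.181] days
```

That is: 95% of individuals of this population accumulate between ~317 and
~462 degree-days, i.e. take between ~38 and ~59 days at 18 °C. Component
labeling and the baseline comparison:

```r
label_components(d, fit)
#> Labeled mixture components:
#>   component 1 (weight 0.382): large_insect
#>   component 2 (weight 0.618): small_insect
#> rule fired: size_split

compare_methods(d, fit_config(n_restarts = 3, seed = 42))
#> Interval estimates and empirical coverage at nominal 95%:
#>         method         scope k_lower k_upper coverage
#>       proposed      combined   317.4   462.4    0.945
#>  ikemoto_takai ikemoto_takai   356.3   369.7    0.115
```

The mixture intervals cover 94.5% of individuals, near the nominal 95%; the
`±1.96 SE` interval around the Ikemoto–Takai point estimate covers 11.5% —
the under-coverage that motivates the method.

A command-line wrapper over the same functions ships in
`inst/cli/thermomix.R`:

```sh
Rscript inst/cli/thermomix.R simulate --preset necrodes_littoralis --n 500 --seed 7 --out sim.csv
Rscript inst/cli/thermomix.R fit sim.csv --components 2 --seed 7 --out model.json
Rscript inst/cli/thermomix.R intervals model.json --levels 0.5,0.9,0.95
```

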