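# prometheus

Preoperative estimation of the *true* mitotic count of a gastrointestinal
stromal tumor (GIST), and the risk stratification that follows from it.

## The problem

GIST risk classification (Miettinen–Lasota) needs three inputs: tumor
site, tumor size, and the mitotic count per 5 mm² of tissue. The first two
are available before surgery; the mitotic count is measured on a biopsy
that typically examines far less than the 5 mm² reference area, so the
biopsy count systematically under-estimates the count that will later be
found on the surgical specimen. Neoadjuvant therapy adds a second
distortion: a responding tumor's specimen count no longer reflects its
untreated biology. Both lead to under-staging and potential
mistreatment.

This package is for biostatisticians and pathology/sarcoma researchers who
want to model that gap rather than ignore it. It infers, for a new tumor,
the full posterior predictive distribution of the specimen mitotic count
from biopsy-time covariates, and converts it into risk-class
probabilities.

## The model

The specimen count is Poisson with a log-linear rate,

```
M^S_i ~ Poisson(λ_i)
log λ_i = α + β_[L_i]·d_i + γ_[L_i]·s_i + ((1−R_i)·δ + R_i·ε)·m_i
```

with site index `L` (colon-rectum, duodenum, small intestine, stomach),
transformed size `d` (z-scored mm), biopsy surface `s` (mm²), transformed
biopsy count `m` (`log1p`), and response flag `R`. The site-level size and
surface coefficients are partially pooled, `β_l ~ N(μ_β, σ_β)` and
`γ_l ~ N(μ_γ, σ_γ)`; priors are normal (coefficients) and exponential
(scales), calibrated by prior-predictive simulation against field
knowledge (most GISTs below 5 mitoses/5 mm², counts above 50 exceptional).
The response coefficient `ε` keeps treated-responding tumors from
polluting `δ`, and is never used for forecasting.

Fitting is by an adaptive Hamiltonian Monte Carlo sampler built into the
package (analytic gradients, dual-averaging step size, diagonal mass
adaptation, noncentered parameterization for the hierarchies), with
rank-normalized split R-hat, bulk ESS, divergence and energy diagnostics.
Model variants are compared by WAIC and PSIS-LOO; forecasts feed the
Miettinen–Lasota lookup (shipped as editable JSON configuration) and a
proposed preoperative clinical classification.

## Worked example

```r
library(prometheus)

# a synthetic training cohort standing in for the clinical series
cohort <- simulate_gist_cohort(100, seed = 11, params = gist_params(
  alpha = 1, beta = c(0.2, 0.3, 0.4, 0.5), gamma = c(-0.1, -0.2, -0.1, -0.15),
  delta = 1, epsilon = -0.5, mu_beta = 0.35, sigma_beta = 0.15,
  mu_gamma = -0.15, sigma_gamma = 0.1))

fit <- gist_fit(cohort, chains = 4, warmup = 500, draws = 500, seed = 2)
summary(fit)
#>    parameter   mean    sd   5.5%  94.5%  rhat ess_bulk
#>        alpha  0.757 0.143  0.527  0.975 1.007 1142.229
#>      beta[4]  0.381 0.057  0.296  0.473 1.002 1821.410
#>        delta  0.981 0.088  0.843  1.126 1.007 1225.840
#>      epsilon -0.208 0.198 -0.531  0.096 1.003 1908.157
#>      ...                       (15 parameters in total)
```

The posterior mean of `δ` is about 1 — specimen rate roughly proportional
to biopsy count on the `log1p` scale — and every R-hat is ≤ 1.01 with zero
divergent transitions.

Forecast a new tumor: gastric, 72 mm, 14.3 high-power fields examined
(about 3 mm²), 3 mitoses on the biopsy:

```r
tumor <- gist_data(site = "stomach", size_mm = 72,
                   surface_mm2 = hpf_to_mm2(14.3), biopsy_mitoses = 3)
pred <- predict(fit, tumor)
pred
#> Posterior predictive specimen mitotic count (per 5 mm2)
#>   input: stomach, 72 mm, 3.04 mm2 biopsy, 3 biopsy mitoses
#>   predictive mean 8.7; rate HDPI 89% [7.4, 10.0]
#>   most probable counts: 6 to 10 (50% of mass)

miettinen_lasota("stomach", 72, 3 * 5 / hpf_to_mm2(14.3))
#> [1] low
round(predictive_risk(pred, "stomach", 72), 3)
#>   none very_low   low moderate  high insufficient_data
#>  0.000    0.000 0.143    0.000 0.857             0.000
```

This is the package's central message in one screen: judged on its biopsy
alone the tumor is *low* risk, but once the under-sampled surface is
accounted for, the model expects 6–10 specimen mitoses and puts 86% of the
probability on *high* risk.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "prometheus.R", package = "prometheus")`, with
subcommands `simulate`, `fit`, `compare`, `predict` and `prior-check`.

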