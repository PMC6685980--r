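# gutsred

Reduced GUTS (General Unified Threshold models of Survival) for acute
ecotoxicity data: Bayesian calibration of the stochastic-death
(GUTS-RED-SD) and individual-tolerance (GUTS-RED-IT) variants, with full
propagation of posterior uncertainty to the regulatory toxicity endpoints
— lethal concentrations *LC(x, t)*, exposure multiplication factors
*MF(x, t)* (the EFSA *LPx*) and depuration times — under both constant and
time-variable (pulsed) exposure profiles.

The intended users are ecotoxicologists and environmental risk assessors
who fit survival time series from standard toxicity tests (e.g. *Gammarus
pulex* 4-day constant-exposure assays, or pulsed-exposure designs) and
need credible intervals, not just point values, on the endpoints that feed
environmental quality standards.

## The model

Both variants share a one-compartment toxicokinetic for the scaled damage
(internal concentration proxy) driven by the external concentration
C<sub>w</sub>(t):

    dD_w/dt = k_d (C_w(t) − D_w(t)),   D_w(0) = 0

with dominant rate constant k<sub>d</sub> (1/day). The toxicodynamics
differ:

* **SD** — a shared internal threshold z; the hazard rises linearly above
  it with killing rate b<sub>w</sub>, plus background hazard
  h<sub>b</sub>:
  `S(t) = exp(−∫ [b_w max(D_w − z, 0) + h_b] dτ)`.
* **IT** — individual thresholds are log-logistic (median m<sub>w</sub>,
  shape β) and death is immediate at first exceedance:
  `S(t) = exp(−h_b t) (1 − F(max D_w))`.

Damage and the SD hazard integral are computed **piecewise analytically**
(closed form on every interval where the exposure is constant or linear),
so no ODE-solver tolerance enters the results. Observed survivor counts
enter a conditional-binomial likelihood,
`N(t_i) ~ Binomial(N(t_{i−1}), S(t_i)/S(t_{i−1}))`, sampled by an adaptive
Metropolis MCMC under design-derived log10-uniform priors.

Endpoints are defined by `S(LC, t) = S(0, t)(1 − x/100)` (constant
exposure) and `S(MF·C_w, t) = S(C_w, t)(1 − x/100)` (any profile); IT has
closed forms, SD is solved by bracketed root search, and every endpoint is
evaluated over the joint posterior to give medians and 95% credible
intervals. Goodness of fit is summarised by NRMSE, %PPC (posterior
predictive coverage), WAIC and PSIS-LOO.

## Worked example

```r
library(gutsred)

# 8 constant concentrations (control + ladder 0.5..8), 5 daily
# observations, 20 individuals each — simulated from known SD parameters
design <- table1_design("constant")
truth  <- sd_params(kd = 0.8, bw = 0.5, z = 2, hb = 0.01)
data   <- simulate_dataset(truth, design, seed = 1)

fit <- guts_fit(data, model = "SD", chains = 3, iter = 3000,
                warmup = 3000, seed = 1)
summary(fit)
#> GUTS-RED-SD posterior summary (9000 draws):
#>     median    q2.5   q97.5  rhat n_eff
#> kd 0.78117 0.48014 1.30314 1.002   502
#> bw 0.64501 0.36911 1.02098 1.002   586
#> z  2.12433 1.60775 2.58085 1.001   479
#> hb 0.01383 0.00591 0.02855 1.001   835

lcx(fit, x = 50, t = 4)          # lethal concentration at day 4
#>    x t   median     q2.5    q97.5 n_used n_dropped model endpoint
#> 1 50 4 2.976063 2.671739 3.281894   9000         0    SD       LC

drt(fit, x = 50)                 # 50% depuration time (days)
#>    x    median      q2.5    q97.5 n_used n_dropped model endpoint
#> 1 50 0.8873237 0.5319051 1.443636   9000         0    SD      DRT

gof(fit)
#> Goodness-of-fit over 32 count transitions:
#>   NRMSE : 0.097 [0.068, 0.135]
#>   %PPC  : 96.9%
#>   WAIC  : 77.13 (p_waic 5.4)
#>   LOO-CV: 77.61 (max Pareto k 0.76)
```

The posterior medians sit near the generating values (kd = 0.8, z = 2)
with honest 95% intervals; the day-4 LC50 of ≈ 3.0 is the concentration
halving survival relative to the control after four days, and the NRMSE
of ≈ 0.1 with %PPC near 95 is what a well-specified calibration looks
like. For
pulsed profiles, use `mfx(fit, profile, x, t)` to get the multiplication
factor (margin of safety) with its credible interval.

A thin command-line front end over the same functions is installed at
`system.file("cli", "guts.R", package = "gutsred")`, with subcommands
`simulate`, `fit`, `predict`, `lcx`, `mfx`, `gof` and `pipeline`.

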