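---
title: "Reduced GUTS models: methods, design choices and limitations"
author: "gutsred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced GUTS models: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsred)
```

## The model

Acute survival toxicity tests record the number of survivors in a cohort
at a handful of observation times under a known exposure profile
$C_w(t)$. The reduced GUTS framework links exposure to mortality through
a latent *scaled damage* $D_w(t)$ — a one-compartment proxy for the
internal concentration, since reduced models assume no internal
measurements:

$$\frac{dD_w}{dt} = k_d\,(C_w(t) - D_w(t)), \qquad D_w(0) = 0,$$

where $k_d$ (1/day) is the dominant rate constant of the slowest
compensating process. Under constant exposure
$D_w(t) = C_w(1 - e^{-k_d t})$, and the time for damage to decline by
$x\%$ after a pulse (the depuration time) is
$DRT_x = -\ln(1 - x/100)/k_d$. (An alternative reading of the depuration
formula, $-\log(x\%)/k_d$, circulates in the literature; the two coincide
at $x = 50$, and this package implements the "time to an $x\%$
reduction" definition throughout.)

Two death mechanisms are offered:

* **Stochastic death (SD).** All individuals share a threshold $z$; above
  it the hazard grows linearly with rate $b_w$, on top of a background
  hazard $h_b$:
  $$S_{SD}(t) = \exp\left(-h_b t - b_w \int_0^t \max(D_w(\tau) - z,\, 0)\, d\tau\right).$$
* **Individual tolerance (IT).** Thresholds vary between individuals
  following a log-logistic distribution $F$ with median $m_w$ and shape
  $\beta$; death is immediate at the first exceedance, so only the
  running maximum of damage matters:
  $$S_{IT}(t) = e^{-h_b t}\left(1 - F\!\left(\max_{0 \le \tau \le t} D_w(\tau)\right)\right),
  \qquad F(d) = \frac{1}{1 + (d/m_w)^{-\beta}}.$$

## Numerical strategy: piecewise-analytic propagation

Exposure profiles are piecewise linear (measured chemistry) or piecewise
constant (designed pulses). On every segment the damage equation is a
linear ODE with constant-or-linear forcing and has the closed form
$D(\tau) = A + B\tau + C_0 e^{-k_d \tau}$, which the package propagates
segment by segment. The SD hazard integral is also evaluated in closed
form: within a segment $D$ is monotone or unimodal, so threshold
crossings are isolated by splitting at the single stationary point and
located either in closed form (constant forcing) or by a bracketed root
solve at absolute tolerance $10^{-12}$ days; the exceedance integral then
has an explicit antiderivative. This removes ODE-solver tolerances from
every downstream quantity; the test suite still cross-checks the
implementation against a high-accuracy numerical integration
(`deSolve::lsoda` at rtol $10^{-10}$) and agrees to better than $10^{-6}$
relative error on random pulse profiles.

Because the toxicokinetic is linear in its forcing, damage under a
scaled profile is the scaled damage (held to machine precision in the
tests). This is what makes the multiplication-factor endpoint cheap: one
damage computation serves every candidate multiplier.

## Endpoints

$LC(x,t)$ is defined by $S(LC, t) = S(0, t)(1 - x/100)$ — background
mortality cancels. For IT it has the closed form
$LC_{IT}(x,t) = \frac{m_w}{1 - e^{-k_d t}}\left(\frac{x}{100-x}\right)^{1/\beta}$;
for SD the threshold-crossing time depends on the concentration itself,
so the package solves the defining equation by bracketed root search
(bisection bracket grown geometrically from the concentration at which
damage first reaches $z$ at time $t$; relative tolerance $10^{-10}$).
Incipient values ($t \to \infty$) are $z$ for SD and
$m_w (x/(100-x))^{1/\beta}$ for IT. Note the convergence rates differ:
IT converges exponentially in $k_d t$, while the SD lethal concentration
approaches $z$ only like $-\ln(1 - x/100)/(b_w t)$ — a 0.1% check on the
SD limit needs horizons of hundreds of days, which the tests account for.

$MF(x,t)$ multiplies an entire exposure profile. Two baseline
conventions exist for "$x\%$ reduction" and they disagree whenever the
unmultiplied profile is itself toxic: relative to the *control*
($S(0,t)$) or relative to the *unmultiplied profile* ($S(C_w,t)$). The
package defaults to the profile baseline — the convention under which the
IT closed form
$MF_{IT}^\beta = (100 + x(\max D_w/m_w)^{-\beta})/(100-x)$ and the SD
implicit identity hold exactly, and the one matching margin-of-safety
(LPx) practice — and exposes `baseline = "control"` for the alternative.
The intent behind the printed definitions is ambiguous, so both are
offered rather than guessed.

$x$ is clipped to $[0.1, 99.9]$ with a warning: at the extremes the
endpoints are degenerate or unbounded and their posterior uncertainty is
maximal, which is also why 50% is the recommended reporting standard.

## Bayesian calibration

The likelihood is conditional-binomial between consecutive observations,
$N(t_i) \sim \text{Binomial}(N(t_{i-1}),\ S(t_i)/S(t_{i-1}))$ — the
standard choice for GUTS calibration; survival ratios are floored/clamped
only to absorb floating-point noise, and genuinely impossible data under
a parameter set yield $-\infty$.

Priors are independent log10-uniforms whose bounds encode what the
design can inform: $k_d$ between the rate reaching 0.1% of equilibrium
over the whole experiment and the rate reaching 99.9% within the
shortest observation gap; $z$/$m_w$ between the smallest positive and
largest tested concentration; $b_w \in [10^{-4}, 10^4]$,
$\beta \in [10^{-2}, 10^2]$; $h_b$ up to the worst-case control
mortality rate (largest cohort reduced to one expected survivor by the
end), lower bound $10^{-6}$/day.

Sampling is an adaptive random-walk Metropolis on the log10 scale: chains
start from a jittered rough mode (a few short Nelder–Mead searches),
warmup tunes a global step size toward 0.234 acceptance and estimates the
joint proposal covariance from the chain history (restarted at
mid-warmup so the frozen proposal reflects the stationary regime); after
warmup both are frozen, so kept draws form a valid Markov chain. One
user seed derives per-chain seeds deterministically — identical seed and
settings give bitwise-identical draws. Defaults are 3 chains, 5000
warmup and 5000 kept iterations, thinned to at most 10000 total draws.
Convergence is reported per parameter as split-chain R-hat and effective
sample size (via `coda`); R-hat > 1.05 or ESS < 100 attaches an explicit
warning to the fit. The SD posterior under short constant designs has a
pronounced $k_d$–$b_w$–$z$ ridge; the covariance-adapted joint proposal
is what makes it mixable, and the diagnostics should always be checked.

All posterior summaries (parameters, survival bands, endpoints) are
0.025/0.5/0.975 quantiles with the type-7 (linear interpolation)
convention, so bands are reproducible to the bit. Count predictions use
the exact binomial-mixture predictive (the conditional-binomial chain has
$\text{Binomial}(N_{init}, S(t))$ margins), not simulation. Endpoint
draws where the quantity is undefined (e.g. an MF for a no-effect
parameter set) are dropped and counted, never imputed; more than 50%
undefined draws at a grid point is an error.

## Goodness of fit

Four measures, all computed per *count transition* conditioning on the
previous **observed** count (one-step-ahead — stated explicitly because
the numbers depend on it):

* **NRMSE** — per posterior draw, the RMSE between observed counts and
  *sampled* one-step-ahead predictive counts (one sample per draw per
  observation, under a fixed sub-seed derived from the fit seed),
  normalised by the mean observed count; reported as posterior median and
  95% interval. Sampled rather than expected counts were chosen to match
  the posterior-predictive-check machinery.
* **%PPC** — the percentage of observations inside their central 95%
  predictive interval, computed from the exact mixture CDF. Because count
  intervals are discrete they over-cover, so well-specified fits sit at
  or slightly above 95%.
* **WAIC** — deviance scale, $-2(\text{lppd} - p_{WAIC})$ with
  $p_{WAIC}$ the summed posterior variance of per-observation log
  predictive density, with log-sum-exp stabilisation.
* **LOO-CV** — PSIS-smoothed leave-one-observation-out expected log
  predictive density on the deviance scale, implemented with the
  Zhang–Stephens generalized-Pareto tail fit (validated against
  independent reference implementations); Pareto-k diagnostics are
  attached and more than 10% of observations above $k = 0.7$ triggers a
  reliability warning.

Validation against new data is a pure data swap: every measure accepts a
dataset other than the calibration one.

## Synthetic data and the reference designs

The design library reproduces the layouts of the classic *G. pulex*
acute assays: constant designs with 8 profiles (control plus a 7-step
geometric ladder) observed daily for 4 days with 20 individuals each, and
compound-specific double-pulse variable designs (two one-day pulses with
a 2-day or 7-day gap; 2–4 profiles over 10–22 days with 70–80
individuals, e.g. 51 records for the carbendazim layout and 70 for
malathion). The tested concentrations of the original experiments are not
public, so the constant ladder spans $[z/4,\ 4z]$ of the generating
parameters — guaranteeing partial kills on several profiles, which is
what makes recovery experiments informative. Observation grids for the
variable designs are likewise not public; deterministic power-law grids
(denser early) stand in for them. Counts are generated by conditional
binomial sampling with per-profile RNG streams derived from one seed.

The default ground truth for recovery experiments is $k_d = 0.8$/day
(within the range implied by reported *G. pulex* depuration times),
$z = m_w = 2$, $b_w = 0.5$, $\beta = 2$, $h_b = 0.01$/day. Under these
conditions the test suite demands that each true parameter fall inside
its 95% credible interval in at least 90% of 20 replicates and that the
posterior medians of $k_d$ and the threshold sit within 25% of truth on
median — run with 3 chains of 4000 warmup + 4000 kept draws, the
smallest chain length at which the posterior-median estimate was found
stable.

What the generator does **not** emulate: measurement error on
concentrations, inter-individual frailty beyond the IT threshold
distribution, time-varying background mortality, and sub-lethal effects.
Passing recovery tests therefore demonstrates the estimation machinery
is sound under the model's own assumptions, not that the model fits any
particular real dataset.

## Pulsed-design experiments

`figure_experiment_profiles()` builds equal-dose families: 9/6/3 one-day
pulses over 20 days (amplitudes 1×/1.5×/3×), and two-pulse profiles with
0.5/2/7-day gaps. Two qualitative predictions of the framework are
enforced as tests: at equal total dose, fewer-but-higher pulses depress
survival at least as much as many low pulses, and closely spaced pulses
(gap below the depuration time) depress survival at least as much as
well-separated ones, for both SD and IT under effect-positive
parameters.

## Known limitations

* Only the reduced (scaled-damage) GUTS variants: no measured internal
  concentrations, no mixtures, no sub-lethal endpoints.
* $LC(x,t)$ is meaningful only for constant exposure; the package does
  not define it for pulsed profiles (use $MF(x,t)$ there).
* The random-walk sampler is robust but not gradient-based; very long
  ridges (e.g. from effect-free datasets) mix slowly, which the R-hat /
  ESS diagnostics will flag.
* PSIS-LOO k diagnostics above 0.7 for a subset of observations are
  common for small count datasets; the LOO value is then approximate and
  the attached warning should be heeded.
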