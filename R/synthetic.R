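#' Experimental designs
#'
#' An `experimental_design` couples exposure profiles with per-profile
#' observation times and initial cohort sizes; it is the input of
#' [simulate_dataset()].
#'
#' @param profiles list of [exposure_profile()] objects with unique labels.
#' @param obs_times list of numeric observation-time vectors (first time 0),
#'   one per profile.
#' @param n_init integer vector of initial individuals per profile
#'   (recycled).
#' @return an object of class `experimental_design`.
#' @export
experimental_design <- function(profiles, obs_times, n_init) {
  stopifnot(is.list(profiles), is.list(obs_times),
            length(profiles) == length(obs_times))
  labels <- vapply(profiles, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("profile labels must be unique")
  n_init <- rep_len(as.integer(n_init), length(profiles))
  if (any(n_init <= 0)) stop("`n_init` must be positive")
  for (i in seq_along(obs_times)) {
    ot <- obs_times[[i]]
    if (ot[1L] != 0 || any(diff(ot) <= 0))
      stop("observation times must start at 0 and increase")
  }
  structure(list(profiles = profiles, obs_times = obs_times,
                 n_init = n_init),
            class = "experimental_design")
}

#' @export
print.experimental_design <- function(x, ...) {
  cat("Experimental design: ", length(x$profiles), " profiles, ",
      sum(lengths(x$obs_times)), " observation records\n", sep = "")
  invisible(x)
}

# design implied by an existing dataset
.design_of <- function(data) {
  experimental_design(
    profiles = lapply(data$series, `[[`, "profile"),
    obs_times = lapply(data$series, `[[`, "time"),
    n_init = vapply(data$series, function(s) s$Nsurv[1L], integer(1)))
}

#' Forward simulation of survival datasets
#'
#' Simulates survivor counts with known ground-truth parameters under a
#' design: for each profile the model survival curve is computed and counts
#' are drawn sequentially by conditional binomial sampling,
#' \eqn{N(t_i) \sim \mathrm{Binomial}(N(t_{i-1}), S(t_i)/S(t_{i-1}))},
#' starting from `n_init`.  One integer seed deterministically derives an
#' independent RNG stream per profile, so adding a profile does not change
#' the counts of the others.
#'
#' @param params an [sd_params()] or [it_params()] object (the truth).
#' @param design an [experimental_design()].
#' @param seed integer seed.
#' @return a [guts_data()] dataset.
#' @examples
#' des <- table1_design("constant")
#' d <- simulate_dataset(sd_params(0.8, 0.5, 2, 0.01), des, seed = 1)
#' @export
simulate_dataset <- function(params, design, seed = 1L) {
  stopifnot(inherits(params, "guts_params"),
            inherits(design, "experimental_design"))
  set.seed(as.integer(seed))
  prof_seeds <- sample.int(2147483646L, length(design$profiles))
  series <- lapply(seq_along(design$profiles), function(i) {
    prof <- design$profiles[[i]]
    tt <- design$obs_times[[i]]
    S <- pmax(guts_survival(params, prof, tt), 1e-300)
    ratio <- pmin(S[-1L] / S[-length(S)], 1)
    set.seed(prof_seeds[i])
    N <- integer(length(tt))
    N[1L] <- design$n_init[i]
    for (k in seq_along(ratio))
      N[k + 1L] <- stats::rbinom(1L, N[k], ratio[k])
    list(label = prof$label, profile = prof, time = tt, Nsurv = N)
  })
  structure(list(series = series), class = "guts_data")
}

#' Standard experimental designs
#'
#' Reference designs mirroring the classic *Gammarus pulex* acute toxicity
#' experiments:
#'
#' * `"constant"`: 8 constant-concentration profiles (a control plus a
#'   7-step geometric ladder spanning `c_ref/4` to `4 * c_ref`), observed
#'   at 5 daily time points over 4 days with 20 individuals per profile —
#'   40 observation records.
#' * `"variable"`: compound-specific double-pulse designs (two one-day
#'   pulses separated by a short, 2-day, or long, 7-day, interval), with
#'   the per-compound number of profiles, duration, initial individuals
#'   and per-profile observation counts of the original datasets
#'   (e.g. carbendazim: 4 profiles, 51 records; malathion: 2 profiles of
#'   35 times over 22 days, 70 records).  Observation grids are uneven,
#'   denser early in the experiment.
#'
#' `c_ref` sets the concentration scale of the design; choose it near the
#' (true or expected) threshold so that the ladder and pulses are
#' informative.
#'
#' @param kind `"constant"` or `"variable"`.
#' @param compound one of `"carbendazim"`, `"cypermethrin"`,
#'   `"dimethoate"`, `"malathion"`, `"propiconazole"` (variable designs
#'   differ between compounds; constant designs are identical).
#' @param c_ref reference concentration scale (default 2).
#' @param pulse_amp pulse amplitude for variable designs (default
#'   `4 * c_ref`).
#' @return an [experimental_design()].
#' @export
table1_design <- function(kind = c("constant", "variable"),
                          compound = c("carbendazim", "cypermethrin",
                                       "dimethoate", "malathion",
                                       "propiconazole"),
                          c_ref = 2, pulse_amp = 4 * c_ref) {
  kind <- match.arg(kind)
  compound <- match.arg(compound)
  if (kind == "constant") {
    concs <- c(0, c_ref * 4^seq(-1, 1, length.out = 7))
    profiles <- lapply(seq_along(concs), function(i) {
      exposure_profile(0, concs[i], label = sprintf("C%d", i))
    })
    return(experimental_design(profiles,
                               obs_times = rep(list(0:4), length(concs)),
                               n_init = 20L))
  }
  spec <- switch(compound,
    carbendazim  = list(n_init = 80L, days = 10, npts = c(8, 14, 16, 13)),
    cypermethrin = list(n_init = 80L, days = 10, npts = c(10, 18, 18, 15)),
    dimethoate   = list(n_init = 80L, days = 10, npts = c(10, 16, 17, 15)),
    malathion    = list(n_init = 70L, days = 22, npts = c(35, 35)),
    propiconazole = list(n_init = 70L, days = 10, npts = c(11, 21, 21, 21)))
  gaps <- rep(c(2, 7), length.out = length(spec$npts))
  profiles <- lapply(seq_along(spec$npts), function(i) {
    pulse_profile(n_pulses = 2, amplitude = pulse_amp, width = 1,
                  start_times = c(0, 1 + gaps[i]),
                  total_duration = spec$days,
                  label = sprintf("V%d", i))
  })
  obs_times <- lapply(spec$npts, function(np) .uneven_grid(spec$days, np))
  experimental_design(profiles, obs_times, n_init = spec$n_init)
}

# deterministic uneven observation grid over [0, days]: denser early
.uneven_grid <- function(days, n) {
  u <- seq(0, 1, length.out = n)^0.8
  tt <- round(days * u, 2)
  # rounding safeguard: enforce strict increase
  for (i in seq_len(n - 1L))
    if (tt[i + 1L] <= tt[i]) tt[i + 1L] <- tt[i] + 0.01
  tt
}

#' Pulsed-design exploration profiles
#'
#' Equal-dose (same area under the curve) profile families used to study
#' how pulse number and pulse spacing shape survival:
#'
#' * `"pulse_number"`: three 20-day profiles with 9, 6 and 3 one-day
#'   pulses; amplitudes scaled (1x, 1.5x, 3x) so all carry the same total
#'   dose.
#' * `"pulse_interval"`: three equal-dose profiles of two one-day pulses
#'   separated by 0.5, 2 and 7 days.
#'
#' @param which `"pulse_number"` or `"pulse_interval"`.
#' @param amplitude base amplitude (the 9-pulse profile, or each of the
#'   two pulses).
#' @param total_duration profile length in days (default 20).
#' @return a named list of [exposure_profile()] objects.
#' @export
figure_experiment_profiles <- function(which = c("pulse_number",
                                                 "pulse_interval"),
                                       amplitude = 1, total_duration = 20) {
  which <- match.arg(which)
  if (which == "pulse_number") {
    starts <- list(p9 = seq(0, 16, by = 2), p6 = seq(0, 15, by = 3),
                   p3 = seq(0, 14, by = 7))
    amps <- amplitude * c(p9 = 1, p6 = 1.5, p3 = 3)
    out <- lapply(names(starts), function(nm) {
      pulse_profile(length(starts[[nm]]), amps[[nm]], width = 1,
                    start_times = starts[[nm]],
                    total_duration = total_duration,
                    label = paste0("pulses", length(starts[[nm]])))
    })
    names(out) <- c("pulses9", "pulses6", "pulses3")
  } else {
    gaps <- c(0.5, 2, 7)
    out <- lapply(gaps, function(g) {
      pulse_profile(2, amplitude, width = 1, start_times = c(0, 1 + g),
                    total_duration = total_duration,
                    label = paste0("gap", g))
    })
    names(out) <- paste0("gap", gaps)
  }
  out
}
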