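#' Exposure-concentration profiles
#'
#' An `exposure_profile` represents the external (water) concentration
#' \eqn{C_w(t)} that forces the toxicokinetic model: a set of time points
#' (days, starting at 0) with measured or designed concentrations, plus an
#' interpolation rule.  Measured chemistry is usually interpolated linearly;
#' designed rectangular pulses are represented exactly by a left-continuous
#' step function (`"const"`): between two breakpoints the concentration is
#' the value at the left breakpoint.  Beyond the last time point the last
#' concentration is held.
#'
#' A profile with a single time point denotes constant exposure for all
#' `t >= 0`.
#'
#' @param time numeric vector of strictly increasing time points (days),
#'   first element 0.
#' @param conc numeric vector of non-negative concentrations, same length
#'   as `time`.
#' @param interpolation `"linear"` (piecewise linear) or `"const"`
#'   (piecewise constant, left breakpoint value).
#' @param label character label identifying the profile within a dataset.
#'
#' @return An object of class `exposure_profile`.
#' @examples
#' const <- exposure_profile(0, 2, label = "C2")
#' puls  <- pulse_profile(n_pulses = 2, amplitude = 5, width = 1,
#'                        start_times = c(0, 7), total_duration = 10)
#' conc_at(puls, c(0.5, 3, 7.5))
#' profile_auc(puls, 0, 10)
#' @export
exposure_profile <- function(time, conc, interpolation = c("linear", "const"),
                             label = "profile") {
  interpolation <- match.arg(interpolation)
  time <- as.numeric(time)
  conc <- as.numeric(conc)
  if (length(time) != length(conc) || length(time) < 1L)
    stop("`time` and `conc` must have equal length >= 1")
  if (any(!is.finite(time)) || any(!is.finite(conc)))
    stop("`time` and `conc` must be finite")
  if (time[1L] != 0)
    stop("the first time point must be 0")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("`time` must be strictly increasing")
  if (any(conc < 0))
    stop("concentrations must be non-negative")
  structure(list(label = as.character(label)[1L], time = time, conc = conc,
                 interpolation = interpolation),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  kind <- if (is_constant_profile(x)) "constant"
          else paste0("time-variable (", x$interpolation, ")")
  cat("Exposure profile '", x$label, "': ", kind, ", ",
      length(x$time), " breakpoint(s), conc range [",
      format(min(x$conc)), ", ", format(max(x$conc)), "]\n", sep = "")
  invisible(x)
}

#' Is a profile constant in time?
#'
#' @param profile an [exposure_profile()].
#' @return `TRUE` if the concentration is the same at every breakpoint.
#' @export
is_constant_profile <- function(profile) {
  length(unique(profile$conc)) == 1L
}

#' Concentration at arbitrary times
#'
#' Evaluates \eqn{C_w(t)} under the profile's interpolation rule.  Beyond
#' the last breakpoint the last concentration is held.
#'
#' @param profile an [exposure_profile()].
#' @param t numeric vector of times (days), all `>= 0`.
#' @return numeric vector of concentrations.
#' @export
conc_at <- function(profile, t) {
  t <- as.numeric(t)
  if (any(t < 0)) stop("`t` must be non-negative")
  if (length(profile$time) == 1L)
    return(rep(profile$conc, length(t)))
  if (profile$interpolation == "const") {
    idx <- findInterval(t, profile$time)
    idx[idx < 1L] <- 1L
    profile$conc[idx]
  } else {
    stats::approx(profile$time, profile$conc, xout = t, method = "linear",
                  rule = 2)$y
  }
}

#' Rectangular pulse profiles
#'
#' Builds a left-continuous step profile with `n_pulses` rectangular pulses
#' of the given amplitude and width, zero concentration elsewhere.  Used for
#' the pulsed designs of the simulation experiments (equal-dose families
#' varying pulse number or pulse spacing).
#'
#' @param n_pulses number of pulses; must equal `length(start_times)`.
#' @param amplitude pulse height (concentration units).
#' @param width pulse duration (days).
#' @param start_times start time of each pulse (days).
#' @param total_duration length of the profile (days); pulses must fit
#'   inside it and must not overlap.
#' @param label profile label.
#' @return An [exposure_profile()] with `interpolation = "const"`.
#' @export
pulse_profile <- function(n_pulses, amplitude, width, start_times,
                          total_duration, label = "pulse") {
  start_times <- sort(as.numeric(start_times))
  if (length(start_times) != n_pulses)
    stop("`start_times` must have length `n_pulses`")
  if (amplitude < 0 || width <= 0) stop("invalid pulse amplitude or width")
  if (any(start_times < 0) ||
      start_times[n_pulses] + width > total_duration + 1e-12)
    stop("pulses must fit within `total_duration`")
  if (n_pulses > 1L && any(diff(start_times) < width - 1e-12))
    stop("pulses overlap")
  time <- 0
  conc <- 0
  for (s in start_times) {
    time <- c(time, s, s + width)
    conc <- c(conc, amplitude, 0)
  }
  # later entries win (a pulse starting at 0 overrides the baseline 0)
  keep <- !duplicated(time, fromLast = TRUE)
  time <- time[keep]
  conc <- conc[keep]
  o <- order(time)
  exposure_profile(time[o], conc[o], interpolation = "const", label = label)
}

#' Scale a profile by a constant factor
#'
#' @param profile an [exposure_profile()].
#' @param factor non-negative multiplier applied to every concentration.
#' @return the scaled [exposure_profile()].
#' @export
scale_profile <- function(profile, factor) {
  if (factor < 0) stop("`factor` must be non-negative")
  profile$conc <- profile$conc * factor
  profile
}

#' Area under an exposure profile
#'
#' Exact integral of the interpolated concentration over `[t0, t1]`
#' (trapezoids for linear interpolation, rectangles for step profiles).
#'
#' @param profile an [exposure_profile()].
#' @param t0,t1 integration bounds, `0 <= t0 < t1`.
#' @return the integral (concentration x days).
#' @export
profile_auc <- function(profile, t0, t1) {
  if (t0 < 0 || t1 <= t0) stop("need 0 <= t0 < t1")
  brk <- sort(unique(c(t0, t1, profile$time[profile$time > t0 &
                                            profile$time < t1])))
  a <- brk[-length(brk)]
  b <- brk[-1L]
  if (profile$interpolation == "const" && length(profile$time) > 1L) {
    sum(conc_at(profile, a) * (b - a))
  } else {
    sum((conc_at(profile, a) + conc_at(profile, b)) / 2 * (b - a))
  }
}

# Decompose a profile on [0, t_end] into forcing segments
# (t0, t1, a, b): C(t) = a + b * (t - t0) on [t0, t1].
# Past the last breakpoint the last value is held (b = 0).
.profile_segments <- function(profile, t_end) {
  tm <- profile$time
  cc <- profile$conc
  brk <- c(tm[tm < t_end], t_end)
  brk <- sort(unique(c(0, brk)))
  t0 <- brk[-length(brk)]
  t1 <- brk[-1L]
  a <- conc_at(profile, t0)
  if (profile$interpolation == "linear" && length(tm) > 1L) {
    b <- (conc_at(profile, t1) - a) / (t1 - t0)
    # hold-last-value region is flat
    b[t0 >= tm[length(tm)]] <- 0
  } else {
    b <- rep(0, length(t0))
  }
  list(t0 = t0, t1 = t1, a = a, b = b)
}
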