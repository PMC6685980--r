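#' Lethal concentrations LC(x, t)
#'
#' `LC(x, t)` is the constant external concentration producing an `x`%
#' reduction in survival at time `t` relative to the control:
#' \deqn{S(LC(x,t), t) = S(0, t) (1 - x/100),}
#' in which the background mortality cancels.  For the IT model it has the
#' closed form
#' \deqn{LC_{IT}(x,t) = \frac{m_w}{1 - e^{-k_d t}}
#'   \left(\frac{x}{100-x}\right)^{1/\beta};}
#' for the SD model the threshold-crossing time depends on the
#' concentration itself, so the defining equation is solved by a bracketed
#' root search on the (monotone) hazard-exceedance integral.
#'
#' `lc_incipient()` gives the large-time asymptote: `z` for SD (any `x`) and
#' \eqn{m_w (x/(100-x))^{1/\beta}} for IT.
#'
#' `x` is clipped to `[0.1, 99.9]` with a warning: the endpoint is
#' unbounded or degenerate at the extremes and its uncertainty explodes
#' there.
#'
#' @param params an [sd_params()] or [it_params()] object.
#' @param x percent survival reduction, in (0, 100); vectorised.
#' @param t exposure duration (days), `> 0`; vectorised (recycled
#'   against `x`).
#' @return lethal concentration(s), same length as `x`/`t` recycled.
#' @examples
#' lc_it(it_params(kd = log(2), mw = 2, beta = 1), x = 50, t = 1)  # 4
#' lc_incipient(sd_params(kd = 1, bw = 1, z = 3), x = 10)          # 3
#' @export
lc_it <- function(params, x, t) {
  if (!inherits(params, "it_params"))
    stop("`params` must be an it_params() object")
  x <- .clip_x(x)
  if (any(t <= 0)) stop("`t` must be positive")
  params$mw / (1 - exp(-params$kd * t)) * (x / (100 - x))^(1 / params$beta)
}

#' @rdname lc_it
#' @param conc_ceiling upper bound for the SD root search; exceeding it
#'   raises a convergence error.
#' @export
lc_sd <- function(params, x, t, conc_ceiling = 1e12) {
  if (!inherits(params, "sd_params"))
    stop("`params` must be an sd_params() object")
  x <- .clip_x(x)
  if (any(t <= 0)) stop("`t` must be positive")
  n <- max(length(x), length(t))
  x <- rep_len(x, n); t <- rep_len(t, n)
  vapply(seq_len(n), function(i) {
    .lc_sd_one(params, x[i], t[i], conc_ceiling)
  }, numeric(1))
}

.lc_sd_one <- function(params, x, t, conc_ceiling) {
  kd <- params$kd; bw <- params$bw; z <- params$z
  target <- -log(1 - x / 100) / bw
  f <- function(C) .const_exceedance_integral(C, kd, z, t) - target
  # damage first reaches z at time t when C = z / (1 - exp(-kd t))
  lo <- z / (1 - exp(-kd * t))
  hi <- max(2 * lo, z + 1, target / t)
  while (f(hi) < 0) {
    hi <- hi * 4
    if (hi > conc_ceiling)
      stop("lc_sd: no solution below the concentration ceiling")
  }
  stats::uniroot(f, lower = lo, upper = hi,
                 tol = 1e-10 * max(1, hi))$root
}

# Integral over [0, t] of max(D_w - z, 0) for constant concentration C.
.const_exceedance_integral <- function(C, kd, z, t) {
  if (C <= z) return(0)
  tz <- if (z == 0) 0 else -log(1 - z / C) / kd
  if (t <= tz) return(0)
  C * (t - tz) + C * (exp(-kd * t) - exp(-kd * tz)) / kd - z * (t - tz)
}

#' @rdname lc_it
#' @export
lc_incipient <- function(params, x) {
  x <- .clip_x(x)
  switch(.model_tag(params),
         SD = rep_len(params$z, length(x)),
         IT = params$mw * (x / (100 - x))^(1 / params$beta))
}

#' Exposure multiplication factors MF(x, t) (LPx)
#'
#' The multiplication factor is the scalar applied to an entire exposure
#' profile that produces an `x`% survival reduction at time `t`.  Because
#' the toxicokinetic is linear in its forcing, damage under the multiplied
#' profile is the multiplied damage, so a single damage computation
#' suffices.
#'
#' Two baseline conventions exist for "x% reduction":
#' * `"profile"` (default): reduction relative to survival under the
#'   *unmultiplied* profile, \eqn{S(MF \cdot C_w, t) = S(C_w, t)(1 -
#'   x/100)}.  This is the convention under which the IT closed form
#'   \deqn{MF_{IT}(x,t)^\beta = \frac{100 + x \,(\max D_w / m_w)^{-\beta}}
#'     {100 - x}} holds, and the SD solution satisfies the analogous
#'   implicit identity.
#' * `"control"`: reduction relative to the uncontaminated control,
#'   \eqn{S(MF \cdot C_w, t) = S(0, t)(1 - x/100)}.
#'
#' Background mortality cancels in both.  For SD the equation is solved by
#' a bracketed root search on the multiplier; for IT both conventions are
#' closed-form.
#'
#' @param params an [sd_params()] or [it_params()] object.
#' @param profile an [exposure_profile()]; must be non-zero on `[0, t]`.
#' @param x percent survival reduction, in (0, 100); vectorised.
#' @param t assessment time (days), `> 0`.
#' @param baseline `"profile"` or `"control"` (see Details).
#' @param mf_ceiling upper bound for the SD root search.
#' @return multiplication factor(s).
#' @export
mf_it <- function(params, profile, x, t,
                  baseline = c("profile", "control")) {
  if (!inherits(params, "it_params"))
    stop("`params` must be an it_params() object")
  baseline <- match.arg(baseline)
  x <- .clip_x(x)
  if (any(t <= 0)) stop("`t` must be positive")
  n <- max(length(x), length(t))
  x <- rep_len(x, n); t <- rep_len(t, n)
  maxD <- max_damage(profile, params$kd, t)
  if (any(maxD <= 0))
    stop("profile causes no exposure on [0, t]: MF undefined")
  if (baseline == "profile") {
    ((100 + x * (maxD / params$mw)^(-params$beta)) /
       (100 - x))^(1 / params$beta)
  } else {
    params$mw * (x / (100 - x))^(1 / params$beta) / maxD
  }
}

#' @rdname mf_it
#' @export
mf_sd <- function(params, profile, x, t,
                  baseline = c("profile", "control"), mf_ceiling = 1e9) {
  if (!inherits(params, "sd_params"))
    stop("`params` must be an sd_params() object")
  baseline <- match.arg(baseline)
  x <- .clip_x(x)
  if (any(t <= 0)) stop("`t` must be positive")
  n <- max(length(x), length(t))
  x <- rep_len(x, n); t <- rep_len(t, n)
  kd <- params$kd; bw <- params$bw; z <- params$z
  segs <- .damage_segments(profile, kd, max(t) + 1e-9)
  if (max_damage(profile, kd, max(t)) <= 0)
    stop("profile causes no exposure on [0, t]: MF undefined")
  vapply(seq_len(n), function(i) {
    # J(m) = integral of max(m D - z, 0) = m * integral of max(D - z/m, 0)
    J <- function(m) m * .pos_integral(segs, kd, z / m, t[i])
    base <- if (baseline == "profile") J(1) else 0
    target <- base - log(1 - x[i] / 100) / bw
    f <- function(m) J(m) - target
    maxD_t <- max_damage(profile, kd, t[i])
    lo <- if (z > 0) z / maxD_t else 1e-12
    hi <- max(2 * lo, 2)
    while (f(hi) < 0) {
      hi <- hi * 4
      if (hi > mf_ceiling)
        stop("mf_sd: no solution below the multiplier ceiling")
    }
    stats::uniroot(f, lower = lo, upper = hi,
                   tol = 1e-10 * max(1, hi))$root
  }, numeric(1))
}

.clip_x <- function(x) {
  if (any(x <= 0 | x >= 100))
    stop("`x` must be strictly inside (0, 100)")
  if (any(x < 0.1 | x > 99.9)) {
    warning("x clipped to [0.1, 99.9]: endpoints at extreme x are ",
            "dominated by uncertainty")
    x <- pmin(pmax(x, 0.1), 99.9)
  }
  x
}
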