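#' Scaled damage (toxicokinetics)
#'
#' The reduced GUTS toxicokinetic is the one-compartment scaled-damage
#' equation \deqn{dD_w/dt = k_d (C_w(t) - D_w(t)), \quad D_w(0) = 0,} whose
#' solution is the scaled internal concentration driven by the exposure
#' profile.  On every interval where the forcing is constant or linear the
#' equation has a closed form, so the solution is propagated exactly
#' segment by segment — no numerical ODE solver is involved.
#'
#' For constant exposure this reduces to
#' \eqn{D_w(t) = C_w (1 - e^{-k_d t})}.
#'
#' @param profile an [exposure_profile()].
#' @param kd dominant rate constant (1/day), `> 0`.
#' @param t numeric vector of times (days), `>= 0`.
#' @return `scaled_damage()`: \eqn{D_w(t)} at each requested time;
#'   `max_damage()`: the running maximum \eqn{\max_{0 \le \tau \le t}
#'   D_w(\tau)}.
#' @examples
#' p <- exposure_profile(0, 2, label = "C2")
#' scaled_damage(p, kd = log(2), t = 1)  # 2 * (1 - 1/2) = 1
#' @export
scaled_damage <- function(profile, kd, t) {
  .check_pos(kd = kd)
  t <- as.numeric(t)
  if (any(t < 0)) stop("`t` must be non-negative")
  if (length(t) == 0L) return(numeric(0))
  segs <- .damage_segments(profile, kd, max(t, profile$time[1L]) + 1e-9)
  idx <- findInterval(t, segs$t0)
  idx[idx < 1L] <- 1L
  tau <- t - segs$t0[idx]
  segs$A[idx] + segs$B[idx] * tau + segs$C0[idx] * exp(-kd * tau)
}

#' @rdname scaled_damage
#' @export
max_damage <- function(profile, kd, t) {
  .check_pos(kd = kd)
  t <- as.numeric(t)
  if (any(t < 0)) stop("`t` must be non-negative")
  if (length(t) == 0L) return(numeric(0))
  segs <- .damage_segments(profile, kd, max(t) + 1e-9)
  n <- length(segs$t0)
  # running max of D at each segment start
  seg_full_max <- vapply(seq_len(n), function(k) {
    .seg_max(segs$A[k], segs$B[k], segs$C0[k], kd,
             segs$t1[k] - segs$t0[k])
  }, numeric(1))
  run_max_at_start <- c(0, cummax(seg_full_max))[seq_len(n)]
  idx <- findInterval(t, segs$t0)
  idx[idx < 1L] <- 1L
  vapply(seq_along(t), function(i) {
    k <- idx[i]
    tau <- t[i] - segs$t0[k]
    max(run_max_at_start[k],
        .seg_max(segs$A[k], segs$B[k], segs$C0[k], kd, tau))
  }, numeric(1))
}

#' Depuration time
#'
#' Time after the end of a pulse for the scaled internal concentration to
#' decline by `x` percent.  During depuration \eqn{D_w} decays as
#' \eqn{e^{-k_d t}}, so the x% reduction time is
#' \eqn{DRT_x = -\ln(1 - x/100) / k_d}; `x = 50` gives the elimination
#' half-life \eqn{\ln 2 / k_d}.
#'
#' @param kd dominant rate constant (1/day), `> 0`.
#' @param x percent reduction, in (0, 100); may be a vector.
#' @return depuration time(s) in days.
#' @export
depuration_time <- function(kd, x = 50) {
  .check_pos(kd = kd)
  if (any(x <= 0 | x >= 100)) stop("`x` must be in (0, 100)")
  -log(1 - x / 100) / kd
}

# Segment decomposition of D_w on [0, t_end].
# On each segment (local time tau in [0, L]):
#   D(tau) = A + B*tau + C0*exp(-kd*tau)
# with forcing C(tau) = a + b*tau, A = a - b/kd, B = b, C0 = D0 - a + b/kd.
.damage_segments <- function(profile, kd, t_end) {
  sg <- .profile_segments(profile, t_end)
  n <- length(sg$t0)
  A <- numeric(n); B <- numeric(n); C0 <- numeric(n); D0 <- numeric(n)
  d <- 0
  for (k in seq_len(n)) {
    D0[k] <- d
    A[k] <- sg$a[k] - sg$b[k] / kd
    B[k] <- sg$b[k]
    C0[k] <- d - A[k]
    L <- sg$t1[k] - sg$t0[k]
    d <- A[k] + B[k] * L + C0[k] * exp(-kd * L)
  }
  list(t0 = sg$t0, t1 = sg$t1, a = sg$a, b = sg$b,
       A = A, B = B, C0 = C0, D0 = D0)
}

# Max of D(tau) = A + B*tau + C0*exp(-kd*tau) over [0, upto].
# D' = B - kd*C0*exp(-kd*tau) changes sign at most once, so D is monotone
# or unimodal: the max is attained at an endpoint or the stationary point.
.seg_max <- function(A, B, C0, kd, upto) {
  if (upto <= 0) return(A + C0)
  cand <- c(A + C0, A + B * upto + C0 * exp(-kd * upto))
  if (B != 0 && C0 != 0 && sign(B) == sign(C0)) {
    ts <- log(kd * C0 / B) / kd
    if (ts > 0 && ts < upto)
      cand <- c(cand, A + B * ts + C0 * exp(-kd * ts))
  }
  max(cand)
}

# Integral of max(D(tau) - z, 0) over local time [0, upto] of one segment.
.seg_pos_integral <- function(A, B, C0, kd, z, upto) {
  if (upto <= 0) return(0)
  f <- function(s) A + B * s + C0 * exp(-kd * s) - z
  # antiderivative of (D - z)
  G <- function(s) A * s + B * s^2 / 2 - (C0 / kd) * exp(-kd * s) - z * s
  # split at the stationary point so each piece is monotone
  brk <- c(0, upto)
  if (B != 0 && C0 != 0 && sign(B) == sign(C0)) {
    ts <- log(kd * C0 / B) / kd
    if (ts > 0 && ts < upto) brk <- c(0, ts, upto)
  }
  total <- 0
  for (j in seq_len(length(brk) - 1L)) {
    p <- brk[j]; q <- brk[j + 1L]
    fp <- f(p); fq <- f(q)
    if (fp <= 0 && fq <= 0) next
    if (fp >= 0 && fq >= 0) {
      total <- total + (G(q) - G(p))
      next
    }
    # one sign change on a monotone piece: locate the crossing
    if (B == 0) {
      # A + C0*exp(-kd*c) = z  (closed form)
      cr <- -log((z - A) / C0) / kd
    } else {
      cr <- stats::uniroot(f, c(p, q), tol = 1e-12)$root
    }
    if (fp < 0) total <- total + (G(q) - G(cr))
    else        total <- total + (G(cr) - G(p))
  }
  max(total, 0)
}

# Cumulative integral of max(D - z, 0) from 0 to each time in t.
.pos_integral <- function(segs, kd, z, t) {
  n <- length(segs$t0)
  seg_int <- vapply(seq_len(n), function(k) {
    .seg_pos_integral(segs$A[k], segs$B[k], segs$C0[k], kd, z,
                      segs$t1[k] - segs$t0[k])
  }, numeric(1))
  cum_at_start <- c(0, cumsum(seg_int))[seq_len(n)]
  idx <- findInterval(t, segs$t0)
  idx[idx < 1L] <- 1L
  vapply(seq_along(t), function(i) {
    k <- idx[i]
    cum_at_start[k] + .seg_pos_integral(segs$A[k], segs$B[k], segs$C0[k],
                                        kd, z, t[i] - segs$t0[k])
  }, numeric(1))
}
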