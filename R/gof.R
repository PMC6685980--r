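#' Goodness-of-fit measures
#'
#' Four measures of calibration / prediction robustness computed from a
#' posterior and a dataset (the calibration data by default, or a
#' validation dataset — swapping in new data is all that distinguishes
#' validation from calibration here):
#'
#' * **NRMSE**: for each posterior draw, the root-mean-square error between
#'   observed survivor counts and one-step-ahead posterior-predictive
#'   *sampled* counts, divided by the mean observed count; summarised by
#'   its posterior median and 95% interval.
#' * **%PPC**: the percentage of observations falling inside their 95%
#'   posterior-predictive count interval (exact conditional-binomial
#'   mixture over draws, conditioning on the previous observed count).  A
#'   well-specified fit sits near 95%.
#' * **WAIC** on the deviance scale, \eqn{-2(\mathrm{lppd} -
#'   p_{WAIC})}, with \eqn{p_{WAIC}} the summed posterior variance of the
#'   per-observation log predictive density.
#' * **LOO-CV**: leave-one-observation-out expected log predictive density
#'   by Pareto-smoothed importance sampling, also on the deviance scale;
#'   Pareto-k diagnostics are attached and more than 10% of observations
#'   with k > 0.7 triggers a reliability warning.
#'
#' The unit of observation throughout is one count transition between
#' consecutive observation times (predictions condition on the previous
#' *observed* count, not on simulated trajectories).
#'
#' @param fit a [guts_fit()] object.
#' @param data a [guts_data()] dataset; default the calibration data.
#' @param seed seed for the NRMSE predictive sampling (fixed sub-seed
#'   derived from the fit seed by default).
#' @param ndraws optional deterministic subsample of posterior draws.
#' @return `gof()` returns a `guts_gof` list with elements `nrmse`
#'   (median, q2.5, q97.5), `ppc_pct`, `waic`, `loo`, `pareto_k`, `n_obs`.
#'   The individual measures are also available as [nrmse()],
#'   [ppc_percent()], [waic()] and [loo_cv()].
#' @export
gof <- function(fit, data = NULL, seed = NULL, ndraws = NULL) {
  pp <- .pred_pieces(fit, data, ndraws)
  out <- list(nrmse = .nrmse_impl(pp, seed = .nrmse_seed(fit, seed)),
              ppc_pct = .ppc_impl(pp),
              waic = .waic_impl(pp),
              loo = .loo_impl(pp),
              n_obs = length(pp$nobs))
  res <- list(nrmse = out$nrmse, ppc_pct = out$ppc_pct,
              waic = out$waic$waic, p_waic = out$waic$p_waic,
              loo = out$loo$loo, pareto_k = out$loo$k,
              n_obs = out$n_obs)
  class(res) <- "guts_gof"
  res
}

#' @rdname gof
#' @export
nrmse <- function(fit, data = NULL, seed = NULL, ndraws = NULL) {
  .nrmse_impl(.pred_pieces(fit, data, ndraws), seed = .nrmse_seed(fit, seed))
}

#' @rdname gof
#' @export
ppc_percent <- function(fit, data = NULL, ndraws = NULL) {
  .ppc_impl(.pred_pieces(fit, data, ndraws))
}

#' @rdname gof
#' @export
waic <- function(fit, data = NULL, ndraws = NULL) {
  .waic_impl(.pred_pieces(fit, data, ndraws))$waic
}

#' @rdname gof
#' @export
loo_cv <- function(fit, data = NULL, ndraws = NULL) {
  res <- .loo_impl(.pred_pieces(fit, data, ndraws))
  res$loo
}

#' @export
print.guts_gof <- function(x, ...) {
  cat("Goodness-of-fit over", x$n_obs, "count transitions:\n")
  cat(sprintf("  NRMSE : %.3f [%.3f, %.3f]\n", x$nrmse["median"],
              x$nrmse["q2.5"], x$nrmse["q97.5"]))
  cat(sprintf("  %%PPC  : %.1f%%\n", x$ppc_pct))
  cat(sprintf("  WAIC  : %.2f (p_waic %.1f)\n", x$waic, x$p_waic))
  cat(sprintf("  LOO-CV: %.2f (max Pareto k %.2f)\n", x$loo,
              suppressWarnings(max(x$pareto_k, na.rm = TRUE))))
  invisible(x)
}

.nrmse_seed <- function(fit, seed) {
  if (!is.null(seed)) return(as.integer(seed))
  (fit$seed + 104729L) %% 2147483647L
}

# one-step-ahead predictive pieces: M x N matrices of conditional-binomial
# probabilities and log predictive densities, plus observed counts.
.pred_pieces <- function(fit, data = NULL, ndraws = NULL) {
  stopifnot(inherits(fit, "guts_fit"))
  if (is.null(data)) data <- fit$data
  stopifnot(inherits(data, "guts_data"))
  idx <- seq_len(nrow(fit$draws))
  if (!is.null(ndraws) && ndraws < length(idx))
    idx <- idx[seq(1L, length(idx), length.out = ndraws)]
  nprev <- unlist(lapply(data$series,
                         function(s) s$Nsurv[-length(s$Nsurv)]))
  nobs <- unlist(lapply(data$series, function(s) s$Nsurv[-1L]))
  ratio <- t(vapply(idx, function(j) {
    params <- .draw_params(fit, j)
    unlist(lapply(data$series, function(s) {
      S <- pmax(guts_survival(params, s$profile, s$time), 1e-300)
      pmin(S[-1L] / S[-length(S)], 1)
    }))
  }, numeric(length(nobs))))
  logp <- matrix(stats::dbinom(rep(nobs, each = nrow(ratio)),
                               rep(nprev, each = nrow(ratio)),
                               as.numeric(ratio), log = TRUE),
                 nrow = nrow(ratio))
  # floor to keep variances finite when a draw deems a transition impossible
  logp <- pmax(logp, log(.Machine$double.xmin))
  list(nprev = nprev, nobs = nobs, ratio = ratio, logp = logp,
       M = nrow(ratio))
}

.nrmse_impl <- function(pp, seed) {
  if (mean(pp$nobs) == 0)
    stop("all observed counts are zero: NRMSE undefined")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M <- pp$M
  N <- length(pp$nobs)
  y <- matrix(stats::rbinom(M * N, rep(pp$nprev, each = M),
                            as.numeric(pp$ratio)), nrow = M)
  rmse <- sqrt(rowMeans((y - rep(pp$nobs, each = M))^2))
  nr <- rmse / mean(pp$nobs)
  qs <- stats::quantile(nr, probs = c(0.025, 0.5, 0.975), type = 7)
  c(median = unname(qs[2]), q2.5 = unname(qs[1]), q97.5 = unname(qs[3]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.ppc_impl <- function(pp) {
  inside <- vapply(seq_along(pp$nobs), function(i) {
    n <- pp$nprev[i]
    cdf <- rowMeans(matrix(vapply(pp$ratio[, i], function(p) {
      stats::pbinom(0:n, n, p)
    }, numeric(n + 1L)), nrow = n + 1L))
    lo <- (0:n)[which(cdf >= 0.025 - 1e-12)[1L]]
    hi <- (0:n)[which(cdf >= 0.975 - 1e-12)[1L]]
    pp$nobs[i] >= lo && pp$nobs[i] <= hi
  }, logical(1))
  100 * mean(inside)
}

.waic_impl <- function(pp) {
  M <- pp$M
  lppd <- apply(pp$logp, 2, .log_sum_exp) - log(M)
  p_w <- if (M > 1) apply(pp$logp, 2, stats::var) else rep(0, ncol(pp$logp))
  list(waic = -2 * (sum(lppd) - sum(p_w)), p_waic = sum(p_w))
}

.loo_impl <- function(pp) {
  M <- pp$M
  N <- ncol(pp$logp)
  elpd <- numeric(N)
  k <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    lw <- -pp$logp[, i]          # log importance ratios, up to a constant
    sm <- .psis_smooth(lw)
    lw_s <- sm$lw
    k[i] <- sm$k
    elpd[i] <- .log_sum_exp(lw_s + pp$logp[, i]) - .log_sum_exp(lw_s)
  }
  n_bad <- sum(k > 0.7, na.rm = TRUE)
  if (n_bad > 0.1 * N)
    warning("PSIS-LOO unreliable: ", n_bad, " of ", N,
            " observations have Pareto k > 0.7", call. = FALSE)
  list(loo = -2 * sum(elpd), elpd = elpd, k = k)
}

# Pareto-smoothed importance weights (log scale, centred at max 0).
.psis_smooth <- function(lw) {
  lw <- lw - max(lw)
  S <- length(lw)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (tail_len < 5 || length(unique(lw)) < 5)
    return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  cutoff <- lw[ord[S - tail_len]]
  tail_ids <- ord[(S - tail_len + 1L):S]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  # a degenerate tail (ties, negligible spread) carries no Pareto signal
  if (max(exc) <= 1e-14) return(list(lw = lw, k = NA_real_))
  fit <- .gpdfit(sort(exc))
  if (!is.finite(fit$k) || !is.finite(fit$sigma) || fit$sigma <= 0)
    return(list(lw = lw, k = NA_real_))
  p <- (seq_len(tail_len) - 0.5) / tail_len
  q <- if (abs(fit$k) < 1e-12) {
    -fit$sigma * log1p(-p)
  } else {
    fit$sigma * expm1(-fit$k * log1p(-p)) / fit$k
  }
  sm <- log(exp(cutoff) + q)
  if (any(!is.finite(sm))) return(list(lw = lw, k = fit$k))
  # assign smoothed quantiles in rank order, truncate at the raw max (0)
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(sm, 0)
  list(lw = lw, k = fit$k)
}

# Generalized Pareto fit (Zhang & Stephens 2009 profile posterior mean,
# with the weak prior on k used in PSIS practice).
.gpdfit <- function(x) {
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- suppressWarnings(n * (log(bs / ks) + ks - 1))
  L[!is.finite(L)] <- -Inf
  if (all(L == -Inf)) return(list(k = NA_real_, sigma = NA_real_))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(L - L[j])), numeric(1))
  w[!is.finite(w)] <- 0
  b <- sum(bs * w)
  # shape on the standard GPD convention (positive = heavy tail)
  k <- mean(log1p(-b * x))
  sigma <- -k / b
  k <- (n * k + 10 * 0.5) / (n + 10)   # prior shrinkage toward 0.5
  list(k = k, sigma = sigma)
}

.log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}
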