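#' Posterior predictions of survival over time
#'
#' Evaluates the survival curve under an exposure profile for every joint
#' posterior draw and summarises, at each time point, the 0.025, 0.5 and
#' 0.975 quantiles.  In `"rate"` mode the band is on the survival
#' probability; in `"counts"` mode it is on posterior-predictive survivor
#' counts for `n_init` individuals (under conditional-binomial sampling the
#' marginal count at time t is binomial with probability S(t), so the
#' predictive mixture is computed exactly, without simulation).
#'
#' @param object a [guts_fit()] object.
#' @param profile an [exposure_profile()]; default: the first profile of
#'   the calibration dataset.
#' @param times numeric vector of prediction times (days).
#' @param mode `"rate"` or `"counts"`.
#' @param n_init initial number of individuals (counts mode).
#' @param ndraws optional subsample size of posterior draws (deterministic
#'   thinning) to speed up prediction.
#' @param ... unused.
#' @return A data frame of class `guts_band` with columns `time`, `q2.5`,
#'   `q50`, `q97.5`.
#' @export
predict.guts_fit <- function(object, profile = NULL, times = NULL,
                             mode = c("rate", "counts"), n_init = 20,
                             ndraws = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(profile)) profile <- object$data$series[[1L]]$profile
  if (is.null(times))
    times <- object$data$series[[1L]]$time
  times <- as.numeric(times)
  if (length(times) == 0L) stop("`times` must be non-empty")
  S <- .survival_draws(object, profile, times, ndraws)
  if (mode == "rate") {
    qs <- apply(S, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                type = 7)
  } else {
    qs <- apply(S, 2, function(p) {
      .mixture_binom_quantile(p, n_init, c(0.025, 0.5, 0.975))
    })
  }
  structure(data.frame(time = times, q2.5 = qs[1, ], q50 = qs[2, ],
                       q97.5 = qs[3, ]),
            class = c("guts_band", "data.frame"), mode = mode)
}

# matrix of survival curves: draws x times
.survival_draws <- function(fit, profile, times, ndraws = NULL) {
  idx <- seq_len(nrow(fit$draws))
  if (!is.null(ndraws) && ndraws < length(idx))
    idx <- idx[seq(1L, length(idx), length.out = ndraws)]
  out <- vapply(idx, function(j) {
    guts_survival(.draw_params(fit, j), profile, times)
  }, numeric(length(times)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(times))
  t(out)
}

# Quantiles of a mixture over draws of Binomial(n, p_j): smallest count y
# with mixture CDF >= prob.
.mixture_binom_quantile <- function(p, n, probs) {
  cdf <- rowMeans(outer(0:n, p, function(y, pp) stats::pbinom(y, n, pp)))
  vapply(probs, function(q) (0:n)[which(cdf >= q - 1e-12)[1L]], numeric(1))
}

#' Posterior distribution of an endpoint over a grid
#'
#' Evaluates an endpoint function at every joint posterior draw and every
#' grid row, returning the 0.025/0.5/0.975 quantiles per grid row.  Draws
#' where the endpoint is undefined or non-finite are dropped and counted;
#' more than 50% undefined draws at any grid row is an error (the summary
#' would be meaningless).
#'
#' @param fit a [guts_fit()] object.
#' @param fn `function(params, ...)` returning a scalar endpoint value for
#'   one parameter set.
#' @param grid a data frame whose rows are passed to `fn` as named
#'   arguments.
#' @param ndraws optional deterministic subsample of draws.
#' @return data frame: grid columns plus `median`, `q2.5`, `q97.5`,
#'   `n_used`, `n_dropped`.
#' @export
endpoint_distribution <- function(fit, fn, grid, ndraws = NULL) {
  stopifnot(inherits(fit, "guts_fit"), is.function(fn),
            is.data.frame(grid), nrow(grid) >= 1L)
  idx <- seq_len(nrow(fit$draws))
  if (!is.null(ndraws) && ndraws < length(idx))
    idx <- idx[seq(1L, length(idx), length.out = ndraws)]
  out <- lapply(seq_len(nrow(grid)), function(g) {
    args <- as.list(grid[g, , drop = FALSE])
    vals <- vapply(idx, function(j) {
      v <- tryCatch(do.call(fn, c(list(.draw_params(fit, j)), args)),
                    error = function(e) NA_real_)
      if (is.null(v) || !is.finite(v)) NA_real_ else v
    }, numeric(1))
    ok <- vals[is.finite(vals)]
    n_drop <- length(vals) - length(ok)
    if (n_drop > 0.5 * length(vals))
      stop("endpoint undefined for more than 50% of posterior draws at ",
           "grid row ", g)
    qs <- stats::quantile(ok, probs = c(0.025, 0.5, 0.975), type = 7)
    c(median = unname(qs[2]), q2.5 = unname(qs[1]), q97.5 = unname(qs[3]),
      n_used = length(ok), n_dropped = n_drop)
  })
  res <- cbind(grid, do.call(rbind, out))
  if (sum(res$n_dropped) > 0)
    message(sum(res$n_dropped), " undefined endpoint draws dropped")
  res
}

#' Posterior toxicity endpoints
#'
#' `lcx()` propagates the joint posterior to the lethal concentration
#' `LC(x, t)` (constant-exposure endpoint), `mfx()` to the exposure
#' multiplication factor `MF(x, t)` (LPx) for a given profile, and `drt()`
#' to the x% depuration time.  Each returns the posterior median and 95%
#' credible interval per grid value.
#'
#' @param fit a [guts_fit()] object.
#' @param x percent effect value(s) in (0, 100).
#' @param t time value(s) in days (recycled against `x`).
#' @param profile an [exposure_profile()] (for `mfx`).
#' @param baseline baseline convention for `mfx`, see [mf_sd()].
#' @param ndraws optional deterministic subsample of posterior draws.
#' @return data frame with one row per (x, t) pair: `median`, `q2.5`,
#'   `q97.5`, plus bookkeeping columns.
#' @export
lcx <- function(fit, x = 50, t = NULL, ndraws = NULL) {
  stopifnot(inherits(fit, "guts_fit"))
  if (is.null(t))
    t <- max(vapply(fit$data$series, function(s) max(s$time), numeric(1)))
  n <- max(length(x), length(t))
  grid <- data.frame(x = rep_len(x, n), t = rep_len(t, n))
  fn <- if (fit$model == "SD") {
    function(params, x, t) lc_sd(params, x, t)
  } else {
    function(params, x, t) lc_it(params, x, t)
  }
  res <- endpoint_distribution(fit, fn, grid, ndraws = ndraws)
  res$model <- fit$model
  res$endpoint <- "LC"
  res
}

#' @rdname lcx
#' @export
mfx <- function(fit, profile, x = 50, t = NULL,
                baseline = c("profile", "control"), ndraws = NULL) {
  stopifnot(inherits(fit, "guts_fit"))
  baseline <- match.arg(baseline)
  if (is.null(t)) t <- max(profile$time)
  n <- max(length(x), length(t))
  grid <- data.frame(x = rep_len(x, n), t = rep_len(t, n))
  fn <- if (fit$model == "SD") {
    function(params, x, t) mf_sd(params, profile, x, t, baseline = baseline)
  } else {
    function(params, x, t) mf_it(params, profile, x, t, baseline = baseline)
  }
  res <- endpoint_distribution(fit, fn, grid, ndraws = ndraws)
  res$model <- fit$model
  res$endpoint <- "MF"
  res
}

#' @rdname lcx
#' @export
drt <- function(fit, x = 50, ndraws = NULL) {
  stopifnot(inherits(fit, "guts_fit"))
  grid <- data.frame(x = x)
  res <- endpoint_distribution(fit, function(params, x) {
    depuration_time(params$kd, x)
  }, grid, ndraws = ndraws)
  res$model <- fit$model
  res$endpoint <- "DRT"
  res
}

#' Posterior-predictive simulation of datasets
#'
#' Draws `nsim` replicate survival datasets from the posterior predictive:
#' for each replicate a joint parameter draw is selected at random and a
#' dataset is simulated under the calibration design by conditional
#' binomial sampling.
#'
#' @param object a [guts_fit()] object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of [guts_data()] objects (length `nsim`).
#' @export
simulate.guts_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed + 1L
  set.seed(as.integer(seed))
  picks <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  sub_seeds <- sample.int(2147483646L, nsim)
  design <- .design_of(object$data)
  lapply(seq_len(nsim), function(i) {
    simulate_dataset(.draw_params(object, picks[i]), design,
                     seed = sub_seeds[i])
  })
}

#' @export
residuals.guts_fit <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  params <- .params_from_vector(object$model, coef(object))
  unlist(lapply(object$data$series, function(s) {
    S <- pmax(guts_survival(params, s$profile, s$time), 1e-300)
    ratio <- pmin(S[-1L] / S[-length(S)], 1)
    nprev <- s$Nsurv[-length(s$Nsurv)]
    mu <- nprev * ratio
    r <- s$Nsurv[-1L] - mu
    if (type == "pearson") {
      v <- nprev * ratio * (1 - ratio)
      r <- r / sqrt(pmax(v, 1e-12))
    }
    stats::setNames(r, paste0(s$label, ":t", s$time[-1L]))
  }))
}

#' @export
plot.guts_fit <- function(x, which = NULL, ...) {
  series <- x$data$series
  if (!is.null(which)) series <- series[which]
  np <- length(series)
  nc <- ceiling(sqrt(np))
  nr <- ceiling(np / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in series) {
    tt <- seq(0, max(s$time), length.out = 50)
    band <- predict(x, profile = s$profile, times = tt, mode = "counts",
                    n_init = s$Nsurv[1L], ndraws = min(500, nrow(x$draws)))
    graphics::plot(s$time, s$Nsurv, ylim = c(0, s$Nsurv[1L]),
                   xlab = "time (days)", ylab = "survivors",
                   main = s$label, pch = 19)
    graphics::polygon(c(tt, rev(tt)), c(band$q2.5, rev(band$q97.5)),
                      col = grDevices::adjustcolor("grey", 0.5),
                      border = NA)
    graphics::lines(tt, band$q50, lwd = 2)
    graphics::points(s$time, s$Nsurv, pch = 19)
  }
  invisible(x)
}
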