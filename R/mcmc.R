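#' Bayesian calibration of a GUTS-RED model
#'
#' Fits the stochastic-death (SD) or individual-tolerance (IT) reduced GUTS
#' model to a survival dataset by Markov chain Monte Carlo.  Parameters are
#' sampled on the log10 scale under independent log10-uniform priors (see
#' [default_priors()]); the likelihood is the conditional binomial of
#' [guts_log_likelihood()].  The sampler is an adaptive random-walk
#' Metropolis with joint covariance adaptation during warmup (frozen
#' afterwards, so the kept draws form a valid Markov chain).  A single user
#' seed deterministically derives one RNG seed per chain: identical seed
#' and settings give identical draws.
#'
#' Convergence is summarised by the potential scale reduction factor
#' (R-hat) and effective sample size per parameter; R-hat above 1.05 or
#' effective size below 100 triggers a warning (attached to the fit, never
#' silent).
#'
#' @param data a [guts_data()] survival dataset.
#' @param model `"SD"` or `"IT"`.
#' @param priors a `guts_priors` object; default [default_priors()] on
#'   `data`.
#' @param chains number of chains (>= 2 for R-hat).
#' @param iter kept iterations per chain (after warmup, before thinning).
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param thin thinning interval; default keeps at most 10000 total draws.
#' @param seed integer seed for reproducibility.
#' @return An object of class `guts_fit` with components `draws` (matrix of
#'   posterior draws on the natural scale), `chain` (chain index per draw),
#'   `diagnostics` (R-hat, effective sample size, acceptance rates,
#'   warnings), `priors`, `data`, `settings` and `seed`.
#' @examples
#' \donttest{
#' des <- table1_design("constant")
#' truth <- sd_params(kd = 0.8, bw = 0.5, z = 2, hb = 0.01)
#' d <- simulate_dataset(truth, des, seed = 1)
#' fit <- guts_fit(d, model = "SD", chains = 2, iter = 500, warmup = 500,
#'                 seed = 1)
#' summary(fit)
#' }
#' @export
guts_fit <- function(data, model = c("SD", "IT"), priors = NULL,
                     chains = 3, iter = 5000, warmup = 5000, thin = NULL,
                     seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(data, "guts_data"), chains >= 2, iter >= 1,
            warmup >= 1)
  if (is.null(priors)) priors <- default_priors(data, model)
  stopifnot(inherits(priors, "guts_priors"))
  if (!identical(attr(priors, "model"), model))
    stop("priors were built for model ", attr(priors, "model"))
  if (is.null(thin)) thin <- max(1L, ceiling(chains * iter / 10000))

  lo <- log10(priors$lower)
  up <- log10(priors$upper)
  pnames <- priors$param
  ll <- .make_loglik(data, model)
  lp <- function(theta) {
    if (any(theta < lo | theta > up)) return(-Inf)
    ll(10^theta)
  }

  set.seed(as.integer(seed))
  chain_seeds <- sample.int(2147483646L, chains)
  keep_idx <- seq(thin, iter, by = thin)
  res <- lapply(seq_len(chains), function(ch) {
    .am_chain(lp, lo, up, iter = iter, warmup = warmup,
              seed = chain_seeds[ch], keep_idx = keep_idx)
  })

  draws10 <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(draws10) <- pnames
  chain_id <- rep(seq_len(chains), each = length(keep_idx))
  accept <- vapply(res, `[[`, numeric(1), "accept_rate")

  mcl <- coda::mcmc.list(lapply(res, function(r) coda::mcmc(r$draws)))
  rhat <- tryCatch(
    coda::gelman.diag(mcl, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, length(pnames)))
  ess <- as.numeric(coda::effectiveSize(mcl))
  names(rhat) <- names(ess) <- pnames

  warn <- character(0)
  if (any(is.na(rhat)) || any(rhat > 1.05, na.rm = TRUE))
    warn <- c(warn, paste0("R-hat > 1.05 for: ",
                           paste(pnames[is.na(rhat) | rhat > 1.05],
                                 collapse = ", ")))
  if (any(ess < 100))
    warn <- c(warn, paste0("effective sample size < 100 for: ",
                           paste(pnames[ess < 100], collapse = ", ")))
  for (w in warn) warning("guts_fit convergence: ", w, call. = FALSE)

  structure(list(
    model = model, draws = 10^draws10, chain = chain_id,
    param_names = pnames, priors = priors, data = data,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    thin = thin),
    diagnostics = list(rhat = rhat, ess = ess, accept_rate = accept,
                       warnings = warn),
    seed = as.integer(seed)), class = "guts_fit")
}

# Conditional-binomial log-likelihood closure; params as named numeric
# vector in prior order.  Constant-exposure series (the bulk of standard
# designs) are evaluated with the closed-form survival vectorised over all
# observations at once; time-variable series go through the segment-wise
# machinery.  Same math as guts_log_likelihood(), organised for the tight
# MCMC loop.
.make_loglik <- function(data, model) {
  is_const <- vapply(data$series, function(s) {
    is_constant_profile(s$profile)
  }, logical(1))
  var_series <- data$series[!is_const]

  # flatten the constant series: one row per observation
  cs <- data$series[is_const]
  if (length(cs)) {
    ctime <- unlist(lapply(cs, `[[`, "time"))
    cconc <- unlist(lapply(cs, function(s) {
      rep(s$profile$conc[1L], length(s$time))
    }))
    lens <- vapply(cs, function(s) length(s$time), integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    # transition rows: numerator (current obs) and denominator (previous)
    num <- unlist(lapply(seq_along(cs), function(i) {
      (starts[i] + 1L):ends[i]
    }))
    den <- num - 1L
    n_obs <- unlist(lapply(cs, function(s) s$Nsurv[-1L]))
    n_prev <- unlist(lapply(cs, function(s) s$Nsurv[-length(s$Nsurv)]))
  }

  maker <- if (model == "SD") {
    function(p) structure(list(kd = p[[1]], bw = p[[2]], z = p[[3]],
                               hb = p[[4]]),
                          class = c("sd_params", "guts_params"))
  } else {
    function(p) structure(list(kd = p[[1]], mw = p[[2]], beta = p[[3]],
                               hb = p[[4]]),
                          class = c("it_params", "guts_params"))
  }

  function(p) {
    tot <- 0
    if (length(cs)) {
      if (model == "SD") {
        kd <- p[[1]]; bw <- p[[2]]; z <- p[[3]]; hb <- p[[4]]
        # exceedance integral of the constant-exposure closed form
        tz <- ifelse(cconc > z,
                     if (z == 0) 0 else -log(pmax(1 - z / cconc, 0)) / kd,
                     Inf)
        above <- ctime > tz
        I <- ifelse(above,
                    cconc * (ctime - tz) - z * (ctime - tz) +
                      cconc * (exp(-kd * ctime) - exp(-kd * tz)) / kd,
                    0)
        S <- exp(-(hb * ctime + bw * I))
      } else {
        kd <- p[[1]]; mw <- p[[2]]; beta <- p[[3]]; hb <- p[[4]]
        M <- cconc * (1 - exp(-kd * ctime))
        S <- exp(-hb * ctime) / (1 + (M / mw)^beta)
      }
      S <- pmax(S, 1e-300)
      ratio <- pmin(S[num] / S[den], 1)
      tot <- sum(stats::dbinom(n_obs, n_prev, ratio, log = TRUE))
      if (!is.finite(tot)) return(-Inf)
    }
    if (length(var_series)) {
      params <- maker(p)
      for (s in var_series) {
        S <- pmax(guts_survival(params, s$profile, s$time), 1e-300)
        ratio <- pmin(S[-1L] / S[-length(S)], 1)
        tot <- tot + sum(stats::dbinom(s$Nsurv[-1L],
                                       s$Nsurv[-length(s$Nsurv)],
                                       ratio, log = TRUE))
        if (!is.finite(tot)) return(-Inf)
      }
    }
    tot
  }
}

# One adaptive random-walk Metropolis chain on a box.
# Initialisation: a few short Nelder-Mead searches locate a high-density
# start, jittered per chain.  Warmup: global step-size tuned toward 0.234
# acceptance and proposal covariance estimated Haario-style from the chain
# history (restarted at mid-warmup so the frozen proposal reflects the
# stationary regime, not the transient).  Both are frozen after warmup so
# the kept draws form a valid Markov chain.
.am_chain <- function(lp, lo, up, iter, warmup, seed, keep_idx) {
  set.seed(seed)
  d <- length(lo)
  theta <- .chain_init(lp, lo, up, d)
  lp_cur <- lp(theta)

  ls <- log(2.38 / sqrt(d))
  cov_chol <- diag((up - lo) / 50, d)
  m <- theta
  M2 <- matrix(0, d, d)
  n_hist <- 0L
  restart <- floor(warmup / 2)

  total <- warmup + iter
  kept <- matrix(NA_real_, length(keep_idx), d)
  k_ptr <- 1L
  n_acc_post <- 0L

  for (i in seq_len(total)) {
    prop <- theta + exp(ls) * as.numeric(cov_chol %*% stats::rnorm(d))
    lp_prop <- lp(prop)
    alpha <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp_cur)) else 0
    if (stats::runif(1) < alpha) {
      theta <- prop
      lp_cur <- lp_prop
      if (i > warmup) n_acc_post <- n_acc_post + 1L
    }
    if (i <= warmup) {
      ls <- ls + min(0.1, 3 / sqrt(i)) * (alpha - 0.234)
      if (i == restart) {       # drop transient history
        m <- theta
        M2 <- matrix(0, d, d)
        n_hist <- 0L
      }
      n_hist <- n_hist + 1L
      delta <- theta - m
      m <- m + delta / n_hist
      M2 <- M2 + outer(delta, theta - m)
      if (n_hist > 10 * d && i %% 50 == 0) {
        Sigma <- M2 / (n_hist - 1) + diag(1e-10, d)
        cc <- tryCatch(chol(Sigma), error = function(e) NULL)
        if (!is.null(cc)) cov_chol <- t(cc)
      }
    } else {
      j <- i - warmup
      if (k_ptr <= length(keep_idx) && j == keep_idx[k_ptr]) {
        kept[k_ptr, ] <- theta
        k_ptr <- k_ptr + 1L
      }
    }
  }
  list(draws = kept, accept_rate = n_acc_post / iter)
}

# jittered rough-mode start inside the box
.chain_init <- function(lp, lo, up, d) {
  flp <- function(th) {
    cl <- pmin(pmax(th, lo), up)
    v <- lp(cl)
    if (!is.finite(v)) v <- -1e15
    -(v - 1e4 * sum((th - cl)^2))
  }
  best <- NULL
  best_v <- Inf
  for (r in 1:4) {
    th0 <- lo + stats::runif(d) * (up - lo)
    o <- tryCatch(stats::optim(th0, flp, method = "Nelder-Mead",
                               control = list(maxit = 300)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < best_v) {
      best_v <- o$value
      best <- o$par
    }
  }
  if (is.null(best) || !is.finite(best_v)) best <- (lo + up) / 2
  theta <- pmin(pmax(best + 0.25 * stats::rnorm(d), lo), up)
  if (!is.finite(lp(theta))) theta <- pmin(pmax(best, lo), up)
  tries <- 0
  while (!is.finite(lp(theta)) && tries < 100) {
    theta <- lo + stats::runif(d) * (up - lo)
    tries <- tries + 1
  }
  if (!is.finite(lp(theta)))
    stop("could not find a starting point with finite posterior density")
  theta
}

# Parameter object for posterior draw j.
.draw_params <- function(fit, j) {
  p <- fit$draws[j, ]
  if (fit$model == "SD") {
    structure(list(kd = p[["kd"]], bw = p[["bw"]], z = p[["z"]],
                   hb = p[["hb"]]),
              class = c("sd_params", "guts_params"))
  } else {
    structure(list(kd = p[["kd"]], mw = p[["mw"]], beta = p[["beta"]],
                   hb = p[["hb"]]),
              class = c("it_params", "guts_params"))
  }
}

#' @export
print.guts_fit <- function(x, ...) {
  cat("GUTS-RED-", x$model, " fit: ", nrow(x$draws), " posterior draws (",
      x$settings$chains, " chains)\n", sep = "")
  print(summary(x)$estimates, digits = 4)
  if (length(x$diagnostics$warnings))
    cat("Convergence warnings:\n ",
        paste(x$diagnostics$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
summary.guts_fit <- function(object, ...) {
  qs <- t(apply(object$draws, 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975), type = 7))
  est <- data.frame(median = qs[, 2], q2.5 = qs[, 1], q97.5 = qs[, 3],
                    rhat = object$diagnostics$rhat,
                    n_eff = round(object$diagnostics$ess))
  out <- list(model = object$model, estimates = est,
              n_draws = nrow(object$draws),
              settings = object$settings,
              warnings = object$diagnostics$warnings)
  class(out) <- "summary.guts_fit"
  out
}

#' @export
print.summary.guts_fit <- function(x, ...) {
  cat("GUTS-RED-", x$model, " posterior summary (", x$n_draws,
      " draws):\n", sep = "")
  print(x$estimates, digits = 4)
  if (length(x$warnings))
    cat("Convergence warnings:\n  ", paste(x$warnings, collapse = "\n  "),
        "\n")
  invisible(x)
}

#' @export
coef.guts_fit <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' @export
logLik.guts_fit <- function(object, ...) {
  params <- .params_from_vector(object$model, coef(object))
  val <- guts_log_likelihood(params, object$data)
  structure(val, df = ncol(object$draws), class = "logLik")
}

.params_from_vector <- function(model, p) {
  if (model == "SD") sd_params(p[["kd"]], p[["bw"]], p[["z"]], p[["hb"]])
  else it_params(p[["kd"]], p[["mw"]], p[["beta"]], p[["hb"]])
}

#' Export posterior draws
#'
#' One row per draw, one column per parameter (natural scale) plus a
#' `chain` column, matching the on-disk posterior CSV format.
#'
#' @param fit a [guts_fit()] object.
#' @return a data frame.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "guts_fit"))
  cbind(as.data.frame(fit$draws), chain = fit$chain)
}
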