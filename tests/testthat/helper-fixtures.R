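# Shared fixtures: ground-truth parameter sets, tiny datasets, and a
# constructor for posterior objects with known draws (used to test the
# posterior machinery against enumeration/brute-force oracles).

truth_sd <- function() sd_params(kd = 0.8, bw = 0.5, z = 2, hb = 0.01)
truth_it <- function() it_params(kd = 0.8, mw = 2, beta = 2, hb = 0.01)

const_profile <- function(conc, label = paste0("C", conc)) {
  exposure_profile(0, conc, label = label)
}

# dataset with known counts on a constant profile
tiny_data <- function(conc = 2, counts = c(20, 18, 15, 12, 10),
                      label = "A") {
  guts_data(data.frame(profile = label, time = seq_along(counts) - 1,
                       conc = conc, Nsurv = counts))
}

# a guts_fit shell around an explicit draw matrix
fake_fit <- function(draws, model, data, chain = NULL, seed = 1L) {
  draws <- as.matrix(draws)
  if (is.null(chain)) chain <- rep(1L, nrow(draws))
  structure(list(model = model, draws = draws, chain = chain,
                 param_names = colnames(draws), priors = NULL,
                 data = data, settings = list(),
                 diagnostics = list(rhat = NULL, ess = NULL,
                                    warnings = character(0)),
                 seed = seed),
            class = "guts_fit")
}

draws_matrix <- function(model, ...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, unlist))
  colnames(m) <- if (model == "SD") c("kd", "bw", "z", "hb")
                 else c("kd", "mw", "beta", "hb")
  m
}

# random rectangular pulse profile (for oracle-agreement property tests)
random_pulse_profile <- function(total = 12) {
  n <- sample(1:3, 1)
  width <- stats::runif(1, 0.3, 1.5)
  starts <- sort(stats::runif(n, 0, total - width))
  while (n > 1 && any(diff(starts) < width)) {
    starts <- sort(stats::runif(n, 0, total - width))
  }
  pulse_profile(n, amplitude = stats::runif(1, 0.5, 6), width = width,
                start_times = starts, total_duration = total,
                label = "rand")
}

# high-resolution numerical ODE solution of the damage equation (oracle)
ode_damage <- function(profile, kd, tout) {
  f <- function(t, y, parms) list(kd * (conc_at(profile, t) - y))
  times <- sort(unique(c(seq(0, max(tout), by = 0.005), profile$time,
                         tout)))
  times <- times[times <= max(tout)]
  res <- deSolve::lsoda(c(D = 0), times = times, func = f, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  stats::approx(res[, 1], res[, 2], xout = tout)$y
}
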