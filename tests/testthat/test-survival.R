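test_that("SD survival reduces to background mortality below threshold", {
  params <- sd_params(kd = 1, bw = 5, z = 3, hb = 0.05)
  p <- exposure_profile(0, 2)  # C_w < z: threshold never reached
  tt <- 0:6
  expect_equal(survival_sd(params, p, tt), exp(-0.05 * tt))
  # no exposure, no background: survival 1
  expect_equal(survival_sd(sd_params(1, 1, 0.5, 0), exposure_profile(0, 0),
                           tt), rep(1, 7))
})

test_that("SD hazard integral matches adaptive quadrature", {
  set.seed(17)
  for (i in 1:12) {
    kd <- runif(1, 0.3, 2); bw <- runif(1, 0.1, 2)
    z <- runif(1, 0.2, 2);  hb <- runif(1, 0, 0.05)
    params <- sd_params(kd, bw, z, hb)
    Cw <- runif(1, z * 0.5, z * 4)
    p <- exposure_profile(0, Cw)
    tt <- c(1, 2.5, 4)
    S <- survival_sd(params, p, tt)
    # split the quadrature at the threshold-crossing kink for full accuracy
    tz <- if (Cw > z) -log(1 - z / Cw) / kd else Inf
    Sq <- vapply(tt, function(t1) {
      h <- function(u) bw * pmax(Cw * (1 - exp(-kd * u)) - z, 0) + hb
      v <- if (t1 <= tz) integrate(h, 0, t1, rel.tol = 1e-12)$value
           else integrate(h, 0, tz, rel.tol = 1e-12)$value +
                integrate(h, tz, t1, rel.tol = 1e-12)$value
      exp(-v)
    }, numeric(1))
    expect_equal(S, Sq, tolerance = 1e-8)
  }
  # time-variable profile against quadrature on the analytic damage
  params <- sd_params(0.7, 0.5, 1, 0.01)
  lin <- exposure_profile(c(0, 2, 4), c(0, 4, 0), interpolation = "linear")
  S <- survival_sd(params, lin, c(2, 4, 6))
  Sq <- vapply(c(2, 4, 6), function(t1) {
    h <- function(u) {
      D <- vapply(u, function(x) scaled_damage(lin, 0.7, x), numeric(1))
      0.5 * pmax(D - 1, 0) + 0.01
    }
    exp(-integrate(h, 0, t1, rel.tol = 1e-12)$value)
  }, numeric(1))
  expect_equal(S, Sq, tolerance = 1e-8)
})

test_that("IT survival follows the log-logistic threshold distribution", {
  tt <- 0:5
  # no exposure: background only
  params <- it_params(kd = 1, mw = 2, beta = 2, hb = 0.03)
  expect_equal(survival_it(params, exposure_profile(0, 0), tt),
               exp(-0.03 * tt))
  # damage at the median threshold kills half the cohort
  p1 <- exposure_profile(0, 2)  # C_w = 2 m_w, kd = ln 2: maxD(1) = m_w
  expect_equal(survival_it(it_params(log(2), 1, 1, 0), p1, 1), 0.5)
  # fast kinetics, C_w = m_w: S approaches 0.5 from above
  expect_equal(survival_it(it_params(50, 2, 3, 0), p1, 1), 0.5,
               tolerance = 1e-6)
  expect_equal(survival_it(params, p1, 0), 1)
})

test_that("survival curves are non-increasing and dominated by exposure", {
  set.seed(31)
  tt <- seq(0, 12, by = 0.5)
  for (i in 1:6) {
    prof <- random_pulse_profile()
    sd_p <- sd_params(runif(1, 0.3, 2), runif(1, 0.1, 2),
                      runif(1, 0.1, 2), runif(1, 0, 0.05))
    it_p <- it_params(runif(1, 0.3, 2), runif(1, 0.5, 3),
                      runif(1, 0.5, 3), runif(1, 0, 0.05))
    S1 <- survival_sd(sd_p, prof, tt)
    S2 <- survival_it(it_p, prof, tt)
    expect_true(all(diff(S1) <= 1e-12))
    expect_true(all(diff(S2) <= 1e-12))
    # pointwise-larger exposure cannot increase survival
    up <- scale_profile(prof, 1.7)
    expect_true(all(survival_sd(sd_p, up, tt) <= S1 + 1e-12))
    expect_true(all(survival_it(it_p, up, tt) <= S2 + 1e-12))
  }
})

test_that("general segment path agrees with the constant fast path", {
  # same constant exposure encoded as one breakpoint vs many
  single <- exposure_profile(0, 2.5)
  multi <- exposure_profile(0:4, rep(2.5, 5), interpolation = "linear")
  sd_p <- sd_params(0.9, 0.4, 1.2, 0.02)
  it_p <- it_params(0.9, 1.5, 2, 0.02)
  tt <- c(0, 0.7, 1.9, 3.2, 4)
  expect_equal(survival_sd(sd_p, single, tt), survival_sd(sd_p, multi, tt),
               tolerance = 1e-12)
  expect_equal(survival_it(it_p, single, tt), survival_it(it_p, multi, tt),
               tolerance = 1e-12)
})

test_that("conditional-binomial likelihood matches hand computation", {
  # probability-one data: no exposure, no background, no deaths
  d0 <- guts_data(data.frame(profile = "c", time = 0:3, conc = 0,
                             Nsurv = 20))
  expect_identical(guts_log_likelihood(sd_params(1, 1, 1, 0), d0), 0)

  # single interval with S-ratio exactly 0.5 (hb = ln 2, no exposure)
  d1 <- guts_data(data.frame(profile = "c", time = 0:1, conc = 0,
                             Nsurv = c(20, 10)))
  expect_equal(guts_log_likelihood(sd_params(1, 1, 1, log(2)), d1),
               lchoose(20, 10) + 20 * log(0.5))

  # additivity across series
  df2 <- data.frame(profile = rep(c("a", "b"), each = 2), time = c(0, 1),
                    conc = rep(c(2, 4), each = 2),
                    Nsurv = c(20, 15, 20, 9))
  params <- sd_params(0.8, 0.5, 1, 0.01)
  d_ab <- guts_data(df2)
  ll_a <- guts_log_likelihood(params, guts_data(df2[1:2, ]))
  ll_b <- guts_log_likelihood(params, guts_data(df2[3:4, ]))
  expect_equal(guts_log_likelihood(params, d_ab), ll_a + ll_b)

  # per-observation decomposition sums to the total
  expect_equal(sum(guts_log_likelihood(params, d_ab, by_obs = TRUE)),
               ll_a + ll_b)

  # increasing counts are rejected at construction, with the row named
  expect_error(guts_data(data.frame(profile = "c", time = 0:2, conc = 0,
                                    Nsurv = c(20, 18, 19))),
               "row 3")
})

test_that("the vectorised sampler likelihood equals the reference one", {
  # mixed dataset: constant ladder plus a pulsed series
  des <- table1_design("constant")
  d_const <- simulate_dataset(truth_sd(), des, seed = 44)
  df <- as.data.frame(d_const)
  pulse <- pulse_profile(2, 6, 1, c(0, 3), 4, label = "P")
  d_mix <- guts_data(
    rbind(df, data.frame(profile = "P", time = 0:4,
                         conc = conc_at(pulse, 0:4),
                         Nsurv = c(20, 15, 12, 10, 8))),
    exposure = data.frame(profile = c(unique(df$profile),
                                      rep("P", length(pulse$time))),
                          time = c(rep(0, 8), pulse$time),
                          conc = c(vapply(d_const$series,
                                          function(s) s$profile$conc[1],
                                          numeric(1)), pulse$conc)),
    interpolation = "const")
  set.seed(45)
  for (model in c("SD", "IT")) {
    ll_fast <- gutsred:::.make_loglik(d_mix, model)
    for (i in 1:5) {
      p <- c(runif(1, 0.3, 2), runif(1, 0.2, 2), runif(1, 0.5, 3),
             runif(1, 0, 0.05))
      params <- if (model == "SD") sd_params(p[1], p[2], p[3], p[4])
                else it_params(p[1], p[2], p[3], p[4])
      expect_equal(ll_fast(p), guts_log_likelihood(params, d_mix),
                   tolerance = 1e-12)
    }
  }
})
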