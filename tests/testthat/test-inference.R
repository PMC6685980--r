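test_that("default priors encode the experimental design", {
  des <- table1_design("constant")
  d <- simulate_dataset(truth_sd(), des, seed = 1)
  pr <- default_priors(d, "SD")
  expect_setequal(pr$param, c("kd", "bw", "z", "hb"))
  # kd bounds: 0.1% of equilibrium over the experiment, 99.9% within the
  # shortest observation gap
  expect_equal(pr$lower[pr$param == "kd"], -log(1 - 0.001) / 4)
  expect_equal(pr$upper[pr$param == "kd"], -log(0.001) / 1)
  # threshold bounds span the tested positive concentrations
  expect_equal(pr$lower[pr$param == "z"], 0.5)
  expect_equal(pr$upper[pr$param == "z"], 8)
  expect_equal(pr$lower[pr$param == "bw"], 1e-4)
  expect_equal(pr$upper[pr$param == "bw"], 1e4)

  pr_it <- default_priors(d, "IT")
  expect_setequal(pr_it$param, c("kd", "mw", "beta", "hb"))
  expect_equal(pr_it$lower[pr_it$param == "beta"], 1e-2)

  # identical designs give identical priors
  d2 <- simulate_dataset(truth_sd(), des, seed = 99)
  expect_identical(default_priors(d2, "SD"), pr)

  # a design with no positive concentration cannot inform thresholds
  ctrl_only <- guts_data(data.frame(profile = "c", time = 0:4, conc = 0,
                                    Nsurv = 20))
  expect_error(default_priors(ctrl_only, "SD"), "positive concentrations")
})

test_that("fitting is deterministic given a seed", {
  des <- table1_design("constant")
  d <- simulate_dataset(truth_sd(), des, seed = 2)
  f1 <- suppressWarnings(guts_fit(d, "SD", chains = 2, iter = 150,
                                  warmup = 150, seed = 5))
  f2 <- suppressWarnings(guts_fit(d, "SD", chains = 2, iter = 150,
                                  warmup = 150, seed = 5))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(guts_fit(d, "SD", chains = 2, iter = 150,
                                  warmup = 150, seed = 6))
  expect_false(identical(f1$draws, f3$draws))
  expect_equal(nrow(f1$draws), 300)
  expect_named(f1$diagnostics$rhat, c("kd", "bw", "z", "hb"))
})

test_that("an uninformative dataset returns the prior for the threshold", {
  # controls only at zero concentration, plus one trace-positive series so
  # priors exist: the likelihood carries no information on mw
  df <- data.frame(profile = rep(c("a", "b"), each = 5), time = 0:4,
                   conc = rep(c(0, 1e-8), each = 5), Nsurv = 20L)
  d <- guts_data(df)
  pr <- default_priors(d, "IT")
  pr$lower[pr$param == "mw"] <- 0.5
  pr$upper[pr$param == "mw"] <- 8
  attr(pr, "model") <- "IT"
  fit <- suppressWarnings(guts_fit(d, "IT", priors = pr, chains = 2,
                                   iter = 2000, warmup = 1000, seed = 3))
  lmw <- log10(fit$draws[, "mw"])
  # log10(mw) should look uniform on [log10(0.5), log10(8)]
  expect_equal(mean(lmw), mean(log10(c(0.5, 8))), tolerance = 0.1)
  expect_equal(stats::sd(lmw), diff(log10(c(0.5, 8))) / sqrt(12),
               tolerance = 0.1)
})

test_that("posterior survival bands behave at the edges", {
  d <- tiny_data()
  dr <- draws_matrix("SD",
                     c(kd = 0.8, bw = 0.5, z = 2, hb = 0.01),
                     c(kd = 0.8, bw = 0.5, z = 2, hb = 0.01))
  fit <- fake_fit(dr, "SD", d)
  band <- predict(fit, times = c(0, 1, 2, 4))
  # degenerate posterior: band collapses onto the deterministic curve
  S <- survival_sd(truth_sd(), d$series[[1]]$profile, c(0, 1, 2, 4))
  expect_equal(band$q2.5, S)
  expect_equal(band$q50, S)
  expect_equal(band$q97.5, S)
  expect_equal(unlist(band[band$time == 0, c("q2.5", "q50", "q97.5")]),
               c(q2.5 = 1, q50 = 1, q97.5 = 1))
  expect_error(predict(fit, times = numeric(0)), "non-empty")
})

test_that("count-mode predictive quantiles match exhaustive enumeration", {
  d <- tiny_data()
  dr <- draws_matrix("SD",
                     c(kd = 0.9, bw = 0.4, z = 1, hb = 0.05),
                     c(kd = 0.5, bw = 0.8, z = 2, hb = 0.01))
  fit <- fake_fit(dr, "SD", d)
  t1 <- 2.5
  band <- predict(fit, times = t1, mode = "counts", n_init = 3)
  # brute force: mixture over the two draws of Binomial(3, S_j(t))
  S <- vapply(1:2, function(j) {
    guts_survival(gutsred:::.draw_params(fit, j), d$series[[1]]$profile, t1)
  }, numeric(1))
  pmf <- (dbinom(0:3, 3, S[1]) + dbinom(0:3, 3, S[2])) / 2
  cdf <- cumsum(pmf)
  expected <- vapply(c(0.025, 0.5, 0.975),
                     function(q) (0:3)[which(cdf >= q - 1e-12)[1]],
                     numeric(1))
  expect_equal(unlist(band[1, c("q2.5", "q50", "q97.5")], use.names = FALSE),
               expected)
})

test_that("pooled quantile summaries are invariant to chain order", {
  des <- table1_design("constant")
  d <- simulate_dataset(truth_sd(), des, seed = 4)
  fit <- suppressWarnings(guts_fit(d, "SD", chains = 2, iter = 200,
                                   warmup = 200, seed = 9))
  perm <- order(fit$chain, decreasing = TRUE)
  fit2 <- fit
  fit2$draws <- fit$draws[perm, ]
  fit2$chain <- fit$chain[perm]
  expect_equal(summary(fit2)$estimates[, c("median", "q2.5", "q97.5")],
               summary(fit)$estimates[, c("median", "q2.5", "q97.5")])
})

test_that("endpoint distributions summarise posterior draws exactly", {
  d <- tiny_data()
  # degenerate posterior: all quantiles equal the point value
  dr <- draws_matrix("IT", c(kd = 1, mw = 2, beta = 2, hb = 0),
                     c(kd = 1, mw = 2, beta = 2, hb = 0))
  fit <- fake_fit(dr, "IT", d)
  res <- lcx(fit, x = 50, t = 4)
  pt <- lc_it(it_params(1, 2, 2, 0), 50, 4)
  expect_equal(res$median, pt)
  expect_equal(res$q2.5, pt)
  expect_equal(res$q97.5, pt)

  # quantiles match a direct sort of per-draw evaluations
  set.seed(61)
  n <- 40
  dr2 <- cbind(kd = runif(n, 0.5, 1.5), mw = runif(n, 1, 3),
               beta = runif(n, 1, 3), hb = runif(n, 0, 0.02))
  fit2 <- fake_fit(dr2, "IT", d)
  res2 <- lcx(fit2, x = 50, t = 4)
  vals <- vapply(seq_len(n), function(j) {
    lc_it(it_params(dr2[j, 1], dr2[j, 2], dr2[j, 3], dr2[j, 4]), 50, 4)
  }, numeric(1))
  qs <- quantile(vals, c(0.025, 0.5, 0.975), type = 7)
  expect_equal(res2$median, unname(qs[2]))
  expect_equal(res2$q2.5, unname(qs[1]))
  expect_equal(res2$q97.5, unname(qs[3]))

  # depuration-time distribution is a pure transform of kd
  res3 <- drt(fit2, x = 50)
  expect_equal(res3$median,
               unname(quantile(log(2) / dr2[, "kd"], 0.5, type = 7)))
})

test_that("mostly-undefined endpoints are refused, not summarised", {
  d <- tiny_data()
  dr <- draws_matrix("IT", c(kd = 1, mw = 2, beta = 2, hb = 0),
                     c(kd = 1.2, mw = 2, beta = 2, hb = 0),
                     c(kd = 0.8, mw = 2, beta = 2, hb = 0))
  fit <- fake_fit(dr, "IT", d)
  flaky <- function(params, x) if (params$kd > 0.9) NA_real_ else params$kd
  expect_error(endpoint_distribution(fit, flaky, data.frame(x = 1)),
               "50%")
})

test_that("LC uncertainty grows toward extreme x", {
  d <- tiny_data()
  set.seed(67)
  n <- 60
  dr <- cbind(kd = runif(n, 0.5, 1.5), mw = runif(n, 1, 3),
              beta = runif(n, 0.8, 2.5), hb = runif(n, 0, 0.02))
  fit <- fake_fit(dr, "IT", d)
  res <- lcx(fit, x = c(5, 50, 95), t = 4)
  rel_width <- (res$q97.5 - res$q2.5) / res$median
  expect_gt(rel_width[1], rel_width[2])
  expect_gt(rel_width[3], rel_width[2])
})
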