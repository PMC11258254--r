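# Trace fitting, power regression, branching ratio, model discrimination.

test_that("decay fit recovers rate, amplitude and offset from noiseless traces", {
  tg <- seq(0, 120, 2)
  tr <- mrm_trace(tg, exp(-0.0442 * tg), "A", 242)
  fit <- fit_decay(tr)
  expect_equal(fit$lambda_A, 0.0442, tolerance = 1e-6)
  expect_false(fit$degenerate)

  tr2 <- mrm_trace(tg, 0.9 * exp(-0.0442 * tg) + 0.05, "A", 242)
  fit2 <- fit_decay(tr2)
  expect_equal(fit2$lambda_A, 0.0442, tolerance = 1e-6)
  expect_equal(fit2$I0, 0.05, tolerance = 1e-6)
  expect_equal(fit2$A0_hat, 0.9, tolerance = 1e-6)
})

test_that("a constant trace yields a degenerate zero-rate fit, not an error", {
  tr <- mrm_trace(seq(0, 100, 10), rep(0.7, 11), "A", 100)
  fit <- fit_decay(tr)
  expect_true(fit$degenerate)
  expect_equal(fit$lambda_A, 0)
  expect_equal(fit$I0, 0.7)
})

test_that("buildup fit recovers k2[hv] in its regime of validity", {
  # generator = the late-time representation itself (exact recovery)
  tg <- seq(0, 300, 2)
  D0 <- 0.0442 / (0.0442 - 0.0099)
  tr <- mrm_trace(tg, 1 - D0 * exp(-0.0099 * tg), "D", 242)
  fit <- fit_buildup(tr)
  expect_equal(fit$k2_hv, 0.0099, tolerance = 1e-6)
  expect_false(fit$ill_conditioned)

  # generator = the full closed form, in the regime k2[hv] << (k1+k3)[hv]
  # where the neglected fast exponential is negligible past t_min
  p <- photolysis_params(k1 = 2.9e-3, k2 = 6e-5, k3 = 1e-4)
  hv <- 100  # lamA = 0.3 s^-1, mu = 6e-3 s^-1
  sim <- simulate_mrm_traces("II", p, hv, seq(0, 800, 4))
  d <- sim[sim$species == "D", ]
  fit2 <- fit_buildup(mrm_trace(d$time_s, d$intensity, "D", hv))
  expect_equal(fit2$k2_hv, p$k2 * hv, tolerance = 1e-3)
})

test_that("a plateau-only D trace flags the rate as ill-conditioned", {
  tg <- seq(500, 700, 10)
  y <- 1 - 1.2 * exp(-0.05 * tg)   # numerically flat at these times
  fit <- fit_buildup(mrm_trace(tg, y, "D", 100), t_min = 500)
  expect_true(fit$ill_conditioned)
  expect_equal(fit$plateau, 1, tolerance = 1e-6)
})

test_that("buildup fit validates its time window", {
  tg <- seq(0, 15, 1)
  expect_error(fit_buildup(mrm_trace(tg, 1 - exp(-0.1 * tg), "D", 100),
                           t_min = 20),
               class = "photoxl_validation")
})

test_that("rate fits are invariant to uniform intensity rescaling", {
  tg <- seq(0, 200, 4)
  yA <- 0.8 * exp(-0.03 * tg) + 0.02
  for (s in c(1, 7.5)) {
    f <- fit_decay(mrm_trace(tg, s * yA, "A", 100))
    expect_equal(f$lambda_A, 0.03, tolerance = 1e-6)
  }
  yD <- 1 - 1.3 * exp(-0.008 * tg)
  k <- vapply(c(1, 7.5), function(s)
    fit_buildup(mrm_trace(tg, s * yD, "D", 100))$k2_hv, 0)
  expect_equal(k[1], k[2], tolerance = 1e-8)
})

test_that("power regression recovers the per-photon slope", {
  pts <- data.frame(power = c(101, 150, 242),
                    rate = c(101, 150, 242) * 2.32e-4)
  reg <- regress_rates_vs_power(pts)
  expect_equal(reg$slope, 2.32e-4, tolerance = 1e-10)
  expect_equal(reg$intercept, 0)

  pts0 <- data.frame(power = c(50, 100), rate = c(0, 0))
  reg0 <- regress_rates_vs_power(pts0, intercept = TRUE)
  expect_equal(reg0$slope, 0)
  expect_equal(reg0$intercept, 0)
  expect_error(regress_rates_vs_power(data.frame(power = c(100, 100),
                                                 rate = c(1, 2))),
               class = "photoxl_validation")
})

test_that("weighted regression equals the normal-equations oracle", {
  set.seed(3)
  pts <- data.frame(power = c(35, 101, 150, 200, 242),
                    rate = c(35, 101, 150, 200, 242) * 2.32e-4 +
                      rnorm(5, 0, 1e-3),
                    sd = c(0.5, 1, 2, 1.5, 3) * 1e-3)
  reg <- regress_rates_vs_power(pts)
  expect_true(reg$weighted)
  expect_equal(reg$slope,
               wls_slope_oracle(pts$power, pts$rate, 1 / pts$sd^2),
               tolerance = 1e-12)
})

test_that("joint model-II fit recovers the branching ratio", {
  tg <- seq(0, 600, 5)
  sim <- simulate_mrm_traces("II", reference_kin(0.92), 35, tg)
  A <- sim[sim$species == "A", ]; D <- sim[sim$species == "D", ]
  jf <- fit_model_II_joint(mrm_trace(A$time_s, A$intensity, "A", 35),
                           mrm_trace(D$time_s, D$intensity, "D", 35))
  expect_equal(jf$branching$ratio, 0.92, tolerance = 1e-4)

  # model I nesting: k3 = 0 implies ratio 1
  p1 <- photolysis_params(2.32e-4, 0.73e-4, 0)
  sim1 <- simulate_mrm_traces("I", p1, 35, tg)
  A1 <- sim1[sim1$species == "A", ]; D1 <- sim1[sim1$species == "D", ]
  jf1 <- fit_model_II_joint(mrm_trace(A1$time_s, A1$intensity, "A", 35),
                            mrm_trace(D1$time_s, D1$intensity, "D", 35))
  expect_equal(jf1$branching$ratio, 1, tolerance = 1e-4)
})

test_that("branching recovery is unbiased under multiplicative noise", {
  tg <- seq(0, 600, 10)
  ratios <- vapply(1:50, function(i) {
    sim <- simulate_mrm_traces("II", reference_kin(0.92), 35, tg,
                               noise = noise_model(sd = 0.02, seed = 100 + i))
    A <- sim[sim$species == "A", ]; D <- sim[sim$species == "D", ]
    fit_model_II_joint(mrm_trace(A$time_s, A$intensity, "A", 35),
                       mrm_trace(D$time_s, D$intensity, "D", 35))$branching$ratio
  }, 0)
  expect_lt(abs(mean(ratios) - 0.92), 2 * sd(ratios))
})

test_that("95% intervals of the decay rate cover the truth in most replicates", {
  tg <- seq(0, 120, 4)
  lam <- 2.32e-4 * 242   # generating composite rate at this power
  cover <- vapply(1:200, function(i) {
    sim <- simulate_mrm_traces("II", reference_kin(), 242, tg,
                               noise = noise_model(sd = 0.02, seed = 1000 + i),
                               species = "A")
    # multiplicative noise: weight by the inverse squared signal so the
    # standard errors are calibrated
    f <- fit_decay(mrm_trace(sim$time_s, sim$intensity, "A", 242),
                   weights = 1 / pmax(sim$intensity, 0.01)^2)
    se <- sqrt(f$vcov["lambda", "lambda"])
    abs(f$lambda_A - lam) <= 1.96 * se
  }, NA)
  expect_gte(mean(cover), 0.9)
})

test_that("discrimination recovers the generating model across a parameter grid", {
  tg <- seq(0, 300, 5)
  powers <- c(101, 242)
  cases <- list()
  for (k1 in c(1.5e-4, 2.32e-4, 3e-4)) {
    cases <- c(cases,
      list(list("I",  photolysis_params(k1, 0.7e-4, 0)),
           list("II", photolysis_params(k1, 0.7e-4, 0.25 * k1)),
           list("III", photolysis_params(k1, 0.01, 0.2e-4)),
           list("IV", photolysis_params(k1, 0, 0.5e-4))))
  }
  verdicts <- vapply(cases, function(cs) {
    sim <- simulate_mrm_traces(cs[[1]], cs[[2]], powers, tg)
    discriminate_models(sim)$verdict
  }, "")
  truth <- vapply(cases, `[[`, "", 1)
  expect_gte(mean(verdicts == truth), 0.95)
})

test_that("a single power level yields a partial verdict, not a crash", {
  sim <- simulate_mrm_traces("II", reference_kin(), 242, seq(0, 300, 5))
  dm <- discriminate_models(sim)
  expect_true(is.na(dm$verdict))
  expect_match(dm$untestable, "III")
})

test_that("fit reports are tidy parameter tables", {
  tg <- seq(0, 120, 2)
  f <- fit_decay(mrm_trace(tg, exp(-0.0442 * tg) + 0.01, "A", 242))
  rep <- fit_report(f)
  expect_named(rep, c("parameter", "estimate", "sd", "unit"))
  expect_equal(rep$estimate[rep$parameter == "lambda_A"], 0.0442,
               tolerance = 1e-5)
})
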