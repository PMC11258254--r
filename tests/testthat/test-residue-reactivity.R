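# Five-channel reactivity model: profiles, weight fitting, mechanism
# classification, yield surfaces, water quenching.

test_that("all channel profiles vanish without irradiation", {
  pre <- reactivity_preset("diazo-dominant")
  for (cond in list(irradiation_condition(100, 0),
                    irradiation_condition(0, 60))) {
    prof <- elementary_profiles(pre$kin, pre$ch, cond)
    expect_equal(unlist(prof[, c("I_b1", "I_b2", "I_b3", "I_b4", "I_c")]),
                 setNames(rep(0, 5), c("I_b1", "I_b2", "I_b3", "I_b4", "I_c")))
  }
})

test_that("diazo channels are unimodal and the carbene channel monotone in power", {
  hv <- seq(1, 300, 1)
  for (nm in c("diazo-dominant", "carbene-dominant", "mixed")) {
    pre <- reactivity_preset(nm)
    prof <- elementary_profiles(pre$kin, pre$ch,
                                irradiation_condition(hv, 60))
    for (col in c("I_b1", "I_b2", "I_b3", "I_b4")) {
      y <- prof[[col]]
      if (max(y) == 0) next   # channel switched off in this preset
      # unimodal: the sign of the first difference changes exactly once
      sgn <- sign(diff(y))
      sgn <- sgn[sgn != 0]
      expect_equal(sum(diff(sgn) != 0), 1)
      expect_true(which.max(y) > 1 && which.max(y) < length(y))
    }
    expect_false(is.unsorted(prof$I_c))
    expect_true(all(as.matrix(prof[, 3:7]) >= 0) &&
                  all(as.matrix(prof[, 3:7]) <= 1))
  }
})

test_that("carbene channel is nondecreasing in time as well", {
  pre <- reactivity_preset("diazo-dominant")
  prof <- elementary_profiles(pre$kin, pre$ch,
                              irradiation_condition(100, seq(5, 300, 5)))
  expect_false(is.unsorted(prof$I_c))
})

test_that("channel products never exceed the consumed diazirine", {
  pre <- reactivity_preset("diazo-dominant")
  grid <- expand.grid(hv = c(10, 50, 100, 200, 300),
                      t = c(10, 60, 120, 300))
  prof <- elementary_profiles(pre$kin, pre$ch,
                              irradiation_condition(grid$hv, grid$t),
                              coupled = TRUE)
  consumed <- 1 - exp(-(pre$kin$k1 + pre$kin$k3) * grid$hv * grid$t)
  total <- rowSums(prof[, c("I_b1", "I_b2", "I_b3", "I_b4", "I_c")])
  expect_true(all(total <= consumed + 1e-12))
})

test_that("the saturating-channel limit recovers the diazo branching fraction", {
  kin <- reference_kin(0.92)
  ch <- channel_params(kappa1 = 1e6, kappa2 = 0, kappa3 = 0, kappa4 = 0,
                       kappa_c = 0, pKa = 20, pH = 7)  # all-protonated target
  prof <- elementary_profiles(kin, ch, irradiation_condition(100, 600))
  consumed <- 1 - exp(-(kin$k1 + kin$k3) * 100 * 600)
  expect_equal(prof$I_b1, kin$k1 / (kin$k1 + kin$k3) * consumed,
               tolerance = 1e-3)
})

test_that("the coupled five-channel model conserves mass to 1e-9", {
  for (nm in c("diazo-dominant", "carbene-dominant", "mixed")) {
    pre <- reactivity_preset(nm)
    for (hv in c(10, 100, 300)) {
      for (t in c(10, 120, 600)) {
        mb <- channel_mass_balance(pre$kin, pre$ch,
                                   irradiation_condition(hv, t))
        expect_lt(abs(mb$total - pre$kin$A0), 1e-9)
      }
    }
  }
})

test_that("generating weights are recovered from noiseless curves", {
  conds <- yield_conditions()
  for (nm in c("diazo-dominant", "carbene-dominant", "mixed")) {
    pre <- reactivity_preset(nm)
    cur <- simulate_yield_curves(nm, conds)
    w <- suppressWarnings(fit_weights(cur, pre$kin, pre$ch))
    tw <- pre$weights
    expect_lt(max(abs(c(w$b1, w$b2, w$b3, w$b4, w$c) -
                        c(tw$b1, tw$b2, tw$b3, tw$b4, tw$c))), 0.05)
    expect_equal(w$mechanism_score, tw$mechanism_score, tolerance = 0.05)
  }
})

test_that("mechanism sign is recovered under 2% noise in >= 95% of cases", {
  conds <- yield_conditions()
  n <- 40; ok <- 0
  presets <- rep(c("diazo-dominant", "carbene-dominant"), length.out = n)
  for (i in seq_len(n)) {
    pre <- reactivity_preset(presets[i])
    cur <- simulate_yield_curves(presets[i], conds,
                                 noise_model(sd = 0.02, seed = 500 + i))
    w <- suppressWarnings(fit_weights(cur, pre$kin, pre$ch))
    ok <- ok + (sign(w$mechanism_score) ==
                  sign(pre$weights$mechanism_score))
  }
  expect_gte(ok / n, 0.95)
})

test_that("pure and balanced mechanisms classify as expected", {
  expect_equal(classify_mechanism(elementary_weights(c(0.3, 0.3, 0.2, 0.15),
                                                     0.05))$label, "diazo")
  expect_equal(classify_mechanism(elementary_weights(c(0.01, 0.01, 0.02,
                                                       0.01), 0.95))$label,
               "carbene")
  expect_equal(classify_mechanism(elementary_weights(c(0.125, 0.125, 0.125,
                                                       0.125), 0.5))$label,
               "mixed")
  # score identity under normalization: score = 1 - 2c
  w <- elementary_weights(c(0.4, 0.2, 0.1, 0.1), 0.2)
  expect_equal(w$mechanism_score, 1 - 2 * w$c)
})

test_that("a pure-carbene curve scores about -1", {
  pre <- reactivity_preset("carbene-dominant")
  preset_c <- list(kin = pre$kin, ch = pre$ch,
                   weights = elementary_weights(c(0, 0, 0, 0) + 1e-12, 1))
  cur <- simulate_yield_curves(preset_c, yield_conditions(),
                               noise_model(sd = 0.01, seed = 21))
  w <- suppressWarnings(fit_weights(cur, pre$kin, pre$ch))
  expect_lt(w$mechanism_score, -0.9)
})

test_that("yield surface optima sit where the mechanism dictates", {
  tg <- seq(10, 300, 10); hg <- seq(5, 300, 5)
  pre <- reactivity_preset("diazo-dominant")
  ys <- yield_surface(pre$kin, pre$ch, tg, hg)
  expect_true(all(ys$surface >= 0 & ys$surface <= 1))
  # diazo-dominant: optimum power interior
  expect_gt(ys$optimum$power_mw_cm2, min(hg))
  expect_lt(ys$optimum$power_mw_cm2, max(hg))

  carb <- channel_params(kappa1 = 0, kappa2 = 0, kappa3 = 0, kappa4 = 0,
                         kappa_c = 0.6)
  ysc <- yield_surface(pre$kin, carb, tg, hg)
  expect_equal(ysc$optimum$power_mw_cm2, max(hg))
  expect_equal(ysc$optimum$time_s, max(tg))

  expect_error(yield_surface(pre$kin, pre$ch, numeric(), hg),
               class = "photoxl_validation")
})

test_that("zero power yields zero everywhere in that column", {
  pre <- reactivity_preset("diazo-dominant")
  prof <- elementary_profiles(pre$kin, pre$ch,
                              irradiation_condition(0, seq(10, 100, 10)))
  expect_true(all(as.matrix(prof[, 3:7]) == 0))
})

test_that("water quenching is monotone and suppresses the hydroxyl yield", {
  pre <- reactivity_preset("diazo-dominant")
  expect_equal(water_quench_yield(pre$weights, pre$ch, 0)$yield, 1)
  ws <- vapply(seq(0, 1, 0.1), function(w)
    water_quench_yield(pre$weights, pre$ch, w)$yield, 0)
  expect_false(is.unsorted(rev(ws)))
  # Ser-like preset at 99% water: the hydroxyl is out-competed by water
  expect_lt(water_quench_yield(pre$weights, pre$ch, 0.99)$yield, 0.01)
  # monotone across presets
  for (nm in c("carbene-dominant", "mixed")) {
    p <- reactivity_preset(nm)
    y <- vapply(c(0, 0.3, 0.6, 0.99), function(w)
      water_quench_yield(p$weights, p$ch, w)$yield, 0)
    expect_false(is.unsorted(rev(y)))
  }
})
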