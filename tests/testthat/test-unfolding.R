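test_that("three-state populations conserve probability and are verified against a brute-force Boltzmann sum", {
  # property: conservation for arbitrary finite parameters over 0-10 M
  withr::with_seed(7, {
    for (i in 1:25) {
      pars <- c(dG1 = runif(1, -20, 40), dG2 = runif(1, -20, 40),
                m1 = runif(1, 0.1, 10), m2 = runif(1, 0.1, 10))
      p <- three_state_populations(seq(0, 10, by = 0.5), pars["dG1"],
                                   pars["dG2"], pars["m1"], pars["m2"])
      expect_equal(p$fN + p$fI + p$fU, rep(1, nrow(p)), tolerance = 1e-12)
      expect_true(all(p$fN >= 0 & p$fI >= 0 & p$fU >= 0))
    }
  })

  # high-precision direct evaluation of the Boltzmann sums as oracle
  rt <- 8.314e-3 * 298.15
  k1 <- exp(-(11.6 - 3.5 * 4) / rt)
  k2 <- exp(-(5.1 - 1.8 * 4) / rt)
  z <- 1 + k1 + k1 * k2
  p <- three_state_populations(4, 11.6, 5.1, 3.5, 1.8)
  expect_equal(p$fN, 1 / z, tolerance = 1e-12)
  expect_equal(p$fI, k1 / z, tolerance = 1e-12)
  expect_equal(p$fU, k1 * k2 / z, tolerance = 1e-12)

  # folded limit and step-1 midpoint identity
  p0 <- three_state_populations(0, 50, 50, 3, 2)
  expect_equal(p0$fN, 1, tolerance = 1e-8)
  pm <- three_state_populations(10 / 3.5, 10, 50, 3.5, 1.8) # dG1 = m1*c
  expect_equal(pm$fN, 0.5, tolerance = 1e-8)
  expect_equal(pm$fI, 0.5, tolerance = 1e-8)
})

test_that("fN decreases and fU increases monotonically in urea for positive m-values", {
  grid <- seq(0, 10, by = 0.1)
  p <- three_state_populations(grid, 11.6, 5.1, 3.5, 1.8)
  expect_true(all(diff(p$fN) < 0))
  expect_true(all(diff(p$fU) > 0))
})

test_that("the three-state model collapses to the two-state closed form when step 2 is forbidden", {
  grid <- seq(0, 10, by = 0.25)
  three <- predict_unfolding_signal(
    list(dG1 = 16, dG2 = 500, m1 = 5.3803, m2 = 1e-9,
         yN = 1.2, yI = 0.8, yU = 0.8), grid)
  two <- predict_unfolding_signal(
    list(dG0 = 16, m = 5.3803, yN = 1.2, yU = 0.8), grid,
    model = "two_state")
  expect_equal(three, two, tolerance = 1e-9)

  # degenerate contrast: identical baselines give a flat signal
  flat <- predict_unfolding_signal(
    list(dG1 = 10, dG2 = 5, m1 = 3, m2 = 2, yN = 2, yI = 2, yU = 2), grid)
  expect_equal(flat, rep(2, length(grid)), tolerance = 1e-12)
})

test_that("three-state fits recover every published step-free-energy pair from noiseless curves", {
  for (row in names(table2_rows)) {
    tp <- three_state_truth(row)
    cv <- gen_unfolding_curve("three_state", tp,
                              cfg = generator_config(seed = 1))
    fit <- fit_three_state(cv)
    expect_equal(fit$params[["dG1"]], tp$dG1, tolerance = 1e-4)
    expect_equal(fit$params[["dG2"]], tp$dG2, tolerance = 1e-4)
    expect_equal(fit$dG_total, tp$dG1 + tp$dG2, tolerance = 1e-4)
    # additivity holds exactly by construction
    expect_identical(fit$dG_total,
                     fit$params[["dG1"]] + fit$params[["dG2"]])
    expect_false("nonphysical_m" %in% fit$flags)
  }
})

test_that("noisy three-state fits centre on the generating free energies", {
  # noise_sd 0.001 (signal units of the I337/I350 ratio, contrast 0.4)
  # puts the fitted-parameter spread on the order of the triplicate
  # uncertainties; medians over seeds must fall within those ranges
  tp <- three_state_truth("myb4_ctrl")
  res <- vapply(1:12, function(s) {
    cv <- gen_unfolding_curve("three_state", tp,
                              cfg = generator_config(seed = s,
                                                     noise_sd = 0.001))
    fit <- fit_three_state(cv)
    c(fit$params[["dG1"]], fit$params[["dG2"]])
  }, numeric(2))
  expect_lt(abs(stats::median(res[1, ]) - 11.6), 2.2)
  expect_lt(abs(stats::median(res[2, ]) - 5.1), 1.2)
})

test_that("a pure two-state curve is flagged as having a redundant intermediate", {
  cv <- gen_unfolding_curve("two_state",
                            list(dG0 = 16, m = 5.3803, yN = 1.2, yU = 0.8),
                            cfg = generator_config(seed = 1))
  fit <- fit_three_state(cv)
  expect_true("redundant_intermediate" %in% fit$flags)
  # and a genuinely three-state curve is not
  fit3 <- fit_three_state(gen_unfolding_curve(
    "three_state", three_state_truth("myb4_ctrl"),
    cfg = generator_config(seed = 1)))
  expect_false("redundant_intermediate" %in% fit3$flags)
})

test_that("apparent fraction unfolded tracks fU with a midpoint at Cm", {
  cv <- gen_unfolding_curve("two_state",
                            list(dG0 = 10, m = 2, yN = 1.2, yU = 0.8),
                            cfg = generator_config(seed = 1,
                                                   grid = seq(0, 10, 0.5)))
  fit <- fit_two_state(cv)
  # at 0 M the residual unfolded population is exp(-dG0/RT)/(1+exp(-dG0/RT))
  fu0 <- plogis(-10 / (8.314e-3 * 298.15))
  expect_equal(as.numeric(apparent_fraction_unfolded(fit, 0)), fu0,
               tolerance = 1e-6)
  expect_equal(as.numeric(apparent_fraction_unfolded(fit, 30)), 1,
               tolerance = 1e-6)
  expect_equal(as.numeric(apparent_fraction_unfolded(fit, 5)), 0.5,
               tolerance = 1e-6) # cm = 10/2 = 5 M
})

test_that("two-state midpoint equals dG0/m to machine precision and by bisection", {
  cv <- gen_unfolding_curve("two_state",
                            list(dG0 = 16.0, m = 5.3803,
                                 yN = 1.2, yU = 0.8),
                            cfg = generator_config(seed = 1))
  fit <- fit_two_state(cv)
  expect_equal(fit$cm, fit$params[["dG0"]] / fit$params[["m"]],
               tolerance = 1e-12)
  expect_equal(as.numeric(fit$c_half), 16.0 / 5.3803, tolerance = 1e-7)
  expect_equal(as.numeric(fit$c_half), 2.9739, tolerance = 1e-3)

  cv2 <- gen_unfolding_curve("two_state",
                             list(dG0 = 10, m = 2, yN = 1.2, yU = 0.8),
                             cfg = generator_config(seed = 1,
                                                    grid = seq(0, 10, 0.5)))
  fit2 <- fit_two_state(cv2)
  expect_equal(as.numeric(fit2$c_half), 5.0, tolerance = 1e-6)
})

test_that("three-state midpoint matches a dense-grid oracle on the generator's own fapp", {
  tp <- three_state_truth("myb4_ctrl")
  cv <- gen_unfolding_curve("three_state", tp,
                            cfg = generator_config(seed = 1))
  fit <- fit_three_state(cv)
  # oracle: dense-grid inversion of the generator's apparent fraction
  grid <- seq(0, 10, by = 1e-5)
  y <- predict_unfolding_signal(tp, grid)
  fapp <- (tp$yN - y) / (tp$yN - tp$yU)
  oracle <- grid[which.min(abs(fapp - 0.5))]
  expect_equal(as.numeric(fit$c_half), oracle, tolerance = 1e-4)
})

test_that("degenerate and insufficient inputs are rejected", {
  short <- unfolding_curve(seq(0, 2, 0.5), c(1.2, 1.1, 1.0, 0.9, 0.8))
  expect_error(fit_three_state(short), class = "uvf_insufficient_data")
  expect_error(unfolding_curve(c(0, 0.5, 0.5), c(1, 1, 1)),
               class = "uvf_invalid_input")
})
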