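test_that("variants map to their time-constant pairs", {
  expect_equal(make_regulation_config("full")[c("tau_g", "tau_half")],
               list(tau_g = 600, tau_half = 6))
  expect_equal(make_regulation_config("reversed")[c("tau_g", "tau_half")],
               list(tau_g = 6, tau_half = 600))
  expect_equal(make_regulation_config("half_only")$tau_g, Inf)
  expect_equal(make_regulation_config("gmax_only")$tau_half, Inf)
  # half-shifts disabled entirely on top of the reversed (fast-conductance)
  # controller
  hd <- make_regulation_config("half_disabled")
  expect_equal(hd$tau_half, Inf)
  expect_equal(hd$tau_g, 6)
  expect_false(hd$enable_half)
  expect_error(make_regulation_config("bogus"))
})

test_that("weight matrices have the committed shape and signs", {
  w <- default_weights()
  expect_equal(dim(w$w_g), c(7L, 3L))
  expect_equal(dim(w$w_half), c(11L, 3L))
  # inward currents suppressed by positive DC error, outward recruited
  expect_gt(w$w_g["Na", "D"], 0)
  expect_gt(w$w_g["CaS", "D"], 0)
  expect_lt(w$w_g["Kd", "D"], 0)
  expect_lt(w$w_g["KCa", "D"], 0)
  # activation curves shift right (positive) under positive error for
  # inward currents: negative entries in the update matrix
  expect_lt(w$w_half["Na_act", "D"], 0)
  expect_gt(w$w_half["Na_inact", "D"], 0)
  expect_gt(w$w_half["Kd_act", "D"], 0)
})

test_that("zero error and frozen pathways are exact identities", {
  cfg <- with_targets(make_regulation_config("full"), c(F = 1, S = 1, D = 1))
  g <- c(10, 2, 5, 30, 4, 60, 0.1)
  sh <- runif(11, -3, 3)
  e0 <- c(F = 0, S = 0, D = 0)
  expect_identical(conductance_update(g, e0, cfg, 0.05), g)
  frozen <- with_targets(make_regulation_config("gmax_only"),
                         c(F = 1, S = 1, D = 1))
  ebig <- c(F = 5, S = -5, D = 5)
  expect_identical(halfshift_update(sh, ebig, frozen, 0.05), sh)
  gfrozen <- with_targets(make_regulation_config("half_only"),
                          c(F = 1, S = 1, D = 1))
  expect_identical(conductance_update(g, ebig, gfrozen, 0.05), g)
})

test_that("conductances stay positive for arbitrary bounded errors", {
  cfg <- with_targets(make_regulation_config("full"), c(F = 1, S = 1, D = 1))
  set.seed(42)
  g <- rep(1, 7)
  for (i in 1:2000) {
    e <- setNames(runif(3, -50, 50), c("F", "S", "D"))
    g <- conductance_update(g, e, cfg, dt = 1)
    expect_true(all(g > 0))
  }
})

test_that("shift dynamics decay to the anchor and saturate at the soft bound", {
  cfg <- with_targets(make_regulation_config("full"), c(F = 1, S = 1, D = 1))
  cfg$error_deadzone <- 0
  # zero error: exponential decay toward the anchor at rate lambda
  sh <- rep(2, 11)
  t_total <- 0
  for (i in 1:1000) { sh <- halfshift_update(sh, c(F = 0, S = 0, D = 0), cfg, 10)
                      t_total <- t_total + 0.01 }
  expect_equal(unname(sh), rep(2 * exp(-cfg$lambda * t_total), 11),
               tolerance = 1e-4)
  # constant error: converges to -(W e) / (lambda * tau_half), finite
  e <- c(F = 0.5, S = -0.25, D = 1)
  sh <- rep(0, 11)
  for (i in 1:40000) sh <- halfshift_update(sh, e, cfg, 50)
  expected <- -as.numeric(cfg$w_half %*% (e / cfg$targets)) /
    (cfg$lambda * cfg$tau_half)
  # forward-Euler steady state carries an O(dt/tau_half) bias at this
  # deliberately coarse test step
  expect_equal(unname(sh), expected, tolerance = 5e-3)
})

test_that("non-zero anchor shifts the resting point", {
  cfg <- with_targets(make_regulation_config("full"), c(F = 1, S = 1, D = 1))
  cfg <- with_shift_anchor(cfg, c(rep(0, 1), -4, rep(0, 9)))
  sh <- rep(0, 11)
  for (i in 1:40000) sh <- halfshift_update(sh, c(F = 0, S = 0, D = 0), cfg, 50)
  expect_equal(sh[2], -4, tolerance = 5e-3)
  expect_equal(sh[1], 0)
})

test_that("dead zone ignores small deviations entirely", {
  cfg <- with_targets(make_regulation_config("full"),
                      c(F = 10, S = 10, D = 10))
  g <- rep(1, 7)
  e_small <- c(F = 2, S = -2, D = 2)  # 20% relative, inside the 25% band
  expect_identical(conductance_update(g, e_small, cfg, 1), g)
  e_big <- c(F = 5, S = 5, D = 5)
  expect_false(identical(conductance_update(g, e_big, cfg, 1), g))
})
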