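# Gas balances: expected values evaluated by direct arithmetic on the
# balance equations in the test body (independent of the package path).

test_that("gas balances match direct evaluation and vanish at zero exchange", {
  rec <- example_offgas()
  k <- 6 / (0.09 * 22.4)
  ratio <- (1 - 0.2095 - 0.0004) / (1 - 0.19 - 0.02)
  expect_equal(compute_our(rec), 1000 * k * (0.2095 - ratio * 0.19), tolerance = 1e-12)
  expect_equal(compute_cpr(rec), 1000 * k * (0.02 * ratio - 0.0004), tolerance = 1e-12)

  # outlet equal to inlet: no consumption, no production
  same <- rec
  same$xO2_out <- same$xO2_in
  same$xCO2_out <- same$xCO2_in
  expect_equal(compute_our(same), 0)
  expect_equal(compute_cpr(same), 0)

  # CO2-free simplification reduces to the textbook two-gas form
  simple <- tibble::tibble(
    F_in_Lh = 6, V_L = 0.09, xO2_in = 0.21, xCO2_in = 0,
    xO2_out = 0.20, xCO2_out = 0
  )
  expect_equal(
    compute_our(simple),
    1000 * (6 / (0.09 * 22.4)) * (0.21 - (0.79 / 0.80) * 0.20),
    tolerance = 1e-12
  )

  # percent-unit records give the same answer as fractions
  pc <- rec
  pc[c("xO2_in", "xCO2_in", "xO2_out", "xCO2_out")] <-
    pc[c("xO2_in", "xCO2_in", "xO2_out", "xCO2_out")] * 100
  expect_equal(compute_our(pc, unit = "percent"), compute_our(rec))
})

test_that("degenerate gas compositions are rejected", {
  bad <- example_offgas()
  bad$xO2_in <- 0.6
  bad$xCO2_in <- 0.4
  expect_error(compute_our(bad), class = "colibatch_invalid_composition")
  bad2 <- example_offgas()
  bad2$xO2_out <- 1.2
  expect_error(compute_cpr(bad2), class = "colibatch_invalid_composition")
  expect_error(
    compute_our(example_offgas()[, -3]),
    class = "colibatch_input_error"
  )
})

test_that("off-gas inversion is an exact inverse of the balances", {
  # directional sanity at stirred-tank settings
  out <- invert_offgas(OUR = 140, CPR = 143, F_in = 8.964, V = 0.09)
  expect_lt(out$xO2_out, 0.2095)
  expect_gt(out$xCO2_out, 0.0004)

  # property: round-trip over many random feasible records
  withr::with_seed(42, {
    n <- 1000
    F_in <- runif(n, 0.5, 12)
    V <- runif(n, 0.005, 0.12)
    k <- F_in / (V * 22.4) * 1000
    our <- runif(n, 0, 0.18) * k
    cpr <- our * runif(n, 0.8, 1.2)
    frac <- invert_offgas(our, cpr, F_in, V)
    rec <- tibble::tibble(
      F_in_Lh = F_in, V_L = V, xO2_in = 0.2095, xCO2_in = 0.0004,
      xO2_out = frac$xO2_out, xCO2_out = frac$xCO2_out
    )
    expect_lt(max(abs(compute_our(rec) - our) / pmax(our, 1e-6)), 1e-9)
    expect_lt(max(abs(compute_cpr(rec) - cpr) / pmax(cpr, 1e-6)), 1e-9)
  })

  # zero rates: outlet equals inlet
  z <- invert_offgas(0, 0, 6, 0.09, 0.21, 0.0003)
  expect_equal(z$xO2_out, 0.21)
  expect_equal(z$xCO2_out, 0.0003)

  # physically unreachable demand
  expect_error(
    invert_offgas(OUR = 5000, CPR = 10, F_in = 1, V = 0.09),
    class = "colibatch_infeasible_gas"
  )
})

test_that("cumulative oxygen uptake integrates correctly", {
  # constant 1 mmol/(L h) over one hour -> 0.032 g O2/L
  flat <- tibble::tibble(t_h = seq(0, 1, by = 0.1), OUR_mmolLh = 1)
  cum <- cumulative_our(flat)
  expect_equal(cum$cOUR_gL[1], 0)
  expect_equal(cum$cOUR_gL[nrow(cum)], 0.032, tolerance = 1e-12)
  # zero series stays zero; linearity in the integrand
  zero <- flat
  zero$OUR_mmolLh <- 0
  expect_true(all(cumulative_our(zero)$cOUR_gL == 0))
  double <- flat
  double$OUR_mmolLh <- 2
  expect_equal(cumulative_our(double)$cOUR_gL, 2 * cum$cOUR_gL)
  # monotone for non-negative rates
  withr::with_seed(7, {
    bump <- tibble::tibble(t_h = 0:20 / 2, OUR_mmolLh = runif(21, 0, 50))
    expect_true(all(diff(cumulative_our(bump)$cOUR_gL) >= 0))
  })
  expect_error(
    cumulative_our(tibble::tibble(t_h = c(0, 2, 1), OUR_mmolLh = 1)),
    class = "colibatch_input_error"
  )
})

test_that("cumulative OUR agrees with the model's own oxygen integral", {
  sim <- simulate_batch(wg20(), platform_preset("STR"))
  cum <- cumulative_our(tibble::tibble(t_h = sim$time_h, OUR_mmolLh = sim$OUR_mmolLh))
  direct <- pracma::trapz(sim$time_h, sim$qO * sim$X_gL)
  expect_equal(cum$cOUR_gL[nrow(cum)], direct, tolerance = 5e-3)
})

test_that("the biomass estimator is affine in cumulative oxygen uptake", {
  cour <- tibble::tibble(t_h = 0:10, cOUR_gL = seq(0, 2, length.out = 11))
  est <- estimate_biomass(cour, estimator_params(alpha = 1.4, X0 = 0.2))
  expect_equal(est$X_est_gL, cour$cOUR_gL / 1.4 + 0.2)
  zero <- cour
  zero$cOUR_gL <- 0
  expect_true(all(
    estimate_biomass(zero, estimator_params(1.4, X0 = 0.3))$X_est_gL == 0.3
  ))
  expect_error(estimator_params(alpha = -1), class = "colibatch_invalid_parameters")
})

test_that("the soft sensor tracks noiseless model biomass without maintenance", {
  p <- strain_parameters(
    q_S_max = 1.0, q_Ap_max = 0.08, q_Ac_max = 0.05, q_O_max = 5,
    q_m = 1e-9, Y_XS_em = 0.5, Y_OX = 1.4, K_S = 0.01
  )
  # generous transfer capacity: the tracking bound presumes oxygen excess
  cfg <- platform_config(platform = "custom", V = 0.09, X0 = 0.2, S0 = 10, t_end = 10, kLa = 3000)
  sim <- simulate_batch(p, cfg)
  cour <- cumulative_our(tibble::tibble(t_h = sim$time_h, OUR_mmolLh = sim$OUR_mmolLh))
  est <- estimate_biomass(cour, estimator_params(alpha = p$Y_OX, X0 = 0.2))
  pre <- sim$S_gL > 0.5 # before the acetate-only phase
  rel <- abs(est$X_est_gL[pre] - sim$X_gL[pre]) / sim$X_gL[pre]
  expect_lt(max(rel), 0.02)
})

test_that("alpha/beta calibration recovers known coefficients", {
  # a saturating biomass course: growth and maintenance regressors are
  # then linearly independent (a pure exponential would alias them)
  t <- seq(0, 12, by = 0.5)
  X <- 5 / (1 + 24 * exp(-0.5 * t))
  intX <- as.numeric(pracma::cumtrapz(t, X))
  # exact linear recovery at zero noise
  for (beta in c(0, 0.05)) {
    cour <- tibble::tibble(t_h = t, cOUR_gL = 1.4 * (X - X[1]) + beta * intX)
    fit <- fit_alpha_beta(cour, tibble::tibble(t_h = t, X_gL = X), X0 = X[1])
    expect_lt(abs(fit$params$alpha - 1.4) / 1.4, 0.01)
    expect_lt(abs(fit$beta_raw - beta), 0.01)
  }
  # with noise: beta stays positive and residuals look unstructured
  withr::with_seed(11, {
    courn <- tibble::tibble(t_h = t, cOUR_gL = 1.4 * (X - X[1]) + 0.08 * intX +
      rnorm(length(t), 0, 0.02))
    fitn <- fit_alpha_beta(courn, tibble::tibble(t_h = t, X_gL = X), X0 = X[1])
    expect_gt(fitn$beta_raw, 0)
    r <- stats::residuals(fitn$lm_fit)
    expect_lt(abs(cor(r[-1], r[-length(r)])), 0.6)
  })
  # degenerate design
  expect_error(
    fit_alpha_beta(
      tibble::tibble(t_h = t, cOUR_gL = seq_along(t)),
      tibble::tibble(t_h = t, X_gL = rep(1, length(t)))
    ),
    class = "colibatch_degenerate_fit"
  )
  # tidy/glance surface
  fit <- fit_alpha_beta(
    tibble::tibble(t_h = t, cOUR_gL = 1.4 * (X - X[1])),
    tibble::tibble(t_h = t, X_gL = X)
  )
  expect_named(tidy(fit), c("term", "estimate", "std.error"))
  expect_equal(nrow(glance(fit)), 1)
})

test_that("rmse behaves as a proper error metric", {
  a <- tibble::tibble(t = 0:10, v = sin(0:10))
  expect_equal(rmse(a, a), 0)
  b <- a
  b$v <- b$v + 0.37
  expect_equal(rmse(b, a), 0.37, tolerance = 1e-12)
  # interpolation to observation times
  dense <- tibble::tibble(t = seq(0, 10, by = 0.01), v = seq(0, 10, by = 0.01))
  coarse <- tibble::tibble(t = c(2.5, 7.25), v = c(2.5, 7.25) + 1)
  expect_equal(rmse(dense, coarse), 1, tolerance = 1e-9)
})
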