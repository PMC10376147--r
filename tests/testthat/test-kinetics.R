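# The expected values below are computed by evaluating the rate laws
# directly (independent arithmetic in the test body), not by calling
# the package's vectorized implementation.

test_that("specific rates match a direct hand evaluation of the rate laws", {
  p <- wg10() # q_S_max 1.13, K_S 0.009, q_Ap_max 0.10, q_m 0.056, ...
  r <- specific_rates(list(X = 1, S = 5, A = 0, DOT = 100), p)

  monod <- 5 / (5 + 0.009)
  q_S <- 1.13 * monod
  q_Ap <- 0.10 * monod
  q_m <- 0.056 * 5 / (5 + 1e-4)
  mu <- (q_S - q_m - q_Ap / 0.667) * 0.56
  q_O <- (1.49 * mu + 1.067 * q_m) * 100 / 101

  expect_equal(r$q_S, q_S, tolerance = 1e-12)
  expect_equal(r$q_Ap, q_Ap, tolerance = 1e-12)
  expect_equal(r$q_Ac, 0)
  expect_equal(r$mu, mu, tolerance = 1e-12)
  expect_equal(r$q_O, q_O, tolerance = 1e-12)
})

test_that("rates respect the trivial limiting cases", {
  p <- wg10()
  # no substrate at all: everything off
  r0 <- specific_rates(list(X = 2, S = 0, A = 0, DOT = 100), p)
  expect_equal(unlist(r0), c(q_S = 0, q_Ap = 0, q_Ac = 0, q_O = 0, mu = 0))
  # Monod half-saturation
  rh <- specific_rates(list(X = 1, S = p$K_S, A = 0, DOT = 100), p)
  expect_equal(rh$q_S, p$q_S_max / 2)
  # saturation: q_S approaches q_S_max from below
  rs <- specific_rates(list(X = 1, S = 50, A = 0, DOT = 100), p)
  expect_lt(rs$q_S, p$q_S_max)
  expect_gt(rs$q_S, 0.999 * p$q_S_max)
  # production and consumption co-occur only with both substrates present
  rc <- specific_rates(list(X = 1, S = 2, A = 0.5, DOT = 80), p)
  expect_gt(rc$q_Ap, 0)
  expect_gt(rc$q_Ac, 0)
  # invalid states raise
  expect_error(
    specific_rates(list(X = 1, S = Inf, A = 0, DOT = 50), p),
    class = "colibatch_invalid_state"
  )
})

test_that("respiratory cap re-routes growth shortfall into acetate", {
  p <- strain_parameters(
    q_S_max = 1.5, q_Ap_max = 0.05, q_Ac_max = 0.07, q_O_max = 0.4,
    q_m = 0.05, Y_XS_em = 0.55, Y_OX = 1.45, K_S = 0.01
  )
  r <- specific_rates(list(X = 1, S = 20, A = 0, DOT = 100), p)
  expect_equal(r$q_O, 0.4)
  q_m <- 0.05 * 20 / (20 + 1e-4)
  expect_equal(r$mu, (0.4 - 1.067 * q_m) / 1.45, tolerance = 1e-12)
  # overflow exceeds the saturation-driven production alone
  expect_gt(r$q_Ap, 0.05 * 20 / 20.01)
  # and q_O never exceeds the cap anywhere on a grid of states
  grid <- expand.grid(S = c(0.001, 0.1, 2, 20), A = c(0, 0.5), DOT = c(2, 30, 100))
  rr <- specific_rates(list(X = 1, S = grid$S, A = grid$A, DOT = grid$DOT), p)
  expect_true(all(rr$q_O <= 0.4 + 1e-12))
  expect_true(all(rr$mu >= 0))
})

test_that("state derivatives follow the mass balances", {
  p <- wg10()
  d <- state_derivatives(0, list(X = 1, S = 5, A = 0, DOT = 80), p, platform = 600)
  monod <- 5 / (5 + 0.009)
  q_S <- 1.13 * monod
  q_m <- 0.056 * 5 / (5 + 1e-4)
  mu <- (q_S - q_m - 0.10 * monod / 0.667) * 0.56
  q_O <- (1.49 * mu + 1.067 * q_m) * 80 / 81
  expect_equal(d$dX, mu, tolerance = 1e-12)
  expect_equal(d$dS, -q_S, tolerance = 1e-12)
  expect_equal(d$dA, 0.10 * monod, tolerance = 1e-12)
  expect_equal(d$dDOT, 600 * 20 - q_O * 100 / 7.2e-3, tolerance = 1e-12)
  # abiotic reactor: only the oxygen balance is active
  d0 <- state_derivatives(0, list(X = 0, S = 5, A = 0, DOT = 40), p, platform = 300)
  expect_equal(unlist(d0), c(dX = 0, dS = 0, dA = 0, dDOT = 300 * 60))
  dsat <- state_derivatives(0, list(X = 0, S = 0, A = 0, DOT = 100), p, platform = 300)
  expect_equal(dsat$dDOT, 0)
  expect_error(
    state_derivatives(0, list(X = 1, S = 1, A = 0, DOT = 50), p, platform = -5),
    class = "colibatch_config_error"
  )
})

test_that("batch simulation conserves the yield balance without maintenance", {
  cfg <- platform_config(
    platform = "custom", V = 0.01, X0 = 0.2, S0 = 8, t_end = 14,
    kLa = 800
  )
  sim <- simulate_batch(clean_params(Y = 0.5), cfg)
  consumed <- 8 - sim$S_gL[nrow(sim)]
  dX <- sim$X_gL[nrow(sim)] - 0.2
  expect_lt(abs(dX - 0.5 * consumed), 1e-6 * dX)
  # glucose monotone in plain batch, no pulses
  expect_true(all(diff(sim$S_gL) <= 1e-9))
  expect_equal(nrow(pulse_events(sim)), 0)
})

test_that("trajectories stay non-negative and respect the oxygen caps", {
  params_list <- list(
    wg10(), wg20(), reference_params("WGM", 5),
    strain_parameters(
      q_S_max = 1.4, q_Ap_max = 0.2, q_Ac_max = 0.1, q_O_max = 0.45,
      q_m = 0.06, Y_XS_em = 0.6, Y_OX = 1.3, K_S = 0.02
    )
  )
  cfgs <- list(mini_mbr(), platform_preset("STR"), platform_preset("MTP", S0 = 20))
  for (p in params_list) {
    for (cfg in cfgs) {
      sim <- simulate_batch(p, cfg)
      expect_true(all(sim$X_gL >= -1e-9))
      expect_true(all(sim$S_gL >= -1e-9))
      expect_true(all(sim$A_gL >= -1e-9))
      expect_true(all(sim$DOT_pct >= -1e-9))
      expect_true(all(sim$qO <= p$q_O_max + 1e-9))
      # quasi-steady transfer ceiling where the broth is oxygen-depleted
      otr_cap <- schedule_value(cfg$kLa, sim$time_h) * 7.2e-3 * 1000 / 32
      low <- sim$DOT_pct < 0.5
      if (any(low)) {
        expect_true(all(sim$OUR_mmolLh[low] <= otr_cap[low] * 1.05))
      }
    }
  }
})

test_that("depletion-triggered pulses fire per the configured policy", {
  sim10 <- simulate_batch(wg10(), platform_preset("MBR", S0 = 10))
  expect_equal(nrow(pulse_events(sim10)), 1)
  sim5 <- simulate_batch(reference_params("WG", 5), platform_preset("MBR", S0 = 5))
  ev5 <- pulse_events(sim5)
  expect_equal(nrow(ev5), 2)
  # each pulse restores glucose to its initial level
  i <- findInterval(ev5$time[1] + 1e-6, sim5$time_h)
  expect_lt(abs(max(sim5$S_gL[sim5$time_h > ev5$time[1]]) - 5), 0.2)
  # glucose is non-increasing between pulses
  phases <- cut(sim5$time_h, c(-Inf, ev5$time, Inf))
  for (ph in split(sim5$S_gL, phases)) {
    expect_true(all(diff(ph) <= 1e-9))
  }
  # no pulses configured: none fire
  sim0 <- simulate_batch(wg10(), platform_preset("MTP", S0 = 10))
  expect_equal(nrow(pulse_events(sim0)), 0)
})

test_that("acetate recycling takes over when glucose runs out", {
  p <- wg10()
  cfg <- platform_config(
    platform = "custom", V = 0.01, X0 = 2, S0 = 0, A0 = 1,
    t_end = 2, kLa = 600
  )
  sim <- simulate_batch(p, cfg)
  early <- sim[sim$time_h < 0.5, ]
  expect_true(all(diff(early$A_gL) < 0))
  expect_true(all(early$mu > 0))
  expect_true(all(diff(early$X_gL) > 0))
})

test_that("stirred-tank run reproduces the expected gas-exchange peak", {
  sim <- simulate_batch(wg20(), platform_preset("STR"))
  peak <- max(sim$OUR_mmolLh)
  expect_gt(peak, 140 * 0.75)
  expect_lt(peak, 140 * 1.25)
  # peak occurs at the end of the batch phase
  t_peak <- sim$time_h[which.max(sim$OUR_mmolLh)]
  expect_lt(abs(t_peak - batch_end_time(sim)), 0.25)
  # CPR follows the configured respiratory quotient
  expect_equal(sim$CPR_mmolLh, sim$OUR_mmolLh * 1.0)
})

test_that("lag phase suppresses all metabolic activity until it ends", {
  cfg <- mini_mbr()
  cfg$lag_h <- 1
  sim <- simulate_batch(wg10(), cfg)
  pre <- sim[sim$time_h < 1 - 1e-9, ]
  expect_true(all(pre$mu == 0))
  expect_equal(max(abs(pre$X_gL - cfg$X0)), 0, tolerance = 1e-10)
  expect_equal(max(abs(pre$S_gL - cfg$S0)), 0, tolerance = 1e-10)
})
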