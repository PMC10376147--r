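test_that("platform presets encode the experimental structure", {
  mtp <- platform_preset("MTP")
  expect_equal(mtp$channels, "DOT")
  expect_equal(mtp$V, 0.001)
  # transfer ceiling about 30 mmol O2/(L h)
  expect_equal(max(mtp$kLa$value) * 7.2e-3 * 1000 / 32, 30, tolerance = 0.01)

  mbr5 <- platform_preset("MBR", S0 = 5)
  expect_equal(mbr5$pulses$max_pulses, 2)
  expect_equal(mbr5$pulses$mode, "depletion")
  mbr10 <- platform_preset("MBR", S0 = 10)
  expect_equal(mbr10$pulses$max_pulses, 1)
  expect_setequal(mbr10$channels, c("X", "S", "A", "DOT"))

  str <- platform_preset("STR")
  expect_equal(str$V, 0.09)
  expect_equal(str$S0, 20)
  expect_equal(str$F_in$t, c(0, 2.75, 6.8))
  # aeration steps: 0.22/0.66/1.66 vvm on 90 mL
  expect_equal(str$F_in$value, c(0.22, 0.66, 1.66) * 0.09 * 60)
  expect_setequal(str$channels, c("X", "S", "A", "OUR", "CPR"))

  expect_error(platform_preset("chemostat"), class = "colibatch_config_error")
  expect_error(pulse_schedule(max_pulses = 3), class = "colibatch_config_error")
})

test_that("generation is reproducible and unbiased at zero noise", {
  cfg <- mini_mbr()
  zero_noise <- lapply(default_noise(), \(x) list(rel = 0, floor = 0))
  cfg$noise <- zero_noise
  d <- generate_dataset(wg10(), cfg, seed = 5)
  for (ch in c("X", "S", "A", "DOT")) {
    col <- c(X = "X_gL", S = "S_gL", A = "A_gL", DOT = "DOT_pct")[[ch]]
    truth_at <- approx(d$truth$time_h, d$truth[[col]], d$channels[[ch]]$t_h)$y
    expect_equal(d$channels[[ch]]$value, truth_at, tolerance = 1e-9)
  }
  # determinism: identical seed, identical dataset
  d2 <- generate_dataset(wg10(), mini_mbr(), seed = 99)
  d3 <- generate_dataset(wg10(), mini_mbr(), seed = 99)
  expect_identical(d2$channels, d3$channels)
  d4 <- generate_dataset(wg10(), mini_mbr(), seed = 100)
  expect_false(identical(d2$channels$X$value, d4$channels$X$value))
  # clipping: no negative observations anywhere
  expect_true(all(dataset_observations(d2)$value >= 0))
})

test_that("replicate noise matches the configured magnitude", {
  cfg <- mini_mbr()
  reps <- purrr::map(1:100, \(s) generate_dataset(wg10(), cfg, seed = 2000 + s))
  # biomass channel at a fixed mid-run sampling time
  i <- 10
  xs <- purrr::map_dbl(reps, \(d) d$channels$X$value[i])
  target_sd <- reps[[1]]$channels$X$sd[i]
  expect_lt(abs(sd(xs) - target_sd) / target_sd, 0.15)
  dots <- purrr::map_dbl(reps, \(d) d$channels$DOT$value[200])
  expect_lt(abs(sd(dots) - 2) / 2, 0.15)
})

test_that("fabricated stirred-tank off-gas round-trips the model rates", {
  cfg <- platform_preset("STR")
  cfg$noise <- lapply(default_noise(), \(x) list(rel = 0, floor = 0))
  d <- generate_dataset(wg20(), cfg, seed = 3)
  rates <- offgas_rates(d$offgas)
  our_m <- approx(d$truth$time_h, d$truth$OUR_mmolLh, d$offgas$t_h)$y
  cpr_m <- approx(d$truth$time_h, d$truth$CPR_mmolLh, d$offgas$t_h)$y
  expect_lt(max(abs(rates$OUR_mmolLh - our_m)), 1e-8)
  expect_lt(max(abs(rates$CPR_mmolLh - cpr_m)), 1e-8)
  # gas-analyzer noise propagates into the OUR channel
  dn <- generate_dataset(wg20(), platform_preset("STR"), seed = 3)
  expect_gt(sd(dn$channels$OUR$value - our_m), 0)
})

test_that("microtiter wells at high glucose hit the transfer ceiling", {
  d <- generate_dataset(
    reference_params("WGM", 10), platform_preset("MTP", S0 = 20),
    seed = 8
  )
  tr <- d$truth
  low <- tr$DOT_pct < 5
  # an extended oxygen-limitation plateau...
  expect_gt(sum(low) / nrow(tr), 0.15)
  # ...that ends with a DOT rise at glucose depletion
  t_dep <- batch_end_time(tr)
  expect_false(is.na(t_dep))
  after <- tr[tr$time_h > t_dep + 0.3, ]
  # DOT lifts off the plateau right after depletion and fully recovers
  # once the accumulated acetate is consumed as well
  expect_gt(min(after$DOT_pct), 30)
  expect_gt(max(after$DOT_pct), 80)
})

test_that("campaigns summarize one row per run with sensible ordering", {
  expect_equal(nrow(campaign_table(list())), 0)
  plan <- tidyr::expand_grid(
    strain = c("WG", "WGP", "WGM"), S0 = c(5, 10)
  )
  plan$platform <- "MBR"
  camp <- synthetic_campaign(plan, seed = 4)
  tab <- campaign_table(camp)
  expect_equal(nrow(tab), 6)
  expect_setequal(
    tab$strain,
    c("WG (5)", "WG (10)", "WGP (5)", "WGP (10)", "WGM (5)", "WGM (10)")
  )
  # longer batch phase at the higher initial glucose level
  wg <- tab[startsWith(tab$strain, "WG ("), ]
  expect_gt(
    wg$batch_end_h[wg$S0_gL == 10],
    wg$batch_end_h[wg$S0_gL == 5]
  )
  # pulse counts follow the refeeding policy
  expect_equal(tab$n_pulses[tab$S0_gL == 5], rep(2, 3))
  expect_equal(tab$n_pulses[tab$S0_gL == 10], rep(1, 3))
})
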