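# Estimation machinery on small, fast problems. The full platform-scale
# recovery study lives in test-acceptance.R.

make_clean_dataset <- function(params, seed = 1, noise = TRUE) {
  cfg <- platform_preset("MBR", S0 = 10, t_end = 10)
  # noiseless draws keep the nominal channel sds so the weighted
  # residuals stay well defined
  generate_dataset(params, cfg, seed = seed, noise_scale = if (noise) 1 else 0)
}

test_that("residuals vanish at the generating truth on noiseless data", {
  p <- wg10()
  d <- make_clean_dataset(p, noise = FALSE)
  theta <- unlist(p[parameter_names(free_only = TRUE)])
  r <- fit_residuals(theta, d)
  expect_lt(sqrt(mean(r^2)), 1e-3)
  # any perturbation strictly increases the residual norm
  for (nm in c("q_S_max", "Y_XS_em", "q_Ap_max")) {
    th2 <- theta
    th2[nm] <- th2[nm] * 1.1
    expect_gt(sum(fit_residuals(th2, d)^2), sum(r^2) + 1)
  }
})

test_that("residual vector length tracks the available observations", {
  d <- make_clean_dataset(wg10(), seed = 2)
  theta <- unlist(wg10()[parameter_names(free_only = TRUE)])
  n_full <- length(fit_residuals(theta, d))
  n_expected <- sum(purrr::map_int(d$channels, nrow)) -
    sum(d$channels$DOT$value <= 5)
  expect_equal(n_full, n_expected)
  # DOT-only microtiter data: residuals only where the optode reads > 5%
  dm <- generate_dataset(wg10(), platform_preset("MTP", S0 = 10), seed = 3)
  n_mtp <- length(fit_residuals(theta, dm))
  expect_equal(n_mtp, sum(dm$channels$DOT$value > 5))
  # channel subsetting
  expect_equal(
    length(fit_residuals(theta, d, channels = "A")),
    nrow(d$channels$A)
  )
  # residual length is invariant to theta (penalty contract)
  th_bad <- theta
  th_bad["q_S_max"] <- 1.99
  expect_equal(length(fit_residuals(th_bad, d)), n_full)
})

test_that("zero-noise data are recovered nearly exactly", {
  p <- wg10()
  d <- make_clean_dataset(p, noise = FALSE)
  fit <- fit_parameters(d,
    free = c("q_S_max", "Y_XS_em", "q_Ap_max", "q_Ac_max"),
    template = p, n_starts = 1, seed = 1
  )
  truth <- unlist(p[fit$free])
  est <- coef(fit)[fit$free]
  expect_lt(max(abs(est - truth) / truth), 0.005)
  # near-zero uncertainties on noiseless data
  td <- tidy(fit)
  expect_lt(max(td$std_error[td$role == "free"] / est), 0.01)
  expect_true(fit$converged)
})

test_that("fits are deterministic given the seed", {
  d <- make_clean_dataset(wg10(), seed = 4)
  f1 <- fit_parameters(d,
    free = c("q_S_max", "Y_XS_em"), n_starts = 2, seed = 7
  )
  f2 <- fit_parameters(d,
    free = c("q_S_max", "Y_XS_em"), n_starts = 2, seed = 7
  )
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$rss, f2$rss)
})

test_that("fit results carry the documented structure", {
  d <- make_clean_dataset(wg10(), seed = 5)
  fit <- fit_parameters(d, free = c("q_S_max", "Y_XS_em"), n_starts = 1, seed = 1)
  td <- tidy(fit)
  expect_setequal(td$parameter, parameter_names())
  expect_setequal(unique(td$role), c("free", "fixed", "derived"))
  expect_true(all(td$std_error[td$role == "free"] >= 0))
  expect_true(all(is.na(td$std_error[td$role == "fixed"])))
  # derived growth rate obeys the identity
  est <- coef(fit)
  expect_equal(
    unname(est["mu_max"]),
    unname((est["q_S_max"] - est["q_m"]) * est["Y_XS_em"])
  )
  g <- glance(fit)
  expect_equal(g$nobs, fit$n_obs)
  expect_s3_class(fit$channel_rmse, "tbl_df")
  expect_error(
    fit_parameters(d, free = "q_X_max"),
    class = "colibatch_config_error"
  )
})

test_that("profiles separate well- and poorly-identified parameters", {
  p <- wg10()
  d <- make_clean_dataset(p, noise = FALSE)
  fit <- fit_parameters(d,
    free = c("q_S_max", "K_S"), template = p, n_starts = 1, seed = 1
  )
  # the uptake capacity is sharply identified...
  prof_qs <- profile_identifiability(d, fit, "q_S_max",
    grid = fit$estimates$estimate[fit$estimates$parameter == "q_S_max"] *
      c(0.9, 1, 1.1), maxiter = 25
  )
  expect_gt(min(prof_qs$objective[c(1, 3)]), prof_qs$objective[2] + 10)
  # the objective at the optimum is the profile minimum on noiseless data
  expect_equal(min(prof_qs$objective), prof_qs$objective[2], tolerance = 0.05)
})
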