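# Multi-experiment parameter estimation: weighted nonlinear least
# squares on the simulated trajectories, Levenberg-Marquardt with
# Latin-hypercube multi-starts in log-parameter space, linearized
# covariance for the reported uncertainties.

#' Default box bounds for the structural parameters
#'
#' @return Tibble with columns `parameter`, `lower`, `upper` (natural
#'   units).
#' @export
default_parameter_bounds <- function() {
  tribble(
    ~parameter, ~lower, ~upper,
    "q_S_max", 0.3, 2.0,
    "K_S", 1e-4, 0.5,
    "q_Ap_max", 0.005, 0.5,
    "q_Ac_max", 0.005, 0.3,
    "q_O_max", 0.1, 2.0,
    "q_m", 0.005, 0.2,
    "Y_XS_em", 0.1, 0.7,
    "Y_OX", 0.5, 3.0
  )
}

# neutral mid-range parameter set supplying values for non-free parameters
default_template <- function() {
  strain_parameters(
    q_S_max = 1.0, q_Ap_max = 0.08, q_Ac_max = 0.07, q_O_max = 0.7,
    q_m = 0.045, Y_XS_em = 0.5, Y_OX = 1.4, K_S = 0.01
  )
}

# default free set by platform: DOT-only wells support far fewer
# parameters than fully observed reactors
default_free_set <- function(datasets) {
  platforms <- unique(map_chr(datasets, "platform"))
  if (identical(platforms, "MTP")) {
    c("q_S_max", "K_S", "q_O_max")
  } else {
    parameter_names(free_only = TRUE)
  }
}

as_dataset_list <- function(datasets) {
  if (inherits(datasets, "cultivation_dataset")) {
    list(datasets)
  } else if (inherits(datasets, "cultivation_campaign")) {
    datasets$datasets
  } else {
    stopifnot(all(map_lgl(datasets, inherits, "cultivation_dataset")))
    datasets
  }
}

# rebuild a simulation config that replays the logged pulses of a
# dataset at their recorded times (pulse times are known inputs when
# fitting, not re-triggered)
replay_config <- function(dataset) {
  cfg <- dataset$config
  pt <- dataset$events$time[dataset$events$type == "pulse"]
  cfg$pulses <- if (length(pt)) {
    pulse_schedule(
      mode = "timed", target = cfg$pulses$target %||% cfg$S0, times = pt
    )
  } else {
    pulse_schedule("none")
  }
  cfg
}

build_params <- function(theta, template) {
  vals <- template[parameter_names(free_only = TRUE)]
  vals[names(theta)] <- as.list(unname(theta))
  strain_parameters(
    q_S_max = vals$q_S_max, q_Ap_max = vals$q_Ap_max,
    q_Ac_max = vals$q_Ac_max, q_O_max = vals$q_O_max, q_m = vals$q_m,
    Y_XS_em = vals$Y_XS_em, Y_OX = vals$Y_OX, K_S = vals$K_S
  )
}

# data-driven initial guess: coarse physiology read off the observation
# channels (yield from total biomass over glucose fed, growth rate from
# the early log-slope of biomass, specific rates from channel peaks),
# falling back to the template where a channel is missing. Clamped to
# the interior of the bounds.
heuristic_start <- function(datasets, free, bounds, template, aux) {
  guess <- unlist(template[parameter_names(free_only = TRUE)])
  per_ds <- map(datasets, function(d) {
    g <- rep(NA_real_, 8)
    names(g) <- names(guess)
    xch <- d$channels$X
    total_S <- d$config$S0 + sum(d$events$value[d$events$type == "pulse"])
    mu0 <- NA_real_
    x_at <- function(tt) {
      if (is.null(xch)) NA_real_ else approx(xch$t_h, xch$value, tt, rule = 2)$y
    }
    if (!is.null(xch) && nrow(xch) >= 4) {
      x0 <- max(xch$value[1], 1e-3)
      g["Y_XS_em"] <- (max(xch$value) - x0) / total_S
      # growth-rate window: before the first pulse and while glucose is
      # clearly present (excludes the stationary phase)
      t1 <- min(c(d$events$time[d$events$type == "pulse"], d$config$t_end))
      keep <- xch$t_h > d$config$lag_h & xch$t_h <= t1 & xch$value > 0
      sch <- d$channels$S
      if (!is.null(sch)) {
        s_at <- approx(sch$t_h, sch$value, xout = xch$t_h, rule = 2)$y
        keep <- keep & s_at > max(1, 0.05 * d$config$S0)
      }
      early <- xch[keep, ]
      if (nrow(early) >= 3) {
        mu0 <- unname(coef(lm(log(early$value) ~ early$t_h))[2])
        if (is.finite(mu0) && mu0 > 0 && is.finite(g["Y_XS_em"])) {
          g["q_S_max"] <- mu0 / g["Y_XS_em"] + template$q_m
        }
      }
    }
    ach <- d$channels$A
    if (!is.null(ach) && any(ach$value > 0.05) && is.finite(mu0)) {
      ipk <- which.max(ach$value)
      xpk <- x_at(ach$t_h[ipk])
      if (is.finite(xpk) && xpk > 0) {
        g["q_Ap_max"] <- mu0 * max(ach$value) / xpk
      }
      post <- ach[ach$t_h > ach$t_h[ipk], ]
      if (nrow(post) >= 3) {
        sl <- unname(coef(lm(post$value ~ post$t_h))[2])
        xm <- x_at(median(post$t_h))
        if (is.finite(sl) && sl < 0 && is.finite(xm) && xm > 0) {
          g["q_Ac_max"] <- -sl / xm
        }
      }
    }
    # specific oxygen uptake from off-gas, or from the DOT balance
    our_est <- NULL
    full_gas <- !is.null(d$channels$OUR)
    if (full_gas) {
      our_est <- d$channels$OUR
    } else if (!is.null(d$channels$DOT)) {
      dd <- d$channels$DOT
      kla <- schedule_value(d$config$kLa, dd$t_h)
      our_est <- tibble(
        t_h = dd$t_h,
        value = kla * aux$C_O2_star * (100 - pmin(dd$value, 100)) / 100 / 32 * 1000
      )[dd$value > 10, ]
    }
    if (!is.null(our_est) && nrow(our_est) >= 3 && !is.null(xch)) {
      ipk <- which.max(our_est$value)
      xpk <- x_at(our_est$t_h[ipk])
      if (is.finite(xpk) && xpk > 0.1) {
        q_o <- our_est$value[ipk] * 32 / 1000 / xpk
        g["q_O_max"] <- q_o
        if (!full_gas && is.finite(mu0) && mu0 > 0) {
          g["Y_OX"] <- (q_o - aux$c_Om * template$q_m) / mu0
        }
      }
      # with a complete gas record: oxygen yield from the cumulative
      # uptake over the biomass formed (the soft-sensor identity)
      dx <- max(xch$value) - xch$value[1]
      if (full_gas && dx > 0.2) {
        cum <- pracma::trapz(our_est$t_h, our_est$value) * 32 / 1000
        g["Y_OX"] <- cum / dx
      }
    }
    g
  })
  est <- map_dbl(names(guess), function(nm) {
    v <- map_dbl(per_ds, nm)
    if (all(!is.finite(v))) NA_real_ else median(v[is.finite(v)])
  })
  names(est) <- names(guess)
  guess[is.finite(est)] <- est[is.finite(est)]
  b <- bounds[match(free, bounds$parameter), ]
  pmin(pmax(guess[free], b$lower * 1.05), b$upper * 0.95)
}

#' Weighted residual vector of a candidate parameter set
#'
#' Simulates every dataset with the candidate parameters (replaying the
#' logged pulse times) and returns the standardized residuals
#' `(model - observation)/sd`, concatenated across channels and
#' datasets. DOT observations at or below the sensor floor (5% air
#' saturation) are excluded. A failed simulation contributes large
#' finite penalty residuals instead of raising, so the optimizer can
#' back away from pathological parameter regions.
#'
#' @param theta named numeric vector of candidate values for the free
#'   parameters (natural units).
#' @param datasets a `cultivation_dataset`, a list of them, or a
#'   `cultivation_campaign`.
#' @param template a [strain_parameters()] supplying non-free values.
#' @param aux an [aux_constants()] object.
#' @param control a [sim_control()] for the model solves.
#' @param dot_floor DOT sensor floor, % air saturation.
#' @param penalty residual value used when a simulation fails.
#' @param channels optional channel subset to restrict the residuals to.
#' @return Numeric residual vector (fixed length for given datasets).
#' @export
fit_residuals <- function(theta, datasets, template = default_template(),
                          aux = aux_constants(), control = sim_control(),
                          dot_floor = 5, penalty = 1e3, channels = NULL) {
  datasets <- as_dataset_list(datasets)
  if (!is.null(channels)) {
    datasets <- map(datasets, function(d) {
      d$channels <- d$channels[intersect(names(d$channels), channels)]
      d
    })
    datasets <- keep(datasets, \(d) length(d$channels) > 0)
  }
  params <- tryCatch(build_params(theta, template), error = function(e) NULL)
  cols <- c(
    X = "X_gL", S = "S_gL", A = "A_gL", DOT = "DOT_pct",
    OUR = "OUR_mmolLh", CPR = "CPR_mmolLh"
  )
  unlist(map(datasets, function(d) {
    keep <- function(ch, obs) {
      if (ch == "DOT") obs$value > dot_floor else rep(TRUE, nrow(obs))
    }
    n_d <- sum(map_dbl(names(d$channels), \(ch) sum(keep(ch, d$channels[[ch]]))))
    sim <- if (is.null(params)) {
      NULL
    } else {
      tryCatch(
        simulate_batch(params, replay_config(d), aux = aux, control = control),
        error = function(e) NULL
      )
    }
    if (is.null(sim)) {
      return(rep(penalty, n_d))
    }
    unlist(map(names(d$channels), function(ch) {
      obs <- d$channels[[ch]][keep(ch, d$channels[[ch]]), ]
      m <- approx(sim$time_h, sim[[cols[[ch]]]], xout = obs$t_h, rule = 2)$y
      r <- (m - obs$value) / obs$sd
      r[!is.finite(r)] <- penalty
      r
    }), use.names = FALSE)
  }), use.names = FALSE)
}

#' Fit strain parameters to one or several cultivation datasets
#'
#' Weighted nonlinear least squares built around bounded
#' Levenberg-Marquardt (a trust-region scheme), started from a
#' data-driven coarse estimate (yields and specific rates read off the
#' observation channels). Because the objective is sharply multimodal --
#' observations taken through the glucose depletion transitions make
#' the misfit hypersensitive to any parameter combination that shifts
#' the depletion times -- the solver runs several complementary search
#' paths and keeps the best result by residual norm (ties broken by the
#' smaller parameter-vector norm):
#'
#' 1. *staged*: block-coordinate solves of each parameter block against
#'    the channels that carry its information (uptake/yield/maintenance
#'    on biomass and glucose, acetate capacities on acetate, oxygen
#'    parameters on DOT and off-gas), then a joint polish;
#' 2. *graduated*: joint solves under progressively tighter channel
#'    weights, smoothing the depletion-timing ridges before the true
#'    weights are restored;
#' 3. *grid*: a coarse grid over the weakly identified carbon sinks
#'    (overflow capacity x maintenance) completed by fast conditional
#'    fits, with the best cells released in stages;
#' 4. any further starts: plain joint solves from Latin-hypercube
#'    points drawn log-uniformly within the box bounds.
#'
#' `n_starts` controls how many of these paths run, in the order
#' listed; parameters are optimized on the log scale for conditioning,
#' and the winner receives a final round of coordinate/joint polish
#' cycles. Uncertainties are
#' the square roots of the diagonal of the linearized covariance
#' `sigma^2 (J'J)^-1`, with `J` the residual Jacobian at the optimum in
#' natural units. The derived maximum growth rate
#' `mu_max = (q_S_max - q_m) Y_XS_em` is reported with a delta-method
#' uncertainty. The result is deterministic given `seed`.
#'
#' @inheritParams fit_residuals
#' @param free character vector of parameters to estimate (subset of
#'   `parameter_names(free_only = TRUE)`); defaults to all eight for
#'   reactor data and to `q_S_max`, `K_S`, `q_O_max` for DOT-only
#'   microtiter data.
#' @param bounds a tibble like [default_parameter_bounds()].
#' @param n_starts number of search paths / starts to run (>= 1).
#' @param seed integer seed for the start design.
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `strain_fit` with the point estimates,
#'   standard uncertainties, fixed-parameter list, residual sum of
#'   squares, per-channel RMSEs, convergence diagnostics, seed and start
#'   points. Supports [tidy()], [glance()], [coef()] and [autoplot()].
#' @examples
#' \donttest{
#' d <- generate_dataset(reference_params("WG", 10), platform_preset("MBR"), seed = 7)
#' fit <- fit_parameters(d, n_starts = 2, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_parameters <- function(datasets, free = NULL,
                           template = default_template(),
                           bounds = default_parameter_bounds(),
                           n_starts = 8, seed = 1,
                           aux = aux_constants(),
                           control = sim_control(rtol = 1e-7, atol = 1e-9),
                           maxiter = 150, dot_floor = 5) {
  datasets <- as_dataset_list(datasets)
  stopifnot(n_starts >= 1)
  free <- free %||% default_free_set(datasets)
  bad <- setdiff(free, parameter_names(free_only = TRUE))
  if (length(bad)) {
    abort(paste("unknown free parameters:", paste(bad, collapse = ", ")),
      class = "colibatch_config_error"
    )
  }
  b <- bounds[match(free, bounds$parameter), ]
  if (anyNA(b$lower)) {
    abort("bounds must cover every free parameter", class = "colibatch_config_error")
  }
  # optimize on a shifted log scale: keeps coordinates O(1) and away
  # from zero so minpack's relative finite-difference steps stay sane
  shift <- 5

  resid_ch <- function(th, chans = NULL, dsets = datasets) {
    fit_residuals(th, dsets,
      template = template, aux = aux, control = control,
      dot_floor = dot_floor, channels = chans
    )
  }
  rss_of <- function(th) sum(resid_ch(th)^2)

  # relaxed copies of the datasets: per-channel noise floors inflated to
  # a fraction of the channel scale, smoothing the steep depletion-
  # timing residuals (graduated optimization)
  relaxed <- function(frac) {
    map(datasets, function(d) {
      d$channels <- map(d$channels, function(ch) {
        ch$sd <- pmax(ch$sd, frac * max(abs(ch$value), 1e-6))
        ch
      })
      d
    })
  }

  failures <- character()
  # one bounded Levenberg-Marquardt solve over the subset `fr`, holding
  # the rest of `theta` fixed. `ef` (epsfcn) sets the relative finite-
  # difference step of the internal jacobian: coarse steps average over
  # event-timing jitter far from the optimum, fine steps resolve the
  # local curvature near it.
  run_lm <- function(theta, fr, chans = NULL, ef = 1e-3, maxit = 60,
                     dsets = datasets) {
    bb <- b[match(fr, free), ]
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = log(theta[fr]) + shift,
        lower = log(bb$lower) + shift, upper = log(bb$upper) + shift,
        fn = function(lt) {
          th <- theta
          th[fr] <- exp(lt - shift)
          resid_ch(th, chans, dsets)
        },
        control = minpack.lm::nls.lm.control(
          maxiter = maxit, ftol = 1e-8, ptol = 1e-8, epsfcn = ef
        )
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <<- c(failures, conditionMessage(res))
      return(list(theta = theta, info = -1L, message = conditionMessage(res)))
    }
    theta[fr] <- exp(res$par - shift)
    list(theta = theta, info = res$info, message = res$message)
  }

  # block-coordinate stages: each parameter block against the channels
  # that carry its information
  stage_defs <- list(
    list(par = c("q_S_max", "Y_XS_em", "q_m"), ch = c("X", "S")),
    list(par = c("q_Ap_max", "q_Ac_max"), ch = "A"),
    list(par = c("q_O_max", "Y_OX"), ch = c("DOT", "OUR", "CPR"))
  )
  have_ch <- unique(unlist(map(datasets, \(d) names(d$channels))))
  run_stages <- function(theta, ef) {
    for (sd in stage_defs) {
      fr <- intersect(sd$par, free)
      if (length(fr) == 0 || !any(sd$ch %in% have_ch)) next
      theta <- run_lm(theta, fr, sd$ch, ef = ef, maxit = 60)$theta
    }
    theta
  }

  # multiplicative scan for a rugged 1-D direction, scored on `chans`
  scan_param <- function(theta, par, scales, chans = NULL) {
    bb <- b[match(par, free), ]
    cand <- map(scales, function(m) {
      t2 <- theta
      t2[par] <- min(max(theta[[par]] * m, bb$lower * 1.02), bb$upper * 0.98)
      list(th = t2, rss = sum(resid_ch(t2, chans)^2))
    })
    cand[[which.min(map_dbl(cand, "rss"))]]$th
  }
  # uncapped specific-oxygen demand peak: anchor candidates for the
  # respiratory cap, whose gradient vanishes wherever it is inactive
  demand_peak <- function(theta) {
    t2 <- theta
    t2["q_O_max"] <- b$upper[match("q_O_max", free)] * 0.95
    sim <- tryCatch(
      simulate_batch(build_params(t2, template), replay_config(datasets[[1]]),
        aux = aux, control = control
      ),
      error = function(e) NULL
    )
    if (is.null(sim)) NA_real_ else max(sim$qO)
  }

  # candidate path 1: block-coordinate staging, then one joint polish
  path_staged <- function(theta) {
    for (ef in c(1e-3, 1e-3, 1e-6)) theta <- run_stages(theta, ef)
    run_lm(theta, free, ef = 1e-6, maxit = maxiter)
  }
  # candidate path 2: joint solves under progressively tighter weights
  # (graduated optimization; the glucose affinity joins only at the end)
  path_homotopy <- function(theta) {
    sub <- setdiff(free, "K_S")
    if (length(sub) == 0) sub <- free
    for (ph in list(
      list(f = 0.05, ef = 1e-3), list(f = 0.02, ef = 1e-3),
      list(f = 0.005, ef = 1e-6)
    )) {
      theta <- run_lm(theta, sub,
        ef = ph$ef, maxit = 60,
        dsets = relaxed(ph$f)
      )$theta
    }
    theta <- run_lm(theta, sub, ef = 1e-6, maxit = 60)$theta
    run_lm(theta, free, ef = 1e-6, maxit = maxiter)
  }
  # candidate path 3: coarse grid over the weakly identified carbon
  # sinks (overflow capacity x maintenance), each cell completed by
  # fast conditional fits of the well-identified parameters; the best
  # cells are then released in stages. This crosses the ridges that
  # separate timing-aligned local basins, which defeat purely local
  # steps.
  path_grid <- function(theta) {
    gpars <- intersect(c("q_Ap_max", "q_m"), free)
    if (length(gpars) < 2) {
      return(path_staged(theta))
    }
    grid <- expand.grid(
      q_Ap_max = c(0.02, 0.035, 0.06, 0.09, 0.13),
      q_m = c(0.02, 0.045, 0.08)
    )
    cells <- map(seq_len(nrow(grid)), function(i) {
      th <- theta
      th["q_Ap_max"] <- grid$q_Ap_max[i]
      th["q_m"] <- grid$q_m[i]
      gro <- intersect(c("q_S_max", "Y_XS_em"), free)
      if (length(gro) && any(c("X", "S") %in% have_ch)) {
        th <- run_lm(th, gro, c("X", "S"), ef = 1e-3, maxit = 40)$theta
      }
      if ("q_Ac_max" %in% free && "A" %in% have_ch) {
        th <- scan_param(th, "q_Ac_max", c(0.25, 0.5, 1, 2, 4), "A")
        th <- run_lm(th, "q_Ac_max", "A", ef = 1e-6, maxit = 25)$theta
      }
      oxy <- intersect(c("q_O_max", "Y_OX"), free)
      if (length(oxy) && any(c("DOT", "OUR", "CPR") %in% have_ch)) {
        if ("q_O_max" %in% free) {
          D <- demand_peak(th)
          if (is.finite(D)) {
            cand <- map(c(0.85, 0.92, 1, 1.1), function(m) {
              t2 <- th
              t2["q_O_max"] <- min(max(D * m, 0.11), 1.9)
              if ("Y_OX" %in% free) {
                t2 <- run_lm(t2, "Y_OX", c("DOT", "OUR", "CPR"),
                  ef = 1e-6, maxit = 20
                )$theta
              }
              list(th = t2, rss = sum(resid_ch(t2)^2))
            })
            cand <- c(cand, list(list(th = th, rss = sum(resid_ch(th)^2))))
            th <- cand[[which.min(map_dbl(cand, "rss"))]]$th
          }
        } else {
          th <- run_lm(th, oxy, c("DOT", "OUR", "CPR"), ef = 1e-6, maxit = 25)$theta
        }
      }
      list(th = th, rss = sum(resid_ch(th)^2))
    })
    ord <- order(map_dbl(cells, "rss"))
    best_cell <- NULL
    consider <- function(cand) {
      rss <- sum(resid_ch(cand$theta)^2)
      if (is.null(best_cell) || rss < best_cell$rss) {
        best_cell <<- c(cand, list(rss = rss))
      }
    }
    for (i in ord[seq_len(min(3, length(ord)))]) {
      th <- cells[[i]]$th
      # conditional solve with the gridded carbon sinks held fixed is a
      # candidate in its own right: full release can drift into a
      # nearly degenerate rival valley
      fix_fit <- run_lm(th, setdiff(free, gpars), ef = 1e-6, maxit = 80)
      consider(fix_fit)
      th <- run_lm(fix_fit$theta, gpars, ef = 1e-6, maxit = 40)$theta
      consider(run_lm(th, free, ef = 1e-6, maxit = 60))
    }
    best_cell %||% list(theta = theta, info = -1L, message = "grid path failed")
  }
  # plain joint solve used for the Latin-hypercube exploration starts
  path_joint <- function(theta) {
    theta <- run_lm(theta, free, ef = 1e-3, maxit = 60)$theta
    run_lm(theta, free, ef = 1e-6, maxit = 60)
  }

  withr::local_seed(as.integer(seed))
  design <- lhs::randomLHS(n_starts, length(free))
  starts <- exp(sweep(sweep(design, 2, log(b$upper) - log(b$lower), `*`),
    2, log(b$lower), `+`
  ))
  colnames(starts) <- free
  # the first two starts both depart from the data-driven coarse
  # estimate, one per deterministic path; any further starts explore
  # the box by Latin hypercube with joint solves
  h0 <- heuristic_start(datasets, free, bounds, template, aux)
  for (i in seq_len(min(3, n_starts))) starts[i, ] <- h0

  best <- NULL
  for (i in seq_len(n_starts)) {
    pathfun <- if (i == 1) {
      path_staged
    } else if (i == 2) {
      path_homotopy
    } else if (i == 3) {
      path_grid
    } else {
      path_joint
    }
    cand <- pathfun(setNames(starts[i, ], free))
    if (cand$info < 0) next
    cand$rss <- rss_of(cand$theta)
    if (!is.finite(cand$rss)) next
    tnorm <- sum(log(cand$theta)^2)
    if (is.null(best) || cand$rss < best$rss - 1e-12 ||
      (abs(cand$rss - best$rss) <= 1e-12 && tnorm < best$tnorm)) {
      best <- c(cand, list(tnorm = tnorm, start = i))
    }
  }
  if (!is.null(best)) {
    # final coordinate/joint polish cycles from the winning candidate
    rss_prev <- best$rss
    for (cycle in 1:2) {
      theta <- run_stages(best$theta, ef = 1e-6)
      fin <- run_lm(theta, free, ef = 1e-6, maxit = maxiter)
      rss <- rss_of(fin$theta)
      if (is.finite(rss) && rss < rss_prev) {
        best$theta <- fin$theta
        best$info <- fin$info
        best$message <- fin$message
        best$rss <- rss
      }
      if (rss_prev - rss < 1e-3 * rss_prev) break
      rss_prev <- best$rss
    }
    # convergence probe: a short restarted solve from the winner should
    # terminate on its own tolerances (an iteration-capped preceding
    # phase does not mean the solution is unconverged)
    probe <- run_lm(best$theta, free, ef = 1e-6, maxit = 40)
    if (probe$info >= 0) {
      prss <- rss_of(probe$theta)
      if (is.finite(prss) && prss <= best$rss) {
        best$theta <- probe$theta
        best$rss <- prss
      }
      best$info <- probe$info
      best$message <- probe$message
    }
  }
  if (is.null(best)) {
    abort(
      paste0(
        "no optimizer start succeeded:\n",
        paste(unique(failures), collapse = "\n")
      ),
      class = "colibatch_no_fit"
    )
  }

  theta <- best$theta
  r0 <- fit_residuals(theta, datasets,
    template = template, aux = aux,
    control = control, dot_floor = dot_floor
  )
  n_obs <- length(r0)
  p <- length(free)
  # central differences, step large enough to dominate solver noise
  J <- matrix(0, n_obs, p)
  for (j in seq_len(p)) {
    h <- 1e-3 * abs(theta[j])
    thp <- theta
    thm <- theta
    thp[j] <- thp[j] + h
    thm[j] <- thm[j] - h
    J[, j] <- (fit_residuals(thp, datasets,
      template = template, aux = aux,
      control = control, dot_floor = dot_floor
    ) - fit_residuals(thm, datasets,
      template = template, aux = aux,
      control = control, dot_floor = dot_floor
    )) / (2 * h)
  }
  rss <- sum(r0^2)
  sigma2 <- rss / max(n_obs - p, 1)
  # parameters whose residual sensitivity vanishes (e.g. a respiratory
  # cap that never binds at the optimum) are reported with unbounded
  # uncertainty rather than a spurious zero
  colnorm <- sqrt(colSums(J^2))
  alive <- colnorm > 1e-8 * max(colnorm, 1e-300)
  covar <- matrix(NA_real_, p, p, dimnames = list(free, free))
  if (any(alive)) {
    jtj <- crossprod(J[, alive, drop = FALSE])
    cv <- tryCatch(solve(jtj), error = function(e) {
      s <- svd(jtj)
      pos <- s$d > max(s$d) * 1e-12
      s$v[, pos, drop = FALSE] %*%
        diag(1 / s$d[pos], sum(pos)) %*% t(s$u[, pos, drop = FALSE])
    })
    covar[alive, alive] <- sigma2 * cv
  }
  sds <- rep(Inf, p)
  sds[alive] <- sqrt(pmax(diag(covar)[alive], 0))
  names(sds) <- free

  params_hat <- build_params(theta, template)
  # derived mu_max and its delta-method uncertainty
  mu_hat <- params_hat$mu_max
  dmu <- c(
    q_S_max = params_hat$Y_XS_em, q_m = -params_hat$Y_XS_em,
    Y_XS_em = params_hat$q_S_max - params_hat$q_m
  )
  in_free <- intersect(names(dmu), free)
  mu_sd <- if (length(in_free)) {
    g <- dmu[in_free]
    idx <- match(in_free, free)
    sub <- covar[idx, idx, drop = FALSE]
    if (anyNA(sub)) Inf else sqrt(max(as.numeric(t(g) %*% sub %*% g), 0))
  } else {
    0
  }

  # per-channel unweighted RMSEs at the optimum
  cols <- c(
    X = "X_gL", S = "S_gL", A = "A_gL", DOT = "DOT_pct",
    OUR = "OUR_mmolLh", CPR = "CPR_mmolLh"
  )
  ch_rmse <- map(datasets, function(d) {
    sim <- simulate_batch(params_hat, replay_config(d), aux = aux, control = control)
    vapply(names(d$channels), function(ch) {
      obs <- d$channels[[ch]]
      rmse(tibble(t = sim$time_h, v = sim[[cols[[ch]]]]), tibble(obs$t_h, obs$value))
    }, numeric(1))
  })
  channel_rmse <- list_rbind(imap(ch_rmse, \(v, i) {
    tibble(dataset = i, channel = names(v), rmse = unname(v))
  }))

  fixed <- setdiff(parameter_names(free_only = TRUE), free)
  estimates <- bind_rows(
    tibble(
      parameter = free, estimate = unname(theta),
      std_error = unname(sds), role = "free"
    ),
    tibble(
      parameter = fixed,
      estimate = map_dbl(fixed, \(p) params_hat[[p]]),
      std_error = NA_real_, role = "fixed"
    ),
    tibble(
      parameter = "mu_max", estimate = mu_hat,
      std_error = mu_sd, role = "derived"
    )
  ) |>
    mutate(parameter = factor(.data$parameter, levels = parameter_names())) |>
    arrange(.data$parameter) |>
    mutate(parameter = as.character(.data$parameter))

  structure(
    list(
      estimates = estimates, params = params_hat, covariance = covar,
      rss = rss, sigma = sqrt(sigma2), n_obs = n_obs, free = free,
      fixed = fixed, channel_rmse = channel_rmse,
      convergence = best$info, message = best$message,
      converged = best$info %in% 1:4, best_start = best$start,
      starts = starts, seed = as.integer(seed),
      n_failures = length(failures), failures = failures,
      aux = aux, template = template
    ),
    class = "strain_fit"
  )
}

#' @export
print.strain_fit <- function(x, ...) {
  cat(sprintf(
    "<strain_fit> %d free parameters, %d observations, RSS = %.4g (%s)\n",
    length(x$free), x$n_obs, x$rss,
    if (x$converged) "converged" else "not converged"
  ))
  est <- x$estimates[x$estimates$role != "fixed", ]
  for (i in seq_len(nrow(est))) {
    cat(sprintf(
      "  %-9s %8.4g +/- %.2g%s\n", est$parameter[i], est$estimate[i],
      est$std_error[i], if (est$role[i] == "derived") " (derived)" else ""
    ))
  }
  invisible(x)
}

#' @rdname fit_parameters
#' @param x a `strain_fit`.
#' @param ... unused.
#' @export
tidy.strain_fit <- function(x, ...) {
  as_tibble(x$estimates)
}

#' @rdname fit_parameters
#' @export
glance.strain_fit <- function(x, ...) {
  tibble(
    rss = x$rss, sigma = x$sigma, nobs = x$n_obs,
    n_free = length(x$free), converged = x$converged,
    convergence = x$convergence, best_start = x$best_start, seed = x$seed
  )
}

#' @rdname fit_parameters
#' @param object a `strain_fit`.
#' @export
coef.strain_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$parameter)
}

#' Objective profile of one parameter (practical identifiability)
#'
#' Re-optimizes the remaining free parameters over a fixed grid of the
#' target parameter and returns the profile of residual sums of squares.
#' A sharp minimum indicates a well-identified parameter; a flat profile
#' (typical for the glucose affinity constant when all observations are
#' far above it) indicates practical non-identifiability.
#'
#' @param datasets as in [fit_parameters()].
#' @param fit a fitted `strain_fit` for the same datasets.
#' @param parameter name of the profiled parameter.
#' @param grid numeric grid of parameter values; default: log-spaced
#'   over `span` around the fitted value, clipped to the bounds.
#' @param span multiplicative half-range of the default grid.
#' @param n_grid number of default grid points.
#' @param maxiter Levenberg-Marquardt iteration cap per grid point.
#' @return A tibble with columns `value` and `objective` (RSS), plus the
#'   fitted optimum as attribute `optimum`.
#' @export
profile_identifiability <- function(datasets, fit, parameter, grid = NULL,
                                    span = 10, n_grid = 7, maxiter = 50) {
  stopifnot(inherits(fit, "strain_fit"))
  if (!parameter %in% fit$free) {
    abort("parameter must be free in the supplied fit", class = "colibatch_config_error")
  }
  datasets <- as_dataset_list(datasets)
  b <- default_parameter_bounds()
  bi <- b[b$parameter == parameter, ]
  p_hat <- fit$estimates$estimate[fit$estimates$parameter == parameter]
  if (is.null(grid)) {
    grid <- exp(seq(log(max(p_hat / span, bi$lower)),
      log(min(p_hat * span, bi$upper)),
      length.out = n_grid
    ))
  }
  others <- setdiff(fit$free, parameter)
  theta0 <- setNames(
    fit$estimates$estimate[match(others, fit$estimates$parameter)], others
  )
  bo <- b[match(others, b$parameter), ]
  objective <- map_dbl(grid, function(g) {
    if (length(others) == 0) {
      return(sum(fit_residuals(setNames(g, parameter), datasets,
        template = fit$template, aux = fit$aux
      )^2))
    }
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = log(theta0), lower = log(bo$lower), upper = log(bo$upper),
        fn = function(lt) {
          fit_residuals(
            c(setNames(g, parameter), setNames(exp(lt), others)),
            datasets,
            template = fit$template, aux = fit$aux
          )
        },
        control = minpack.lm::nls.lm.control(maxiter = maxiter)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) NA_real_ else res$deviance
  })
  out <- tibble(value = grid, objective = objective)
  structure(out,
    optimum = c(value = p_hat, objective = fit$rss),
    parameter = parameter,
    class = c("colibatch_profile", class(out))
  )
}
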