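# Batch/pulse cultivation simulator: stiff integration with
# depletion-triggered (or timed) glucose pulse events and stepped
# aeration, on a uniform output grid plus event times.

#' Numerical control settings for the simulator
#'
#' @param rtol,atol relative and absolute integrator tolerances.
#' @param method a [deSolve::ode()] method; `"lsoda"` switches
#'   automatically between stiff and non-stiff steppers.
#' @param maxsteps maximum internal steps per output interval.
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(rtol = 1e-8, atol = 1e-10, method = "lsoda",
                        maxsteps = 50000) {
  structure(
    list(rtol = rtol, atol = atol, method = method, maxsteps = maxsteps),
    class = "sim_control"
  )
}

#' Simulate a batch or glucose-pulse cultivation
#'
#' Integrates the reactor mass balances (see [state_derivatives()]) over
#' the run, firing glucose pulses either when glucose crosses the
#' depletion threshold from above (located by root finding) or at
#' pre-set times, and switching kLa at the configured aeration step
#' times. The trajectory is reported on a uniform output grid with
#' event times inserted, together with the specific rates and the
#' model's gas-exchange rates: `OUR = q_O X / 32 * 1000` (mmol O2/(L h))
#' and `CPR = RQ * OUR`.
#'
#' @param params a [strain_parameters()] object.
#' @param config a [platform_config()] (or [platform_preset()]).
#' @param aux an [aux_constants()] object.
#' @param dt_out output grid spacing, h.
#' @param t_end override of the configured run length, h.
#' @param control a [sim_control()].
#' @return A tibble of class `batch_sim` with columns `time_h`, `X_gL`,
#'   `S_gL`, `A_gL`, `DOT_pct`, `qS`, `qAp`, `qAc`, `qO`, `mu`,
#'   `OUR_mmolLh`, `CPR_mmolLh`, `event_flag`, and attributes `events`
#'   (a tibble of pulse/aeration events) and `config`.
#' @examples
#' sim <- simulate_batch(reference_params("WG", 10), platform_preset("MBR"))
#' attr(sim, "events")
#' @export
simulate_batch <- function(params, config, aux = aux_constants(),
                           dt_out = 1 / 60, t_end = NULL,
                           control = sim_control()) {
  stopifnot(inherits(config, "platform_config"))
  t_end <- t_end %||% config$t_end
  if (t_end <= 0) abort("t_end must be positive", class = "colibatch_config_error")

  pls <- config$pulses
  pulse_target <- pls$target %||% config$S0
  pulses_left <- if (pls$mode == "depletion") pls$max_pulses else 0L
  lag <- config$lag_h

  # parameter block for the compiled rhs (src/colibatch_model.c);
  # slot 16 carries the segment-constant kLa, set per segment below
  parms <- c(
    params$q_S_max, params$K_S, params$q_Ap_max, params$q_Ac_max,
    params$q_O_max, params$q_m, params$Y_XS_em, params$Y_OX,
    aux$Y_AS, aux$Y_XA, aux$K_A, aux$K_O, aux$c_Om, aux$K_IS,
    100 / aux$C_O2_star, NA_real_, lag, pls$threshold
  )

  # segment boundaries: aeration/flow steps, lag end, timed pulses
  breaks <- sort(unique(c(
    config$kLa$t, config$F_in$t, lag,
    if (pls$mode == "timed") pls$times
  )))
  breaks <- c(breaks[breaks > 0 & breaks < t_end], t_end)
  timed_pulses <- if (pls$mode == "timed") pls$times else numeric()

  grid <- seq(0, t_end, by = dt_out)
  y <- c(X = config$X0, S = config$S0, A = config$A0, DOT = config$DOT0)
  t_cur <- 0
  rows <- list()
  events <- list()
  for (kt in setdiff(config$kLa$t, 0)) {
    if (kt < t_end) {
      events[[length(events) + 1]] <-
        tibble(time = kt, type = "aeration", value = schedule_value(config$kLa, kt))
    }
  }

  for (b in breaks) {
    repeat {
      times <- unique(sort(c(t_cur, grid[grid > t_cur & grid < b], b)))
      use_root <- pls$mode == "depletion" && pulses_left > 0 &&
        y["S"] > pls$threshold
      parms[16] <- schedule_value(config$kLa, (t_cur + b) / 2)
      sol <- try(
        if (use_root) {
          deSolve::lsodar(y, times,
            func = "colibatch_derivs", parms = parms,
            dllname = "colibatch", initfunc = "colibatch_init",
            rootfunc = "colibatch_root", nroot = 1,
            rtol = control$rtol, atol = control$atol,
            maxsteps = control$maxsteps
          )
        } else {
          deSolve::ode(y, times,
            func = "colibatch_derivs", parms = parms,
            dllname = "colibatch", initfunc = "colibatch_init",
            method = control$method,
            rtol = control$rtol, atol = control$atol,
            maxsteps = control$maxsteps
          )
        },
        silent = TRUE
      )
      if (inherits(sol, "try-error") || any(!is.finite(sol[nrow(sol), -1]))) {
        abort(
          sprintf(
            "integration failed near t = %.4g h (last valid time %.4g h)",
            b, t_cur
          ),
          class = "colibatch_integration_error",
          last_valid_time = t_cur
        )
      }
      n <- nrow(sol)
      rows[[length(rows) + 1]] <- sol[if (t_cur > 0) -1L else TRUE, , drop = FALSE]
      t_last <- sol[n, 1]
      y <- pmax(sol[n, -1], 0)
      names(y) <- c("X", "S", "A", "DOT")
      rooted <- use_root && t_last < b - 1e-10
      if (!use_root && t_last < b - 1e-10) {
        # solver returned early without reaching the segment end
        abort(
          sprintf(
            "integration stopped early at t = %.4g h (target %.4g h)",
            t_last, b
          ),
          class = "colibatch_integration_error",
          last_valid_time = t_last
        )
      }
      t_cur <- t_last
      if (rooted) {
        # glucose depleted: re-feed to the pulse target
        events[[length(events) + 1]] <-
          tibble(time = t_last, type = "pulse", value = as.numeric(pulse_target - y["S"]))
        y["S"] <- pulse_target
        pulses_left <- pulses_left - 1L
      } else {
        break
      }
    }
    if (b %in% timed_pulses) {
      events[[length(events) + 1]] <-
        tibble(time = b, type = "pulse", value = as.numeric(pulse_target - y["S"]))
      y["S"] <- pulse_target
    }
  }

  out <- do.call(rbind, rows)
  traj <- tibble(
    time_h = out[, 1],
    X_gL = pmax(out[, 2], 0), S_gL = pmax(out[, 3], 0),
    A_gL = pmax(out[, 4], 0), DOT_pct = pmin(pmax(out[, 5], 0), 100 + 1e-6)
  )
  r <- .rates(traj$X_gL, traj$S_gL, traj$A_gL, traj$DOT_pct, params, aux)
  lagged <- traj$time_h < lag
  for (nm in names(r)) r[[nm]][lagged] <- 0
  ev <- if (length(events)) bind_rows(events) else
    tibble(time = numeric(), type = character(), value = numeric())
  traj <- traj |>
    mutate(
      qS = r$q_S, qAp = r$q_Ap, qAc = r$q_Ac, qO = r$q_O, mu = r$mu,
      OUR_mmolLh = .data$qO * .data$X_gL / 32 * 1000,
      CPR_mmolLh = config$RQ * .data$OUR_mmolLh,
      event_flag = .data$time_h %in% ev$time
    )
  structure(traj,
    events = ev, config = config, params = params,
    class = c("batch_sim", class(traj))
  )
}

#' Pulse events of a simulated trajectory
#'
#' @param sim a `batch_sim` trajectory from [simulate_batch()].
#' @return Tibble of pulse events (`time`, `value` = glucose added g/L).
#' @export
pulse_events <- function(sim) {
  ev <- attr(sim, "events")
  ev[ev$type == "pulse", ]
}

#' Time of final glucose depletion of a trajectory
#'
#' The last time glucose falls below `threshold` (the end of the final
#' batch phase, visible experimentally as the terminal DOT rise).
#' Returns `NA` if glucose never depletes.
#'
#' @param sim a `batch_sim` trajectory.
#' @param threshold depletion level, g/L.
#' @return Time in h, or `NA`.
#' @export
batch_end_time <- function(sim, threshold = 0.05) {
  below <- sim$S_gL < threshold
  if (!any(below)) {
    return(NA_real_)
  }
  above <- which(!below)
  last_above <- if (length(above)) max(above) else 0L
  if (last_above == nrow(sim)) {
    return(NA_real_)
  }
  sim$time_h[last_above + 1L]
}
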