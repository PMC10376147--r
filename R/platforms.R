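# Platform/reactor context: volumes, mass transfer, aeration, sampling
# grids, measurement noise and glucose-pulse policy.

#' Step schedule for a time-varying operating variable
#'
#' @param t step start times, h; must begin at 0 and be non-decreasing.
#' @param value value holding from each start time onward.
#' @return A tibble with columns `t` and `value`.
#' @export
schedule <- function(t, value) {
  if (length(t) == 0 || length(t) != length(value)) {
    abort("schedule needs matching, non-empty t and value", class = "colibatch_config_error")
  }
  if (t[1] != 0 || is.unsorted(t)) {
    abort("schedule times must start at 0 and be non-decreasing", class = "colibatch_config_error")
  }
  tibble(t = as.numeric(t), value = as.numeric(value))
}

# value of a step schedule at times tt
schedule_value <- function(sch, tt) {
  sch$value[findInterval(tt, sch$t, rightmost.closed = FALSE)]
}

as_schedule <- function(x) {
  if (is.data.frame(x)) schedule(x$t, x$value) else schedule(0, x)
}

#' Glucose pulse policy
#'
#' Batch cultivations are optionally re-fed ("pulsed") back to a target
#' glucose concentration, either when glucose depletes below a trigger
#' threshold or at pre-recorded times (for replaying logged experiments).
#'
#' @param mode `"depletion"`, `"timed"`, or `"none"`.
#' @param target glucose concentration restored by a pulse, g/L; defaults
#'   to the run's initial glucose when `NULL`.
#' @param threshold depletion trigger threshold, g/L.
#' @param max_pulses maximum number of pulses (0, 1 or 2).
#' @param times pulse times for `"timed"` mode, h.
#' @return A list of class `pulse_schedule`.
#' @export
pulse_schedule <- function(mode = c("none", "depletion", "timed"),
                           target = NULL, threshold = 0.05,
                           max_pulses = 0, times = numeric()) {
  mode <- match.arg(mode)
  if (threshold < 0) {
    abort("pulse threshold must be >= 0", class = "colibatch_config_error")
  }
  if (!max_pulses %in% 0:2) {
    abort("max_pulses must be 0, 1 or 2", class = "colibatch_config_error")
  }
  if (mode == "timed" && length(times) > 2) {
    abort("at most two timed pulses are supported", class = "colibatch_config_error")
  }
  structure(
    list(
      mode = mode, target = target, threshold = threshold,
      max_pulses = if (mode == "timed") length(times) else max_pulses,
      times = sort(as.numeric(times))
    ),
    class = "pulse_schedule"
  )
}

# default per-channel measurement noise; sd = max(rel*|value|, floor),
# except purely additive channels where only floor applies
default_noise <- function() {
  list(
    X = list(rel = 0.05, floor = 0.01),
    S = list(rel = 0.03, floor = 0.05),
    A = list(rel = 0.05, floor = 0.02),
    DOT = list(rel = 0, floor = 2),
    gas = list(rel = 0, floor = 2e-4),
    OUR = list(rel = 0.03, floor = 1),
    CPR = list(rel = 0.03, floor = 1)
  )
}

#' Reactor/platform configuration
#'
#' Describes the cultivation context: working volume, oxygen transfer
#' (kLa schedule), aeration, inlet gas composition, initial state,
#' sampling grids, per-channel noise, pulse policy and run length.
#' Usually built via [platform_preset()] and adjusted through `...`
#' overrides there or by modifying fields directly.
#'
#' @param platform tag: `"MTP"`, `"MBR"`, `"STR"` or `"custom"`.
#' @param V working volume, L.
#' @param X0,S0,A0,DOT0 initial biomass, glucose, acetate (g/L) and DOT
#'   (% air saturation).
#' @param t_end simulated run length, h.
#' @param kLa volumetric mass-transfer coefficient, 1/h; a constant or a
#'   [schedule()].
#' @param F_in inlet gas flow, L/h; constant or [schedule()].
#' @param gas_in inlet mole fractions, named `O2` and `CO2`.
#' @param RQ respiratory quotient used for the model CPR.
#' @param lag_h initial dead time with no metabolic activity, h.
#' @param pulses a [pulse_schedule()].
#' @param channels measured channels, subset of
#'   `c("X","S","A","DOT","OUR","CPR")`.
#' @param sampling named list of sampling intervals per channel group,
#'   h: `DOT`, `atline` (X/S/A), `offgas`.
#' @param noise named list of per-channel noise settings (`rel`,
#'   `floor`); see defaults in the vignette.
#' @param temperature cultivation temperature tag, C.
#' @return A list of class `platform_config`.
#' @export
platform_config <- function(platform = "custom", V, X0, S0, A0 = 0, DOT0 = 100,
                            t_end = 12, kLa = 600, F_in = 1,
                            gas_in = c(O2 = 0.2095, CO2 = 0.0004),
                            RQ = 1.0, lag_h = 0,
                            pulses = pulse_schedule(),
                            channels = c("X", "S", "A", "DOT"),
                            sampling = list(DOT = 1 / 60, atline = 0.5, offgas = 1 / 60),
                            noise = default_noise(),
                            temperature = 37) {
  kLa <- as_schedule(kLa)
  F_in <- as_schedule(F_in)
  if (any(kLa$value <= 0)) {
    abort("kLa must be strictly positive", class = "colibatch_config_error")
  }
  if (any(F_in$value <= 0)) {
    abort("F_in must be strictly positive", class = "colibatch_config_error")
  }
  stopifnot(V > 0, X0 >= 0, S0 >= 0, A0 >= 0, DOT0 >= 0, t_end > 0, lag_h >= 0)
  bad <- setdiff(channels, c("X", "S", "A", "DOT", "OUR", "CPR"))
  if (length(bad)) {
    abort(paste("unknown channels:", paste(bad, collapse = ", ")),
      class = "colibatch_config_error"
    )
  }
  structure(
    list(
      platform = platform, V = V, X0 = X0, S0 = S0, A0 = A0, DOT0 = DOT0,
      t_end = t_end, kLa = kLa, F_in = F_in, gas_in = gas_in, RQ = RQ,
      lag_h = lag_h, pulses = pulses, channels = channels,
      sampling = sampling, noise = modifyList(default_noise(), noise),
      temperature = temperature
    ),
    class = "platform_config"
  )
}

#' Platform presets for the three cultivation scales
#'
#' Returns a ready-made [platform_config()] for one of the three
#' platforms of the characterization workflow:
#'
#' * `"MTP"`: 24-well microtiter plate, 1 mL, DOT-only optode monitoring
#'   on a 1-min grid, inoculated to OD600 0.25; kLa chosen so the
#'   maximum oxygen transfer rate is about 30 mmol O2/(L h).
#' * `"MBR"`: 10 mL stirred mini-bioreactor, OD600 0.5, initial glucose
#'   5 or 10 g/L with depletion-triggered glucose pulses (twice at
#'   5 g/L, once at 10 g/L); DOT on a 1-min grid and atline X/S/A every
#'   30 min.
#' * `"STR"`: 100 mL stirred-tank (90 mL working volume), 20 g/L
#'   glucose, 1-min off-gas analysis, stepped aeration (0.22 vvm, then
#'   0.66 vvm from 2.75 h, then 1.66 vvm from 6.8 h) with a matching
#'   stepped kLa; atline X/S/A hourly.
#'
#' Biomass is converted from OD600 with 0.37 g/L per OD unit
#' (configurable via `od_to_dcw`).
#'
#' @param platform `"MTP"`, `"MBR"` or `"STR"`.
#' @param S0 initial glucose, g/L. Defaults: MTP 10, MBR 10, STR 20.
#' @param od_to_dcw dry-cell-weight per OD600 unit, g/L.
#' @param ... overrides passed on to [platform_config()] fields (applied
#'   with [modifyList()] semantics on the preset arguments).
#' @return A [platform_config()].
#' @examples
#' platform_preset("MBR", S0 = 5)$pulses$max_pulses
#' @export
platform_preset <- function(platform = c("MTP", "MBR", "STR"), S0 = NULL,
                            od_to_dcw = 0.37, ...) {
  platform <- tryCatch(match.arg(platform), error = function(e) {
    abort(sprintf("unknown platform tag '%s'", platform[1]),
      class = "colibatch_config_error"
    )
  })
  args <- switch(platform,
    MTP = list(
      platform = "MTP", V = 0.001, X0 = 0.25 * od_to_dcw,
      S0 = S0 %||% 10, t_end = 16,
      # kLa * C_O2_star ~ 30 mmol O2/(L h) ceiling of the well plate
      kLa = 133, F_in = 0.06,
      channels = "DOT",
      sampling = list(DOT = 1 / 60, atline = Inf, offgas = Inf)
    ),
    MBR = {
      s0 <- S0 %||% 10
      list(
        platform = "MBR", V = 0.010, X0 = 0.5 * od_to_dcw, S0 = s0,
        t_end = 12, kLa = 600, F_in = 0.3,
        pulses = pulse_schedule(
          mode = "depletion", target = s0, threshold = 0.05,
          max_pulses = if (s0 <= 5) 2 else 1
        ),
        channels = c("X", "S", "A", "DOT"),
        sampling = list(DOT = 1 / 60, atline = 0.5, offgas = Inf)
      )
    },
    STR = list(
      platform = "STR", V = 0.090, X0 = 0.5 * od_to_dcw,
      S0 = S0 %||% 20, t_end = 14,
      kLa = schedule(c(0, 2.75, 6.8), c(300, 500, 900)),
      # 0.22 / 0.66 / 1.66 vvm on 90 mL
      F_in = schedule(c(0, 2.75, 6.8), c(0.22, 0.66, 1.66) * 0.090 * 60),
      channels = c("X", "S", "A", "OUR", "CPR"),
      sampling = list(DOT = 1 / 60, atline = 1, offgas = 1 / 60)
    )
  )
  do.call(platform_config, modifyList(args, list(...)))
}

#' @export
print.platform_config <- function(x, ...) {
  cat(sprintf(
    "<platform_config> %s: V=%g L, X0=%.3g g/L, S0=%g g/L, t_end=%g h\n",
    x$platform, x$V, x$X0, x$S0, x$t_end
  ))
  cat(sprintf(
    "  kLa %s 1/h; pulses: %s (max %d); channels: %s\n",
    paste(unique(x$kLa$value), collapse = "/"), x$pulses$mode,
    x$pulses$max_pulses, paste(x$channels, collapse = ",")
  ))
  invisible(x)
}
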