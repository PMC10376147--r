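# In-silico cultivation datasets: simulate a ground-truth trajectory,
# sample each measurement channel on its grid, and corrupt with the
# platform's noise model. For the stirred-tank platform, outlet gas
# fractions are fabricated from the model OUR/CPR and perturbed with
# gas-analyzer noise before the rates are re-derived, exactly as a
# real off-gas train would produce them.

sample_channel <- function(truth_t, truth_v, grid_t, noise, noise_scale = 1) {
  v <- approx(truth_t, truth_v, xout = grid_t, rule = 2)$y
  sd <- pmax(noise$rel * abs(v), noise$floor)
  obs <- pmax(v + noise_scale * rnorm(length(v), 0, sd), 0)
  tibble(t_h = grid_t, value = obs, sd = sd)
}

#' Generate one synthetic cultivation dataset
#'
#' Simulates the true trajectory under `config` with [simulate_batch()],
#' samples the configured channels on their grids and applies the
#' platform noise model: multiplicative Gaussian noise (with an absolute
#' floor) for biomass, glucose and acetate; additive noise for DOT and
#' for the gas mole fractions. Negative draws are clipped at zero.
#' Generation is reproducible given `seed`.
#'
#' @param params a [strain_parameters()] object (the ground truth).
#' @param config a [platform_config()].
#' @param seed integer seed for the measurement noise.
#' @param aux an [aux_constants()] object.
#' @param control a [sim_control()].
#' @param noise_scale multiplier on every noise draw; 0 gives noiseless
#'   observations while keeping the nominal channel sds (useful for
#'   consistency checks).
#' @return An object of class `cultivation_dataset`: a list with
#'   elements `platform`, `strain`, `channels` (named list of tibbles
#'   `t_h`, `value`, `sd`), `offgas` (fabricated analyzer table for
#'   platforms with off-gas analysis, else `NULL`), `truth` (the
#'   noiseless `batch_sim` trajectory), `events` (pulse/aeration log),
#'   `config` and `seed`.
#' @examples
#' d <- generate_dataset(reference_params("WG", 10), platform_preset("MBR"), seed = 1)
#' names(d$channels)
#' @export
generate_dataset <- function(params, config, seed, aux = aux_constants(),
                             control = sim_control(), noise_scale = 1) {
  stopifnot(inherits(config, "platform_config"))
  truth <- simulate_batch(params, config, aux = aux, control = control)
  events <- attr(truth, "events")
  noise <- config$noise

  withr::local_seed(as.integer(seed))

  grids <- list(
    X = seq(0, config$t_end, by = config$sampling$atline),
    S = seq(0, config$t_end, by = config$sampling$atline),
    A = seq(0, config$t_end, by = config$sampling$atline),
    DOT = seq(0, config$t_end, by = config$sampling$DOT)
  )
  cols <- c(X = "X_gL", S = "S_gL", A = "A_gL", DOT = "DOT_pct")

  channels <- list()
  for (ch in intersect(c("X", "S", "A", "DOT"), config$channels)) {
    channels[[ch]] <- sample_channel(
      truth$time_h, truth[[cols[[ch]]]], grids[[ch]], noise[[ch]], noise_scale
    )
  }

  offgas <- NULL
  if (any(c("OUR", "CPR") %in% config$channels)) {
    tg <- seq(0, config$t_end, by = config$sampling$offgas)
    our_m <- approx(truth$time_h, truth$OUR_mmolLh, xout = tg, rule = 2)$y
    cpr_m <- approx(truth$time_h, truth$CPR_mmolLh, xout = tg, rule = 2)$y
    f_in <- schedule_value(config$F_in, tg)
    frac <- invert_offgas(our_m, cpr_m, f_in, config$V,
      x_O2_in = config$gas_in[["O2"]], x_CO2_in = config$gas_in[["CO2"]]
    )
    gs <- noise$gas$floor
    offgas <- tibble(
      t_h = tg, F_in_Lh = f_in, V_L = config$V,
      xO2_in = config$gas_in[["O2"]], xCO2_in = config$gas_in[["CO2"]],
      xO2_out = pmin(pmax(frac$xO2_out + noise_scale * rnorm(length(tg), 0, gs), 0), 0.9999),
      xCO2_out = pmin(pmax(frac$xCO2_out + noise_scale * rnorm(length(tg), 0, gs), 0), 0.9999)
    )
    rates <- offgas_rates(offgas)
    if ("OUR" %in% config$channels) {
      channels$OUR <- tibble(
        t_h = tg, value = rates$OUR_mmolLh,
        sd = pmax(noise$OUR$rel * abs(rates$OUR_mmolLh), noise$OUR$floor)
      )
    }
    if ("CPR" %in% config$channels) {
      channels$CPR <- tibble(
        t_h = tg, value = rates$CPR_mmolLh,
        sd = pmax(noise$CPR$rel * abs(rates$CPR_mmolLh), noise$CPR$floor)
      )
    }
  }

  structure(
    list(
      platform = config$platform,
      strain = params$strain,
      channels = channels,
      offgas = offgas,
      truth = truth,
      events = events,
      config = config,
      params_truth = params,
      seed = as.integer(seed)
    ),
    class = "cultivation_dataset"
  )
}

#' @export
print.cultivation_dataset <- function(x, ...) {
  cat(sprintf(
    "<cultivation_dataset> %s%s, S0 = %g g/L, channels: %s, seed %d\n",
    x$platform, if (!is.na(x$strain)) paste0(" ", x$strain) else "",
    x$config$S0, paste(names(x$channels), collapse = ","), x$seed
  ))
  invisible(x)
}

#' Observations of a dataset in long form
#'
#' @param dataset a `cultivation_dataset`.
#' @return Tibble with columns `channel`, `t_h`, `value`, `sd`.
#' @export
dataset_observations <- function(dataset) {
  imap(dataset$channels, \(d, ch) mutate(d, channel = ch, .before = 1)) |>
    list_rbind()
}

#' Generate a campaign of synthetic cultivation runs
#'
#' Maps [generate_dataset()] over a plan of strain x platform x
#' condition entries, drawing ground-truth parameters from
#' [reference_params()] unless a `params` list-column is supplied.
#' Per-run seeds are derived deterministically from `seed` (distinct
#' unless given explicitly in a `seed` column, e.g. for replicate
#' semantics).
#'
#' @param plan a data frame with columns `strain`, `platform`, `S0`
#'   (g/L); optional columns `params` (list of [strain_parameters()]),
#'   `seed`, `lag_h`.
#' @param seed campaign-level integer seed.
#' @param aux an [aux_constants()] object.
#' @param ... overrides forwarded to [platform_preset()].
#' @return An object of class `cultivation_campaign`: list of `plan` and
#'   `datasets`.
#' @export
synthetic_campaign <- function(plan, seed = 1, aux = aux_constants(), ...) {
  plan <- as_tibble(plan)
  if (!all(c("strain", "platform", "S0") %in% names(plan))) {
    abort("plan needs columns strain, platform, S0", class = "colibatch_config_error")
  }
  if (!"seed" %in% names(plan)) plan$seed <- seed * 1000L + seq_len(nrow(plan))
  datasets <- pmap(
    list(seq_len(nrow(plan)), plan$strain, plan$platform, plan$S0, plan$seed),
    function(i, strain, platform, S0, run_seed) {
      p <- if ("params" %in% names(plan)) plan$params[[i]] else reference_params(strain, S0)
      cfg <- platform_preset(platform, S0 = S0, ...)
      if ("lag_h" %in% names(plan)) cfg$lag_h <- plan$lag_h[i]
      generate_dataset(p, cfg, seed = run_seed, aux = aux)
    }
  )
  structure(list(plan = plan, datasets = datasets), class = "cultivation_campaign")
}

#' Summarize a campaign, one row per run
#'
#' @param campaign a `cultivation_campaign` (or a list of
#'   `cultivation_dataset`s).
#' @return A tibble with columns `strain`, `platform`, `S0_gL`,
#'   `n_pulses`, `batch_end_h` (time of final glucose depletion),
#'   `peak_OUR_mmolLh`, `final_X_gL`, `peak_A_gL`.
#' @export
campaign_table <- function(campaign) {
  datasets <- if (inherits(campaign, "cultivation_campaign")) {
    campaign$datasets
  } else {
    campaign
  }
  if (length(datasets) == 0) {
    return(tibble(
      strain = character(), platform = character(), S0_gL = numeric(),
      n_pulses = integer(), batch_end_h = numeric(),
      peak_OUR_mmolLh = numeric(), final_X_gL = numeric(), peak_A_gL = numeric()
    ))
  }
  map(datasets, function(d) {
    tr <- d$truth
    tibble(
      strain = d$strain, platform = d$platform, S0_gL = d$config$S0,
      n_pulses = sum(d$events$type == "pulse"),
      batch_end_h = batch_end_time(tr),
      peak_OUR_mmolLh = max(tr$OUR_mmolLh),
      final_X_gL = tr$X_gL[nrow(tr)],
      peak_A_gL = max(tr$A_gL)
    )
  }) |> list_rbind()
}
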