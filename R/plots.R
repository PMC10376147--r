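# ggplot2 views of the main result types.

state_labels <- c(
  X_gL = "biomass [g/L]", S_gL = "glucose [g/L]", A_gL = "acetate [g/L]",
  DOT_pct = "DOT [%]", OUR_mmolLh = "OUR [mmol/(L h)]",
  CPR_mmolLh = "CPR [mmol/(L h)]"
)

#' Plot a simulated cultivation trajectory
#'
#' States (and optionally gas-exchange rates) against time, one facet
#' per variable, with pulse events marked.
#'
#' @param object a `batch_sim` from [simulate_batch()].
#' @param gas include the model OUR/CPR facets.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.batch_sim <- function(object, gas = FALSE, ...) {
  vars <- c("X_gL", "S_gL", "A_gL", "DOT_pct", if (gas) c("OUR_mmolLh", "CPR_mmolLh"))
  long <- as_tibble(object) |>
    select(dplyr::all_of(c("time_h", vars))) |>
    pivot_longer(-"time_h", names_to = "variable") |>
    mutate(variable = factor(state_labels[.data$variable], levels = state_labels[vars]))
  ev <- pulse_events(object)
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time [h]", y = NULL)
  if (nrow(ev)) {
    gg <- gg + ggplot2::geom_vline(
      data = ev, ggplot2::aes(xintercept = .data$time),
      linetype = "dashed", colour = "grey50"
    )
  }
  gg
}

#' Plot a synthetic cultivation dataset
#'
#' Noisy observations (points) over the ground-truth trajectory
#' (lines), one facet per measured channel.
#'
#' @param object a `cultivation_dataset`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cultivation_dataset <- function(object, ...) {
  cols <- c(
    X = "X_gL", S = "S_gL", A = "A_gL", DOT = "DOT_pct",
    OUR = "OUR_mmolLh", CPR = "CPR_mmolLh"
  )
  obs <- dataset_observations(object)
  truth <- imap(object$channels, \(d, ch) {
    tibble(
      channel = ch, t_h = object$truth$time_h,
      value = object$truth[[cols[[ch]]]]
    )
  }) |> list_rbind()
  ggplot2::ggplot(obs, ggplot2::aes(.data$t_h, .data$value)) +
    ggplot2::geom_line(data = truth, colour = "grey40") +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(
      x = "time [h]", y = NULL,
      title = sprintf("%s, S0 = %g g/L", object$platform, object$config$S0)
    )
}

#' Plot fitted parameters with uncertainties
#'
#' Point estimates with +/- 1 and +/- 3 standard-uncertainty bars, one
#' panel per parameter; optional reference values overlaid.
#'
#' @param object a `strain_fit`.
#' @param reference optional named numeric vector of reference parameter
#'   values to overlay (e.g. the generating truth).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.strain_fit <- function(object, reference = NULL, ...) {
  est <- as_tibble(object$estimates) |> filter(.data$role != "fixed")
  gg <- ggplot2::ggplot(est, ggplot2::aes(x = .data$parameter, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$std_error,
      ymax = .data$estimate + .data$std_error
    )) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$estimate - 3 * .data$std_error,
        ymax = .data$estimate + 3 * .data$std_error
      ),
      width = 0.2, linewidth = 0.2
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate")
  if (!is.null(reference)) {
    ref <- tibble(
      parameter = names(reference),
      value = as.numeric(reference)
    ) |> filter(.data$parameter %in% est$parameter)
    gg <- gg + ggplot2::geom_hline(
      data = ref, ggplot2::aes(yintercept = .data$value),
      colour = "red3", linetype = "dotted"
    )
  }
  gg
}

#' Plot an identifiability profile
#'
#' @param object output of [profile_identifiability()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.colibatch_profile <- function(object, ...) {
  opt <- attr(object, "optimum")
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = tibble(value = opt[["value"]], objective = opt[["objective"]]),
      colour = "red3"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = attr(object, "parameter"), y = "residual sum of squares"
    )
}
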