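# Delimited-table and YAML/JSON interfaces: trajectory export, off-gas
# CSV dialect, parameter sets, fit serialization and the Table-2-shaped
# parameter report.

#' Write / read a simulated trajectory as CSV
#'
#' Columns: `time_h, X_gL, S_gL, A_gL, DOT_pct, qS, qAp, qAc, qO, mu,
#' OUR_mmolLh, CPR_mmolLh, event_flag`.
#'
#' @param sim a `batch_sim` trajectory.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a tibble.
#' @export
write_trajectory <- function(sim, path) {
  readr::write_csv(as_tibble(sim), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read an off-gas table as CSV
#'
#' The dialect used throughout the package: columns `t_h, F_in_Lh, V_L,
#' xO2_in, xCO2_in, xO2_out, xCO2_out`, with a `# unit: ...` header line
#' recording whether fractions are stored as 0-1 fractions or percent.
#'
#' @param records an off-gas tibble (see [compute_our()]).
#' @param path file path.
#' @param unit unit flag written into the header metadata.
#' @return `write_offgas()` returns `path` invisibly; `read_offgas()`
#'   returns a tibble with fractions canonicalized to 0-1.
#' @export
write_offgas <- function(records, path, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  writeLines(sprintf("# unit: %s", unit), path)
  readr::write_csv(records, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_offgas
#' @export
read_offgas <- function(path) {
  first <- readLines(path, n = 1)
  unit <- if (grepl("^# unit:", first)) {
    trimws(sub("^# unit:", "", first))
  } else {
    "fraction"
  }
  rec <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  check_offgas(rec, unit = unit)
}

#' Write / read a strain parameter set as YAML
#'
#' Field names follow the standard symbols (`mu_max`, `K_S`, `q_S_max`,
#' `q_Ap_max`, `q_Ac_max`, `q_O_max`, `q_m`, `Y_XS_em`, `Y_OX`).
#'
#' @param params a [strain_parameters()].
#' @param path file path.
#' @return `write_strain_params()` returns `path` invisibly;
#'   `read_strain_params()` returns a [strain_parameters()].
#' @export
write_strain_params <- function(params, path) {
  x <- params[parameter_names()]
  x$strain <- if (!is.na(params$strain)) params$strain else NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_strain_params
#' @export
read_strain_params <- function(path) {
  x <- yaml::read_yaml(path)
  strain_parameters(
    q_S_max = x$q_S_max, q_Ap_max = x$q_Ap_max, q_Ac_max = x$q_Ac_max,
    q_O_max = x$q_O_max, q_m = x$q_m, Y_XS_em = x$Y_XS_em, Y_OX = x$Y_OX,
    K_S = x$K_S, mu_max = x$mu_max, strain = x$strain %||% NA_character_
  )
}

#' Serialize a fit to JSON
#'
#' @param fit a `strain_fit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      estimates = fit$estimates,
      rss = fit$rss, sigma = fit$sigma, n_obs = fit$n_obs,
      free = fit$free, fixed = fit$fixed,
      channel_rmse = fit$channel_rmse,
      converged = fit$converged, convergence = fit$convergence,
      best_start = fit$best_start, seed = fit$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Parameter report across fitted strain x condition columns
#'
#' Arranges several fits into the conventional characterization layout:
#' one row per parameter, one column per strain x condition, cells
#' formatted as `"value +/- sd"`.
#'
#' @param fits named list of `strain_fit` objects; names become the
#'   column headers (e.g. `"WG (10)"`).
#' @param digits significant digits for the cells.
#' @return A tibble with a `parameter` column plus one column per fit.
#' @export
parameter_table <- function(fits, digits = 3) {
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  cols <- imap(fits, function(f, nm) {
    est <- f$estimates
    cell <- ifelse(
      est$role == "fixed",
      paste0(signif(est$estimate, digits), " (fixed)"),
      paste0(
        signif(est$estimate, digits), " ± ",
        signif(est$std_error, 2)
      )
    )
    setNames(tibble(cell), nm)
  })
  bind_cols(tibble(parameter = fits[[1]]$estimates$parameter), cols)
}
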