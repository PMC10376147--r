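#' Strain-specific kinetic parameters
#'
#' Bundles the nine macro-kinetic parameters that characterize one
#' *E. coli* strain under one cultivation condition: Monod uptake
#' kinetics, overflow acetate production, acetate re-consumption,
#' respiratory capacity, maintenance and the two yield coefficients.
#'
#' `mu_max` is not an independent rate-law parameter in this model: the
#' realized maximum growth rate on glucose follows from the flux balance
#' as `(q_S_max - q_m) * Y_XS_em` (further reduced by glucose diverted
#' into acetate). When `mu_max` is omitted it is derived from that
#' identity; when supplied it is kept as a descriptive summary and
#' checked for plausibility.
#'
#' @param q_S_max maximum specific glucose uptake rate, g/(g h).
#' @param q_Ap_max maximum specific acetate production rate, g/(g h).
#' @param q_Ac_max maximum specific acetate consumption rate, g/(g h).
#' @param q_O_max maximum specific oxygen uptake rate, g/(g h).
#' @param q_m maintenance coefficient on glucose, g/(g h); must be
#'   smaller than `q_S_max`.
#' @param Y_XS_em biomass-on-glucose yield excluding maintenance, g/g;
#'   bounded above by `Y_XS_em_max`.
#' @param Y_OX oxygen-on-biomass yield, g/g.
#' @param K_S glucose affinity constant, g/L.
#' @param mu_max maximum specific growth rate, 1/h; derived from the
#'   yield identity when `NULL`.
#' @param strain optional strain label.
#' @param Y_XS_em_max thermodynamic sanity bound on `Y_XS_em` (g/g).
#'
#' @return An object of class `strain_parameters` (a named list).
#' @seealso [aux_constants()], [reference_strains()]
#' @examples
#' p <- strain_parameters(
#'   q_S_max = 1.13, q_Ap_max = 0.10, q_Ac_max = 0.07, q_O_max = 0.91,
#'   q_m = 0.056, Y_XS_em = 0.56, Y_OX = 1.49, K_S = 0.009
#' )
#' p$mu_max
#' @export
strain_parameters <- function(q_S_max, q_Ap_max, q_Ac_max, q_O_max, q_m,
                              Y_XS_em, Y_OX, K_S = 0.01, mu_max = NULL,
                              strain = NA_character_, Y_XS_em_max = 0.7) {
  vals <- c(
    q_S_max = q_S_max, q_Ap_max = q_Ap_max, q_Ac_max = q_Ac_max,
    q_O_max = q_O_max, q_m = q_m, Y_XS_em = Y_XS_em, Y_OX = Y_OX, K_S = K_S
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all kinetic parameters must be finite and strictly positive",
      class = "colibatch_invalid_parameters"
    )
  }
  if (Y_XS_em > Y_XS_em_max) {
    abort(
      sprintf("Y_XS_em = %.3g exceeds the sanity bound %.3g g/g", Y_XS_em, Y_XS_em_max),
      class = "colibatch_invalid_parameters"
    )
  }
  if (q_m >= q_S_max) {
    abort("maintenance coefficient q_m must be smaller than q_S_max",
      class = "colibatch_invalid_parameters"
    )
  }
  derived <- (q_S_max - q_m) * Y_XS_em
  if (is.null(mu_max)) {
    mu_max <- derived
  } else if (!is.finite(mu_max) || mu_max <= 0) {
    abort("mu_max must be finite and strictly positive",
      class = "colibatch_invalid_parameters"
    )
  }
  structure(
    list(
      mu_max = mu_max, K_S = K_S, q_S_max = q_S_max, q_Ap_max = q_Ap_max,
      q_Ac_max = q_Ac_max, q_O_max = q_O_max, q_m = q_m,
      Y_XS_em = Y_XS_em, Y_OX = Y_OX, strain = strain
    ),
    class = "strain_parameters"
  )
}

#' @export
print.strain_parameters <- function(x, ...) {
  cat("<strain_parameters>",
    if (!is.na(x$strain)) paste0(" ", x$strain), "\n",
    sep = ""
  )
  nm <- parameter_names()
  for (p in nm) cat(sprintf("  %-9s %.4g\n", p, x[[p]]))
  invisible(x)
}

#' @export
as.data.frame.strain_parameters <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x[parameter_names()]))
}

#' Names of the strain-level kinetic parameters
#'
#' @param free_only if `TRUE`, drop `mu_max` (a derived summary, see
#'   [strain_parameters()]) and return only the eight structural
#'   parameters that enter the rate laws.
#' @return Character vector of parameter names.
#' @export
parameter_names <- function(free_only = FALSE) {
  nm <- c(
    "mu_max", "K_S", "q_S_max", "q_Ap_max", "q_Ac_max",
    "q_O_max", "q_m", "Y_XS_em", "Y_OX"
  )
  if (free_only) setdiff(nm, "mu_max") else nm
}

#' Auxiliary stoichiometric and saturation constants
#'
#' Constants the growth model needs beyond the strain-level parameters:
#' overflow stoichiometry, acetate yield and affinity, oxygen affinity,
#' maintenance oxygen demand, glucose inhibition of acetate uptake and
#' the dissolved-oxygen saturation concentration. They are never fitted.
#'
#' @param Y_AS acetate-per-glucose overflow yield, g/g (at most 0.667,
#'   i.e. 2 mol acetate per mol glucose).
#' @param Y_XA biomass-on-acetate yield, g/g.
#' @param K_A acetate affinity for consumption, g/L.
#' @param K_O dissolved-oxygen affinity for oxygen-dependent rates,
#'   % air saturation.
#' @param c_Om oxygen demand per unit maintenance glucose, g O2 per g
#'   glucose.
#' @param K_IS glucose inhibition constant on acetate consumption, g/L.
#'   The large default disables the inhibition, i.e. glucose/acetate
#'   co-consumption is enabled.
#' @param C_O2_star dissolved-oxygen saturation concentration at 37 C,
#'   g/L.
#' @return An object of class `aux_constants` (a named list).
#' @export
aux_constants <- function(Y_AS = 0.667, Y_XA = 0.40, K_A = 0.05, K_O = 1.0,
                          c_Om = 1.067, K_IS = 1e6, C_O2_star = 7.2e-3) {
  vals <- c(
    Y_AS = Y_AS, Y_XA = Y_XA, K_A = K_A, K_O = K_O,
    c_Om = c_Om, K_IS = K_IS, C_O2_star = C_O2_star
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all auxiliary constants must be finite and strictly positive",
      class = "colibatch_invalid_parameters"
    )
  }
  if (Y_AS > 0.667 + 1e-12) {
    abort("Y_AS cannot exceed 0.667 g/g (2 mol acetate per mol glucose)",
      class = "colibatch_invalid_parameters"
    )
  }
  structure(as.list(vals), class = "aux_constants")
}

#' Instantaneous reactor state
#'
#' @param X biomass, g/L.
#' @param S glucose, g/L.
#' @param A acetate, g/L.
#' @param DOT dissolved oxygen tension, % air saturation.
#' @return A named list of class `reactor_state`.
#' @export
reactor_state <- function(X, S = 0, A = 0, DOT = 100) {
  vals <- c(X = X, S = S, A = A, DOT = DOT)
  if (any(!is.finite(vals))) {
    abort("reactor state components must be finite",
      class = "colibatch_invalid_state"
    )
  }
  if (any(vals < 0)) {
    abort("reactor state components must be non-negative",
      class = "colibatch_invalid_state"
    )
  }
  if (DOT > 100 + 1e-6) {
    abort("DOT cannot exceed 100 % air saturation",
      class = "colibatch_invalid_state"
    )
  }
  structure(as.list(vals), class = "reactor_state")
}

#' Published strain parameter estimates
#'
#' Point estimates and standard uncertainties for the three W3110-derived
#' PTS knockout strains (WG, WGP, WGM) characterized at initial glucose
#' concentrations of 5 and 10 g/L (mini-bioreactor) and 20 g/L
#' (stirred-tank). These serve as reference parameter sets and as ground
#' truth for the synthetic-data generator.
#'
#' @return A tibble with one row per strain x condition and columns
#'   `strain`, `glucose_gL`, `platform`, plus `<parameter>` and
#'   `<parameter>_sd` for each of the nine parameters.
#' @seealso [reference_params()]
#' @export
reference_strains <- function() {
  tribble(
    ~strain, ~glucose_gL, ~platform,
    ~mu_max, ~mu_max_sd, ~K_S, ~K_S_sd, ~q_S_max, ~q_S_max_sd,
    ~q_Ap_max, ~q_Ap_max_sd, ~q_Ac_max, ~q_Ac_max_sd,
    ~q_O_max, ~q_O_max_sd, ~q_m, ~q_m_sd,
    ~Y_XS_em, ~Y_XS_em_sd, ~Y_OX, ~Y_OX_sd,
    "WG", 5, "MBR", 0.55, 0.06, 0.010, 0.002, 1.12, 0.01,
    0.10, 0.01, 0.07, 0.005, 0.79, 0.01, 0.047, 0.002, 0.53, 0.06, 1.43, 0.01,
    "WG", 10, "MBR", 0.62, 0.09, 0.009, 0.002, 1.13, 0.01,
    0.10, 0.01, 0.07, 0.01, 0.91, 0.01, 0.056, 0.004, 0.56, 0.08, 1.49, 0.01,
    "WGP", 5, "MBR", 0.46, 0.04, 0.011, 0.002, 0.98, 0.01,
    0.05, 0.005, 0.06, 0.005, 0.67, 0.01, 0.044, 0.003, 0.49, 0.04, 1.45, 0.01,
    "WGP", 10, "MBR", 0.45, 0.04, 0.010, 0.002, 0.97, 0.01,
    0.04, 0.005, 0.06, 0.01, 0.66, 0.01, 0.047, 0.004, 0.49, 0.05, 1.47, 0.01,
    "WGM", 5, "MBR", 0.41, 0.03, 0.010, 0.002, 0.87, 0.01,
    0.13, 0.01, 0.06, 0.01, 0.62, 0.01, 0.044, 0.004, 0.50, 0.04, 1.46, 0.01,
    "WGM", 10, "MBR", 0.47, 0.05, 0.011, 0.002, 0.98, 0.01,
    0.08, 0.01, 0.07, 0.005, 0.68, 0.01, 0.044, 0.003, 0.51, 0.05, 1.45, 0.01,
    "WG", 20, "STR", 0.44, 0.03, 0.010, 0.002, 1.03, 0.01,
    0.06, 0.01, 0.08, 0.005, 0.55, 0.01, 0.044, 0.002, 0.45, 0.03, 1.25, 0.01,
    "WGP", 20, "STR", 0.36, 0.02, 0.010, 0.002, 0.98, 0.01,
    0.06, 0.01, 0.0708, 0.005, 0.41, 0.01, 0.044, 0.003, 0.39, 0.02, 1.24, 0.01
  )
}

#' Look up one reference parameter set
#'
#' @param strain one of `"WG"`, `"WGP"`, `"WGM"`.
#' @param glucose_gL initial glucose concentration of the condition,
#'   g/L (5, 10 or 20).
#' @return A [strain_parameters()] object carrying the published point
#'   estimates for that strain x condition.
#' @examples
#' reference_params("WG", 10)$q_S_max
#' @export
reference_params <- function(strain, glucose_gL) {
  tab <- reference_strains()
  row <- tab[tab$strain == strain & tab$glucose_gL == glucose_gL, ]
  if (nrow(row) != 1) {
    abort(
      sprintf("no reference parameter set for %s at %g g/L", strain, glucose_gL),
      class = "colibatch_config_error"
    )
  }
  strain_parameters(
    q_S_max = row$q_S_max, q_Ap_max = row$q_Ap_max, q_Ac_max = row$q_Ac_max,
    q_O_max = row$q_O_max, q_m = row$q_m, Y_XS_em = row$Y_XS_em,
    Y_OX = row$Y_OX, K_S = row$K_S, mu_max = row$mu_max,
    strain = sprintf("%s (%g)", strain, glucose_gL)
  )
}
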