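# Macro-kinetic rate laws: glucose partitioning, overflow metabolism and
# acetate recycling, with maintenance and a respiratory capacity cap.

# Vectorized core; X,S,A,DOT numeric vectors of equal length.
# Returns a list of numeric vectors. No validation: hot path of the ODE rhs.
.rates <- function(X, S, A, DOT, p, a) {
  S <- pmax(S, 0)
  A <- pmax(A, 0)
  DOT <- pmax(DOT, 0)

  monod <- ifelse(S > 0, S / (S + p$K_S), 0)
  q_S <- p$q_S_max * monod
  q_Ap <- p$q_Ap_max * monod
  q_Ac <- ifelse(
    A > 0,
    p$q_Ac_max * (A / (A + a$K_A)) * (a$K_IS / (a$K_IS + S)) *
      (DOT / (DOT + a$K_O)),
    0
  )
  # maintenance draws on glucose: inactive once glucose is exhausted.
  # Shut off smoothly over a negligible glucose scale (1e-4 g/L) so the
  # derivative field stays continuous through depletion.
  q_m <- p$q_m * S / (S + 1e-4)

  # potential growth: glucose flux net of maintenance and of the glucose
  # diverted into acetate (q_Ap/Y_AS), plus growth on recycled acetate
  mu_pot <- pmax((q_S - q_m - q_Ap / a$Y_AS) * p$Y_XS_em + q_Ac * a$Y_XA, 0)

  # oxygen demand, attenuated by dissolved-oxygen availability
  q_O_dem <- (p$Y_OX * mu_pot + a$c_Om * q_m) * (DOT / (DOT + a$K_O))

  over <- q_O_dem > p$q_O_max
  q_O <- ifelse(over, p$q_O_max, q_O_dem)
  mu <- ifelse(over, pmax((p$q_O_max - a$c_Om * q_m) / p$Y_OX, 0), mu_pot)
  # respiration-limited growth shortfall spills into extra acetate
  q_Ap <- q_Ap + ifelse(over, a$Y_AS * (mu_pot - mu) / p$Y_XS_em, 0)

  list(q_S = q_S, q_Ap = q_Ap, q_Ac = q_Ac, q_O = q_O, mu = mu)
}

#' Specific reaction rates at a reactor state
#'
#' Evaluates the macro-kinetic rate laws: Monod glucose uptake, glucose-
#' saturation-driven overflow acetate production, acetate consumption
#' (inhibited by glucose via `K_IS`, enabled for co-consumption by
#' default, and dependent on dissolved oxygen), maintenance, the
#' resulting potential growth rate, and the oxygen demand capped at the
#' strain's respiratory capacity `q_O_max`. When the cap binds, the
#' unrealized growth is re-routed into additional acetate overflow.
#'
#' @param state a [reactor_state()], or any data frame / named list with
#'   numeric components `X`, `S`, `A`, `DOT` (vectors allowed, recycled
#'   to a common length).
#' @param params a [strain_parameters()] object.
#' @param aux an [aux_constants()] object.
#' @return A tibble with columns `q_S`, `q_Ap`, `q_Ac`, `q_O` (g/(g h))
#'   and `mu` (1/h), one row per state.
#' @examples
#' p <- reference_params("WG", 10)
#' specific_rates(list(X = 1, S = 5, A = 0, DOT = 100), p)
#' @export
specific_rates <- function(state, params, aux = aux_constants()) {
  st <- lapply(state[c("X", "S", "A", "DOT")], as.numeric)
  if (any(vapply(st, is.null, logical(1)))) {
    abort("state must provide X, S, A and DOT", class = "colibatch_invalid_state")
  }
  n <- max(lengths(st))
  st <- lapply(st, rep_len, length.out = n)
  if (any(!vapply(st, function(v) all(is.finite(v)), logical(1)))) {
    abort("state components must be finite", class = "colibatch_invalid_state")
  }
  as_tibble(.rates(st$X, st$S, st$A, st$DOT, params, aux))
}

#' Time derivatives of the reactor state
#'
#' Mass balances of the batch reactor: growth, glucose depletion, net
#' acetate accumulation, and the dissolved-oxygen balance between kLa
#' transfer and biological uptake.
#'
#' @param t time, h (used to resolve the platform kLa schedule).
#' @param state as in [specific_rates()].
#' @param params a [strain_parameters()] object.
#' @param aux an [aux_constants()] object.
#' @param platform a [platform_config()] supplying the kLa schedule; a
#'   single positive number is accepted as a constant kLa (1/h).
#' @return A tibble with columns `dX`, `dS`, `dA` (g/(L h)) and `dDOT`
#'   (%/h).
#' @export
state_derivatives <- function(t, state, params, aux = aux_constants(),
                              platform = NULL) {
  kla <- if (is.numeric(platform)) {
    rep_len(platform, length(t))
  } else if (inherits(platform, "platform_config")) {
    schedule_value(platform$kLa, t)
  } else {
    abort("platform must be a platform_config or a constant kLa",
      class = "colibatch_config_error"
    )
  }
  if (any(!is.finite(kla)) || any(kla <= 0)) {
    abort("kLa must be strictly positive", class = "colibatch_config_error")
  }
  r <- specific_rates(state, params, aux)
  X <- rep_len(as.numeric(state$X), nrow(r))
  DOT <- rep_len(as.numeric(state$DOT), nrow(r))
  tibble(
    dX = r$mu * X,
    dS = -r$q_S * X,
    dA = (r$q_Ap - r$q_Ac) * X,
    dDOT = kla * (100 - DOT) - r$q_O * X * (100 / aux$C_O2_star)
  )
}
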