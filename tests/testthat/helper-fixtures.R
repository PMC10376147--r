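# Shared fixtures: parameter sets and small platform configurations
# used across the test files. Everything is generated in code.

wg10 <- function() reference_params("WG", 10)
wg20 <- function() reference_params("WG", 20)

# a fast-running MBR-like configuration for unit tests
mini_mbr <- function(...) platform_preset("MBR", S0 = 10, ...)

# minimal clean batch: no maintenance, no acetate, no oxygen limitation
clean_params <- function(Y = 0.5) {
  strain_parameters(
    q_S_max = 1.0, q_Ap_max = 1e-9, q_Ac_max = 1e-9, q_O_max = 50,
    q_m = 1e-9, Y_XS_em = Y, Y_OX = 1.4, K_S = 0.01
  )
}

# an off-gas record used in several balance tests
example_offgas <- function() {
  tibble::tibble(
    t_h = 1, F_in_Lh = 6, V_L = 0.09,
    xO2_in = 0.2095, xCO2_in = 0.0004,
    xO2_out = 0.19, xCO2_out = 0.02
  )
}
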