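## Preset Boltzmann parameters (pH_i = pH_o = 6.0) and pH-coupling
## coefficients for the two fungal channels, a human-like reference, and the
## SlHv1/AoHv1 chimera series. tau_half is the relaxation time constant at
## V_1/2 (ms) used to set the scheme's rate prefactors.
.hv_preset_table <- list(
  SlHv1   = list(V_half = 46.5,  s = 7.6,  c_dpH = -85, c_sym = 19, tau_half = 600),
  AoHv1   = list(V_half = -13.9, s = 7.4,  c_dpH = -90, c_sym = 0,  tau_half = 100),
  hHv1    = list(V_half = 53.0,  s = 11.6, c_dpH = -40, c_sym = 0,  tau_half = 700),
  `ChL1-2`  = list(V_half = 11.4, s = 11.0, c_dpH = -85, c_sym = 19, tau_half = 100),
  `ChL1-2a` = list(V_half = 45.5, s = 7.8,  c_dpH = -85, c_sym = 19, tau_half = 150),
  `ChL1-2b` = list(V_half = 17.6, s = 10.3, c_dpH = -85, c_sym = 19, tau_half = 100),
  `ChL2-3`  = list(V_half = 90.0, s = 15.3, c_dpH = -85, c_sym = 0,  tau_half = 600),
  `ChL3-4`  = list(V_half = 33.1, s = 9.4,  c_dpH = -85, c_sym = 19, tau_half = 600),
  ChCT1   = list(V_half = 64.9, s = 17.1, c_dpH = -85, c_sym = 19, tau_half = 150),
  ChCT2   = list(V_half = 41.5, s = 7.0,  c_dpH = -85, c_sym = 19, tau_half = 600),
  ChCT3   = list(V_half = 50.5, s = 8.2,  c_dpH = -85, c_sym = 19, tau_half = 600),
  `ChL1-2b+L3-4` = list(V_half = 12.7, s = 13.9, c_dpH = -85, c_sym = 19, tau_half = 150),
  ## Sequential-scheme fixture: SlHv1-like voltage dependence carried by a
  ## three-state scheme with total gating charge 5 e0, for limiting-slope work.
  SlHv1_seq = list(V_half = 46.5, s = 7.6, c_dpH = -85, c_sym = 19, tau_half = 2,
                   n_states = 3, z_step = c(2.5, 2.5))
)

#' Available channel presets
#'
#' @return character vector of preset names accepted by [hv_preset()].
#' @export
hv_preset_names <- function() names(.hv_preset_table)

#' Channel model presets
#'
#' Ready-made [hv_model()] objects for SlHv1 and AoHv1 (fungal Hv channels
#' from *Suillus luteus* and *Aspergillus oryzae*), a human-Hv1-like
#' reference, the SlHv1/AoHv1 chimera series (ChL1-2, ChL1-2a, ChL1-2b,
#' ChL2-3, ChL3-4, ChCT1, ChCT2, ChCT3, ChL1-2b+L3-4), and `SlHv1_seq`, a
#' three-state sequential fixture with total gating charge 5 e0 for
#' limiting-slope analysis. Boltzmann parameters are at the reference
#' condition pH_i = pH_o = 6.0; the fungal presets carry a strong
#' pH-gradient coupling (85-90 mV per dpH unit) and SlHv1-background presets
#' a 19 mV/pH symmetric-pH dependence, while the human-like preset follows
#' the canonical 40 mV/dpH rule.
#'
#' @param name preset name, see [hv_preset_names()].
#' @param n_states override the scheme's state count (default 2, or the
#'   preset's own).
#' @param g_max maximal conductance (nS).
#' @param c_dpH_sign,c_sym_sign +1 or -1, flips the sign of the pH-coupling
#'   coefficients (their direction is a convention of the preset).
#' @return an [hv_model()].
#' @examples
#' m <- hv_preset("SlHv1")
#' steady_state_po(50, m)   # 0.613 at the reference voltage
#' @export
hv_preset <- function(name, n_states = NULL, g_max = 10,
                      c_dpH_sign = 1, c_sym_sign = 1) {
  if (!name %in% names(.hv_preset_table))
    stop("unknown preset '", name, "'; see hv_preset_names()")
  p <- .hv_preset_table[[name]]
  ns <- if (!is.null(n_states)) n_states else if (!is.null(p$n_states)) p$n_states else 2
  kT <- thermal_voltage(297)
  if (!is.null(p$z_step) && is.null(n_states)) {
    z <- p$z_step
  } else if (ns == 2) {
    z <- kT / p$s
  } else {
    ## multi-state G-V curves are shallower than their total-charge Boltzmann,
    ## so spread a modestly larger total charge evenly over the transitions
    z <- rep(1.3 * kT / p$s / (ns - 1), ns - 1)
  }
  ## rate prefactor from the target relaxation time at V_1/2: for a two-state
  ## scheme at V = Vm, alpha = beta = rate0 so tau = 1/(2 rate0); used as a
  ## kinetic scale for longer schemes too.
  rate0 <- 1 / (2 * p$tau_half)
  scheme <- hv_scheme(ns, z_step = z, rate0 = rate0)
  hv_model(scheme = scheme, g_max = g_max, V_half_ref = p$V_half, s = p$s,
           c_dpH = c_dpH_sign * p$c_dpH, c_sym = c_sym_sign * p$c_sym,
           label = name)
}
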