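## Physical constants (CODATA), SI units
.R_GAS <- 8.31446261815324    # J K^-1 mol^-1
.FARADAY <- 96485.33212       # C mol^-1
.KB <- 1.380649e-23           # J K^-1
.E0 <- 1.602176634e-19        # C

#' Thermal voltage in millivolts
#'
#' Returns \eqn{k_B T / e_0} (equivalently \eqn{RT/F}) in mV at absolute
#' temperature `T`. This constant links the Boltzmann slope factor `s` (mV)
#' of a two-state channel to its gating charge: \eqn{z = k_B T/(e_0 s)}.
#'
#' @param T absolute temperature (K).
#' @return thermal voltage (mV).
#' @export
thermal_voltage <- function(T) {
  if (!is.numeric(T) || any(T <= 0)) stop("T must be a positive temperature in kelvin")
  1000 * .KB * T / .E0
}

#' Nernst slope for a ten-fold concentration gradient
#'
#' \eqn{\ln(10)\,RT/F} in mV: the equilibrium-potential change per unit pH.
#' At 297 K this evaluates to 58.9 mV/pH.
#'
#' @param T absolute temperature (K).
#' @return slope (mV per pH unit), positive.
#' @export
nernst_slope <- function(T) log(10) * thermal_voltage(T)

#' Nernst equilibrium potential for protons
#'
#' Proton equilibrium potential for a transmembrane pH gradient
#' \eqn{\Delta pH = pH_o - pH_i}:
#' \deqn{E_H = -\ln(10)\frac{RT}{F}(pH_o - pH_i)}
#' For a perfectly proton-selective channel the current reversal potential
#' equals \eqn{E_H}; at 297 K, \eqn{E_H = -58.9\,\Delta pH} mV.
#'
#' @param pH_i,pH_o intracellular and extracellular pH.
#' @param T absolute temperature (K), default 297.
#' @return potential in mV.
#' @examples
#' nernst_potential(6.0, 7.0)   # about -58.9 mV
#' @export
nernst_potential <- function(pH_i, pH_o, T = 297) {
  stopifnot(is.numeric(pH_i), is.numeric(pH_o))
  if (any(pH_i <= 0 | pH_i >= 14) || any(pH_o <= 0 | pH_o >= 14))
    stop("pH values must lie in (0, 14)")
  -nernst_slope(T) * (pH_o - pH_i)
}

#' Recording solutions
#'
#' Intracellular/extracellular pH and temperature of a patch-clamp
#' experiment. The transmembrane pH gradient is `dpH = pH_o - pH_i`.
#'
#' @param pH_i,pH_o intracellular and extracellular pH, in (0, 14).
#' @param T absolute temperature (K); default 297 K so the Nernst slope is
#'   the conventional 58.9 mV/pH reference.
#' @return an object of class `hv_solutions`.
#' @export
hv_solutions <- function(pH_i = 6.0, pH_o = 6.0, T = 297) {
  if (!is.numeric(T) || length(T) != 1 || T <= 0) stop("T must be a positive scalar (kelvin)")
  if (pH_i <= 0 || pH_i >= 14 || pH_o <= 0 || pH_o >= 14) stop("pH values must lie in (0, 14)")
  structure(list(pH_i = pH_i, pH_o = pH_o, T = T,
                 dpH = pH_o - pH_i),
            class = "hv_solutions")
}

#' @export
print.hv_solutions <- function(x, ...) {
  cat(sprintf("solutions: pH_i = %.2f, pH_o = %.2f (dpH = %+.2f), T = %.1f K, E_H = %.1f mV\n",
              x$pH_i, x$pH_o, x$dpH, x$T, nernst_potential(x$pH_i, x$pH_o, x$T)))
  invisible(x)
}
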