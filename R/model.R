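#' Linear gating scheme
#'
#' A sequential kinetic scheme C\\_{n-1} <-> ... <-> C\\_1 <-> O with `n_states`
#' states. Transition `i` carries gating charge `z_step[i]` (elementary
#' charges) and has a voltage-independent rate prefactor `rate0[i]` (1/ms).
#' Forward and backward rates share the prefactor and split the charge
#' symmetrically, so the transition equilibrium constant is
#' \eqn{K_i(V) = \exp(z_i (V - V_m)/(k_B T/e_0))}. The sum of `z_step` is the
#' total gating charge that the limiting-slope estimator should recover.
#'
#' @param n_states number of states (>= 2); the last state is open.
#' @param z_step per-transition gating charges (length `n_states - 1`),
#'   recycled from a scalar.
#' @param rate0 per-transition rate prefactors (1/ms), recycled.
#' @return an object of class `hv_scheme`.
#' @export
hv_scheme <- function(n_states = 2, z_step = 3.37, rate0 = 0.5) {
  if (n_states < 2) stop("n_states must be >= 2")
  z_step <- rep_len(z_step, n_states - 1)
  rate0 <- rep_len(rate0, n_states - 1)
  if (any(z_step < 0)) stop("z_step must be non-negative")
  if (any(!is.finite(rate0)) || any(rate0 <= 0)) stop("rate0 must be positive and finite")
  structure(list(n_states = n_states, z_step = z_step, rate0 = rate0),
            class = "hv_scheme")
}

#' Parametric Hv channel model
#'
#' The generative truth used by the simulator. Macroscopic voltage dependence
#' is summarized by the Boltzmann pair (`V_half_ref`, `s`) at the reference
#' condition pH_i = pH_o = 6.0; pH coupling is phenomenological and linear:
#' \deqn{V_{1/2}(pH_i, pH_o) = V_{1/2}^{ref} + c_{sym}(pH_i - 6) + c_{dpH}(pH_o - pH_i)}
#' Kinetics and activation lag come from the linear scheme in `scheme`; a
#' scheme with more than two states produces the sigmoidal delay seen in real
#' activation time courses and multi-exponential deactivation tails.
#'
#' @param scheme an [hv_scheme()]. For a two-state scheme the single gating
#'   charge is tied to the slope factor by \eqn{z = k_B T_{ref}/(e_0 s)}
#'   (with `T_ref` = 297 K) unless an explicit `z_step` was supplied.
#' @param g_max maximal macroscopic conductance (nS).
#' @param V_half_ref half-activation voltage at pH_i = pH_o = 6.0 (mV).
#' @param s Boltzmann slope factor (mV), positive for channels activated by
#'   depolarization.
#' @param c_dpH V_1/2 shift per unit of dpH = pH_o - pH_i (mV/pH, signed).
#' @param c_sym V_1/2 shift per unit of symmetric pH change (mV/pH, signed).
#' @param label free-text channel tag.
#' @return an object of class `hv_model`.
#' @export
hv_model <- function(scheme = NULL, g_max = 10, V_half_ref = 46.5, s = 7.6,
                     c_dpH = -85, c_sym = 19, label = "custom") {
  if (!is.numeric(s) || s == 0) stop("slope factor s must be non-zero")
  if (g_max <= 0) stop("g_max must be positive")
  if (is.null(scheme)) scheme <- hv_scheme(2, z_step = thermal_voltage(297) / abs(s))
  stopifnot(inherits(scheme, "hv_scheme"))
  structure(list(scheme = scheme, g_max = g_max, V_half_ref = V_half_ref,
                 s = s, c_dpH = c_dpH, c_sym = c_sym, label = label),
            class = "hv_model")
}

#' @export
print.hv_model <- function(x, ...) {
  cat(sprintf("hv_model '%s': V_1/2(ref) = %.1f mV, s = %.1f mV, g_max = %.1f nS\n",
              x$label, x$V_half_ref, x$s, x$g_max))
  cat(sprintf("  pH coupling: c_dpH = %+.1f, c_sym = %+.1f mV/pH; scheme: %d states, z_tot = %.2f e0\n",
              x$c_dpH, x$c_sym, x$scheme$n_states, sum(x$scheme$z_step)))
  invisible(x)
}

#' Effective half-activation voltage under given solutions
#'
#' Applies the model's linear pH coupling to its reference V_1/2:
#' symmetric-pH term `c_sym * (pH_i - 6)` plus gradient term `c_dpH * dpH`.
#'
#' @param model an [hv_model()].
#' @param solutions an [hv_solutions()].
#' @return V_1/2 in mV.
#' @export
effective_v_half <- function(model, solutions) {
  stopifnot(inherits(model, "hv_model"), inherits(solutions, "hv_solutions"))
  model$V_half_ref + model$c_sym * (solutions$pH_i - 6.0) + model$c_dpH * solutions$dpH
}

## Common per-transition midpoint voltage that places the scheme's
## half-activation at `v_half`. Exact for two states; solved numerically
## otherwise (P_O is monotone in the midpoint).
.scheme_vm <- function(scheme, v_half, kT) {
  if (scheme$n_states == 2) return(v_half)
  f <- function(vm) .scheme_po(scheme, v_half, vm, kT) - 0.5
  stats::uniroot(f, lower = v_half - 1000, upper = v_half + 1000, tol = 1e-10)$root
}

## Equilibrium open probability of the linear scheme from its partition
## weights w_1 = 1, w_{i+1} = w_i K_i(V).
.scheme_po <- function(scheme, V, vm, kT) {
  logK <- scheme$z_step * (V - vm) / kT
  logw <- c(0, cumsum(logK))
  logw <- logw - max(logw)          # overflow guard
  w <- exp(logw)
  w[length(w)] / sum(w)
}

#' Steady-state open probability
#'
#' For a two-state model this is the Boltzmann function
#' \eqn{P_O(V) = 1/(1 + \exp((V_{1/2} - V)/s))} with the effective
#' \eqn{V_{1/2}} for the given solutions. For longer schemes it is the
#' equilibrium occupancy of the open state computed from the per-transition
#' equilibrium constants, with the common transition midpoint solved so that
#' half-activation falls exactly at [effective_v_half()].
#'
#' @param V membrane voltage (mV), vectorized.
#' @param model an [hv_model()].
#' @param solutions an [hv_solutions()]; default reference condition.
#' @return open probability in (0, 1).
#' @export
steady_state_po <- function(V, model, solutions = hv_solutions()) {
  stopifnot(inherits(model, "hv_model"))
  vh <- effective_v_half(model, solutions)
  if (model$scheme$n_states == 2) {
    return(1 / (1 + exp((vh - V) / model$s)))
  }
  kT <- thermal_voltage(solutions$T)
  vm <- .scheme_vm(model$scheme, vh, kT)
  vapply(V, function(v) .scheme_po(model$scheme, v, vm, kT), numeric(1))
}

#' Evaluate the Boltzmann activation function
#'
#' \deqn{G/G_{max} = 1/(1 + \exp((V_{1/2} - V)/s))}
#'
#' @param V voltage (mV), vectorized.
#' @param V_half half-activation voltage (mV).
#' @param s slope factor (mV), non-zero; positive for depolarization-activated
#'   channels.
#' @return normalized conductance.
#' @examples
#' eval_boltzmann(50, 46.5, 7.6)    # 0.613
#' eval_boltzmann(-10, -13.9, 7.4)  # 0.629
#' @export
eval_boltzmann <- function(V, V_half, s) {
  if (!is.numeric(s) || any(s == 0)) stop("slope factor s must be non-zero")
  1 / (1 + exp((V_half - V) / s))
}

#' Channel blocker model
#'
#' Two pharmacological mechanisms are supported. Open-channel blockers
#' (guanidinobenzimidazole derivatives such as 2GBI/ClGBI on Hv channels)
#' occlude the conducting channel: at concentration `conc` the available
#' conductance scales by \eqn{1/(1 + conc/K_d)} and gating kinetics are
#' untouched. Closed-state stabilizers (extracellular Zn2+ on animal Hvs)
#' make opening harder: V_1/2 shifts depolarized by
#' \eqn{\Delta V_{1/2}\, conc/(conc + K_d)} and activation slows by
#' `slow_factor`, while open-channel conductance is unchanged.
#'
#' @param mode `"open-channel"` or `"closed-state"`.
#' @param conc blocker concentration (uM), >= 0.
#' @param Kd apparent dissociation constant (uM), > 0.
#' @param dV_half V_1/2 shift at saturating block, closed-state mode (mV, > 0
#'   shifts depolarized).
#' @param slow_factor multiplicative slowing of activation at `conc`,
#'   closed-state mode (>= 1).
#' @return an object of class `hv_blocker`.
#' @export
hv_blocker <- function(mode = c("open-channel", "closed-state"), conc, Kd,
                       dV_half = 0, slow_factor = 1) {
  mode <- match.arg(mode)
  if (conc < 0) stop("blocker concentration must be non-negative")
  if (Kd <= 0) stop("Kd must be positive")
  if (slow_factor < 1) stop("slow_factor must be >= 1")
  structure(list(mode = mode, conc = conc, Kd = Kd, dV_half = dV_half,
                 slow_factor = slow_factor),
            class = "hv_blocker")
}

#' Apply a blocker to a channel model
#'
#' Returns a modified copy of the model implementing the blocker's
#' equilibrium effect (see [hv_blocker()]). With `conc = 0` the model is
#' returned unchanged.
#'
#' @param model an [hv_model()].
#' @param blocker an [hv_blocker()].
#' @return an [hv_model()].
#' @export
apply_blocker <- function(model, blocker) {
  stopifnot(inherits(model, "hv_model"), inherits(blocker, "hv_blocker"))
  if (blocker$conc == 0) return(model)
  out <- model
  if (blocker$mode == "open-channel") {
    out$g_max <- model$g_max / (1 + blocker$conc / blocker$Kd)
  } else {
    occ <- blocker$conc / (blocker$conc + blocker$Kd)
    out$V_half_ref <- model$V_half_ref + abs(blocker$dV_half) * occ
    out$scheme$rate0 <- model$scheme$rate0 / blocker$slow_factor
  }
  out$label <- paste0(model$label, " + ", blocker$mode, " block ", blocker$conc, " uM")
  out
}
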