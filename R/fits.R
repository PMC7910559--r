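#' Single-exponential fit of an activation time course
#'
#' Hv activation shows an initial sigmoidal lag followed by an exponential
#' rise; the lag is short relative to \eqn{\tau_{on}} and is excluded from
#' the fit. The fit start `t0` is the first time the current crosses
#' `lag_fraction` (default 10 percent) of its steady rise above baseline;
#' \eqn{I(t) = a \exp(-(t - t_0)/\tau_{on}) + c} is then fitted on
#' `[t0, end]` by nonlinear least squares.
#'
#' @param trace numeric current vector (pA) for the depolarizing epoch.
#' @param dt sampling interval (ms).
#' @param lag_fraction fraction of the steady rise defining the fit start.
#' @param blank_ms capacitive blanking window at the epoch start (ms).
#' @return an `hv_expfit`: list with `a`, `tau_on` (ms), `c`, `t0` (ms),
#'   standard errors in `se`.
#' @export
fit_activation <- function(trace, dt, lag_fraction = 0.1, blank_ms = 0.5) {
  n <- length(trace)
  t <- (seq_len(n) - 1) * dt
  keep <- t >= blank_ms - 1e-9
  t <- t[keep]; y <- trace[keep]
  if (length(y) < 6) stop("trace too short to fit")
  i_ss <- mean(y[t >= max(t) - max(5, 5 * dt) + 1e-9])
  i0 <- y[1]
  rise <- i_ss - i0
  noise_sd <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(rise) || abs(rise) <= 5 * max(noise_sd, 1e-12))
    stop("no rise detected in trace")
  thr <- i0 + lag_fraction * rise
  cross <- if (rise > 0) which(y >= thr) else which(y <= thr)
  if (!length(cross)) stop("no rise detected in trace")
  t0 <- t[cross[1]]
  tw <- t[t >= t0] - t0
  yw <- y[t >= t0]
  tau0 <- max(tw[which.min(abs((yw - i0) / rise - 0.63))], dt)
  fit <- tryCatch(
    minpack.lm::nlsLM(yw ~ a * exp(-tw / tau) + c0,
                      start = list(a = yw[1] - i_ss, tau = tau0, c0 = i_ss),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("activation fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["tau"]] <= 0) stop("activation fit returned non-positive tau")
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(a = unname(cf[["a"]]), tau_on = unname(cf[["tau"]]),
                 c = unname(cf[["c0"]]), t0 = t0,
                 se = c(a = se[[1]], tau_on = se[[2]], c = se[[3]]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "hv_expfit")
}

#' @export
print.hv_expfit <- function(x, ...) {
  cat(sprintf("exponential fit: tau_on = %.3g ms (t0 = %.3g ms, a = %.3g, c = %.3g)\n",
              x$tau_on, x$t0, x$a, x$c))
  invisible(x)
}

#' Derive a conductance-voltage curve from an I-V relation
#'
#' For steady or ramp I-V data the chord conductance is
#' \eqn{G(V) = I(V)/(V - V_{rev})}; points with \eqn{|V - V_{rev}|} below
#' `exclusion_mV` are masked (the quotient is numerically unstable near the
#' reversal potential). For instantaneous tail I-V data, measured at a fixed
#' tail voltage, the tail amplitude is itself proportional to the
#' conductance at the end of the prepulse, so G is the amplitude as-is.
#' Conductances are normalized by the maximum retained G. Because Hv
#' channels are strongly proton selective, `V_rev` defaults to the Nernst
#' potential when known.
#'
#' @param iv an [hv_iv()].
#' @param V_rev reversal potential (mV).
#' @param exclusion_mV half-width of the masked band around `V_rev`.
#' @return an `hv_gv` data.frame with `voltage`, `G` (nS for steady IVs),
#'   `G_norm`, and logical `masked`; `V_rev` and the kind in attributes.
#' @export
derive_gv <- function(iv, V_rev = 0, exclusion_mV = 5) {
  stopifnot(inherits(iv, "hv_iv"))
  kind <- attr(iv, "kind")
  if (kind == "instantaneous-tail") {
    G <- iv$current
    masked <- rep(FALSE, length(G))
  } else {
    masked <- abs(iv$voltage - V_rev) < exclusion_mV
    G <- ifelse(masked, NA_real_, iv$current / (iv$voltage - V_rev))
  }
  if (all(masked)) stop("all points fall within the exclusion band around V_rev")
  gmax <- max(abs(G[!masked]))
  if (gmax == 0) stop("all conductances are zero")
  sgn <- sign(G[!masked][which.max(abs(G[!masked]))])
  structure(data.frame(voltage = iv$voltage, G = G, G_norm = sgn * G / gmax,
                       masked = masked),
            V_rev = V_rev, kind = kind, class = c("hv_gv", "data.frame"))
}

#' Fit the Boltzmann activation function to a G-V curve
#'
#' Nonlinear least squares of \eqn{G/G_{max} = G_{max}'/(1+\exp((V_{1/2}-V)/s))}
#' over the unmasked points, initialized from the half-maximum crossing and
#' the 10-90 percent rise width. Data that decrease monotonically with
#' voltage are rejected rather than silently fitted with a negative slope.
#'
#' @param gv an `hv_gv` from [derive_gv()], or a data.frame with columns
#'   `voltage` and `G_norm`.
#' @param init optional named list with starting values `V_half`, `s`,
#'   `G_max`.
#' @return an `hv_boltzmann`: list with `V_half` (mV), `s` (mV), `G_max`,
#'   per-parameter `se`, and `residual_norm`.
#' @export
fit_boltzmann <- function(gv, init = NULL) {
  V <- gv$voltage
  G <- if ("G_norm" %in% names(gv)) gv$G_norm else gv$G
  if ("masked" %in% names(gv)) {
    V <- V[!gv$masked]; G <- G[!gv$masked]
  }
  ok <- is.finite(V) & is.finite(G)
  V <- V[ok]; G <- G[ok]
  if (length(V) < 4) stop("need at least 4 points spanning the rising phase")
  if (stats::cor(V, G) < 0)
    stop("conductance decreases with voltage; not an activation curve (check sign conventions)")
  if (is.null(init)) {
    gmax0 <- max(G)
    vh0 <- stats::approx(G / gmax0, V, xout = 0.5, ties = mean)$y
    if (is.na(vh0)) vh0 <- V[which.min(abs(G / gmax0 - 0.5))]
    v10 <- stats::approx(G / gmax0, V, xout = 0.1, ties = mean)$y
    v90 <- stats::approx(G / gmax0, V, xout = 0.9, ties = mean)$y
    s0 <- if (!is.na(v10) && !is.na(v90) && v90 > v10) (v90 - v10) / (2 * log(9)) else
      diff(range(V)) / 10
    init <- list(V_half = vh0, s = max(s0, 0.5), G_max = gmax0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ gmax / (1 + exp((vh - V) / s)),
                      start = list(vh = init$V_half, s = init$s, gmax = init$G_max),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("Boltzmann fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(V_half = unname(cf[["vh"]]), s = unname(cf[["s"]]),
                 G_max = unname(cf[["gmax"]]),
                 se = c(V_half = se[[1]], s = se[[2]], G_max = se[[3]]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 n = length(V)),
            class = "hv_boltzmann")
}

#' @export
print.hv_boltzmann <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V_1/2 = %.2f +/- %.2f mV, s = %.2f +/- %.2f mV, G_max = %.3g (n = %d)\n",
              x$V_half, x$se[["V_half"]], x$s, x$se[["s"]], x$G_max, x$n))
  invisible(x)
}

#' Reversal potential from instantaneous tail currents
#'
#' Linear interpolation between the pair of tail measurements bracketing the
#' sign change; with more than two points, an ordinary least-squares line
#' through the points nearest the crossing (up to two on each side) is used.
#'
#' @param tail_iv an [hv_iv()] of instantaneous tail currents at two or more
#'   voltages bracketing the reversal.
#' @return `V_rev` (mV).
#' @export
estimate_reversal <- function(tail_iv) {
  ord <- order(tail_iv$voltage)
  V <- tail_iv$voltage[ord]
  I <- tail_iv$current[ord]
  if (all(I >= 0) || all(I <= 0)) {
    if (any(I == 0)) return(V[which(I == 0)[1]])
    stop("tail currents do not change sign; cannot bracket V_rev")
  }
  i <- which(diff(sign(I)) != 0)[1]
  if (length(V) == 2) {
    return(V[1] - I[1] * (V[2] - V[1]) / (I[2] - I[1]))
  }
  win <- max(1, i - 1):min(length(V), i + 2)
  fit <- stats::lm(I[win] ~ V[win])
  -unname(stats::coef(fit)[1] / stats::coef(fit)[2])
}

#' Proton selectivity from reversal potentials across pH gradients
#'
#' Ordinary least squares of `V_rev` against the transmembrane pH gradient.
#' For a perfectly proton-selective channel the slope equals
#' \eqn{-\ln(10)RT/F} (-58.9 mV/pH at 297 K); the deviation from that
#' reference is reported.
#'
#' @param vrev_by_dpH data.frame with columns `dpH` and `V_rev` (mV); at
#'   least 3 distinct gradients.
#' @param T absolute temperature (K) for the reference slope.
#' @return list with `slope`, `intercept`, their `se`, `reference_slope`,
#'   `deviation`, and the per-gradient mean `V_rev` table.
#' @export
selectivity_fit <- function(vrev_by_dpH, T = 297) {
  stopifnot(all(c("dpH", "V_rev") %in% names(vrev_by_dpH)))
  if (length(unique(vrev_by_dpH$dpH)) < 3)
    stop("need reversal potentials at >= 3 distinct pH gradients")
  fit <- stats::lm(V_rev ~ dpH, data = vrev_by_dpH)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))  # zero-residual data is legitimate here
  means <- stats::aggregate(V_rev ~ dpH, data = vrev_by_dpH, FUN = mean)
  ref <- -nernst_slope(T)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       se = c(intercept = se[[1]], slope = se[[2]]),
       reference_slope = ref, deviation = unname(cf[2]) - ref,
       mean_vrev = means)
}

#' Shifts of the activation curve with the pH gradient
#'
#' Compares Boltzmann fits obtained under different transmembrane pH
#' gradients: for every condition pair the V_1/2 shift per unit change in
#' gradient is computed, together with each condition's activation threshold
#' voltage (where the normalized conductance first exceeds `threshold`) and
#' the threshold shift expected from the canonical animal-Hv rule of 40 mV
#' of hyperpolarization per unit of gradient increase.
#'
#' @param fits a list of `hv_boltzmann` fits.
#' @param dpH numeric vector of the pH gradient of each fit.
#' @param threshold normalized-conductance level defining V_threshold.
#' @return list with `pairwise` (data.frame of shifts per pH unit),
#'   `V_threshold` per condition, and `expected_animal_shift` per pair.
#' @export
dpH_shift_analysis <- function(fits, dpH, threshold = 0.02) {
  if (length(fits) != length(dpH)) stop("one dpH value per fit required")
  if (length(fits) < 2) stop("need fits for >= 2 pH-gradient conditions")
  vh <- vapply(fits, function(f) f$V_half, numeric(1))
  s <- vapply(fits, function(f) f$s, numeric(1))
  ## V where G/Gmax = threshold: V = V_half - s ln(1/threshold - 1)
  v_thr <- vh - s * log(1 / threshold - 1)
  pairs <- utils::combn(length(fits), 2)
  dd <- dpH[pairs[2, ]] - dpH[pairs[1, ]]
  if (any(dd == 0)) stop("conditions with identical dpH cannot define a shift")
  data.frame0 <- data.frame(
    cond_a = pairs[1, ], cond_b = pairs[2, ], ddpH = dd,
    dV_half = vh[pairs[2, ]] - vh[pairs[1, ]],
    shift_per_pH = (vh[pairs[2, ]] - vh[pairs[1, ]]) / dd,
    expected_animal_dV_thr = -40 * dd)
  list(pairwise = data.frame0, V_threshold = v_thr,
       threshold = threshold)
}

#' Half-deactivation time of a tail current
#'
#' Hv deactivation tails have more than one exponential component, so decay
#' speed is summarized model-free: `I_o` is the current at the repolarization
#' onset (first sample after the capacitive blanking window) and `t_half` is
#' the linearly interpolated time at which the tail first decays to
#' `I_o / 2`. Decays completing within one sample are reported as `dt/2`
#' with the `sub_sample` flag set.
#'
#' @param tail_trace numeric current vector (pA) for the repolarization
#'   epoch.
#' @param dt sampling interval (ms).
#' @param blank_ms capacitive blanking window (ms).
#' @return list with `I_o` (pA), `t_half` (ms, measured from the blanked
#'   onset), `sub_sample` flag.
#' @export
half_deactivation_time <- function(tail_trace, dt, blank_ms = 0.5) {
  n <- length(tail_trace)
  t <- (seq_len(n) - 1) * dt
  keep <- t >= blank_ms - 1e-9
  y <- tail_trace[keep]
  t <- t[keep] - t[keep][1]
  if (length(y) < 2) stop("tail epoch too short")
  i_o <- y[1]
  half <- i_o / 2
  below <- if (i_o >= 0) y <= half else y >= half
  if (!any(below)) stop("tail current never decays to half of its initial value")
  j <- which(below)[1]
  t_half <- if (j == 1) dt / 2 else
    t[j - 1] + (half - y[j - 1]) * (t[j] - t[j - 1]) / (y[j] - y[j - 1])
  list(I_o = i_o, t_half = t_half, sub_sample = t_half < dt)
}

#' Gating charge by the limiting-slope method
#'
#' At very low open probability the logarithm of \eqn{P_o} grows linearly
#' with voltage with slope \eqn{z_g e_0/(k_B T)}; an ordinary least-squares
#' fit of \eqn{\ln P_o} against V over the window \eqn{P_o \le} `po_max`
#' gives the total gating charge
#' \deqn{z_g = (k_B T / e_0)\, \mathrm{slope}.}
#' \eqn{P_o} is taken as normalized conductance.
#'
#' @param po open probabilities (normalized conductance), same length as `V`.
#' @param V voltages (mV).
#' @param po_max upper limit of the fitting window (default 0.02).
#' @param po_min lower limit (default 0, i.e. all positive values).
#' @param T absolute temperature (K).
#' @return an `hv_zg`: list with `z_g` (elementary charges), `slope` (1/mV),
#'   `se`, the window used, and `T`.
#' @export
limiting_slope_zg <- function(po, V, po_max = 0.02, po_min = 0, T = 297) {
  if (length(po) != length(V)) stop("po and V lengths differ")
  win <- is.finite(po) & is.finite(V) & po > po_min & po <= po_max & po > 0
  if (sum(win) < 5) stop("fewer than 5 positive P_o values at or below po_max")
  fit <- stats::lm(log(po[win]) ~ V[win])
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(diag(stats::vcov(fit)))[[2]]
  kT <- thermal_voltage(T)
  structure(list(z_g = kT * slope, slope = slope, se_z = kT * se,
                 n = sum(win), po_window = range(po[win]), T = T),
            class = "hv_zg")
}

#' @export
print.hv_zg <- function(x, ...) {
  cat(sprintf("limiting-slope gating charge: z_g = %.2f +/- %.2f e0 (n = %d, P_o in [%.2g, %.2g], T = %.0f K)\n",
              x$z_g, x$se_z, x$n, x$po_window[1], x$po_window[2], x$T))
  invisible(x)
}

#' Percent inhibition from isochronal currents
#'
#' \eqn{100 (1 - I_{drug}/I_{control})} on current magnitudes; control and
#' drug currents must be channel-mediated currents of the same sign measured
#' under matched protocols.
#'
#' @param I_control,I_drug isochronal currents (pA).
#' @return percent inhibition.
#' @export
inhibition_fraction <- function(I_control, I_drug) {
  if (!is.finite(I_control) || abs(I_control) < 1e-12)
    stop("control current indistinguishable from zero")
  if (I_drug != 0 && sign(I_drug) != sign(I_control))
    stop("control and drug currents have opposite signs")
  100 * (1 - abs(I_drug) / abs(I_control))
}

#' Activation slowing ratio
#'
#' Ratio \eqn{\tau_{on}(+)/\tau_{on}(-)} of activation time constants with
#' and without an inhibitor, from matched voltage steps. Ratios above 1
#' indicate inhibitor-induced deceleration of opening (the closed-state
#' stabilization signature); open-channel blockers leave the ratio at 1.
#'
#' @param fit_plus,fit_minus `hv_expfit` objects (or lists with `tau_on`).
#' @return unitless ratio.
#' @export
tau_ratio <- function(fit_plus, fit_minus) {
  if (is.null(fit_plus$tau_on) || is.null(fit_minus$tau_on))
    stop("both fits must provide tau_on")
  fit_plus$tau_on / fit_minus$tau_on
}
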