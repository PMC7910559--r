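#' Ohmic leak subtraction
#'
#' Fits an ohmic leak \eqn{I_{leak} = g (V - E)} per sweep to samples in a
#' user-designated subthreshold time window (where the channels are closed)
#' and subtracts it from every sample of that sweep. The designated window
#' must contain at least two distinct voltages so that both `g` and `E` are
#' identifiable. If any designated sample sits above `v_max` the fit is
#' flagged as biased and a warning is raised.
#'
#' @param recording an [hv_recording()].
#' @param window_ms numeric length-2: start and end of the subthreshold
#'   window (ms from sweep start).
#' @param v_max highest voltage (mV) regarded as subthreshold; default `Inf`
#'   disables the check.
#' @return the leak-subtracted [hv_recording()]; per-sweep leak parameters in
#'   attribute `"leak"` (data.frame with `sweep`, `g_nS`, `E_mV`,
#'   `biased_fit`).
#' @export
subtract_leak <- function(recording, window_ms, v_max = Inf) {
  stopifnot(inherits(recording, "hv_recording"))
  if (length(window_ms) != 2 || diff(window_ms) <= 0)
    stop("window_ms must be c(start, end) with end > start")
  idx <- which(recording$time >= window_ms[1] - 1e-9 &
               recording$time <= window_ms[2] + 1e-9)
  if (!length(idx)) stop("no samples designated as subthreshold")
  out <- recording
  pars <- data.frame(sweep = seq_len(ncol(recording$current)),
                     g_nS = NA_real_, E_mV = NA_real_, biased_fit = FALSE)
  if (any(recording$voltage[idx, ] > v_max))
    warning("subthreshold window includes voltages above v_max; leak fit may be biased")
  for (sw in seq_len(ncol(recording$current))) {
    V <- recording$voltage[idx, sw]
    I <- recording$current[idx, sw]
    pars$biased_fit[sw] <- any(V > v_max)
    if (length(unique(V)) >= 2) {
      fit <- stats::lm(I ~ V)
      g <- unname(stats::coef(fit)[2])          # pA/mV = nS
      E <- -unname(stats::coef(fit)[1]) / g
    } else {
      ## single designated voltage: assume E = 0 and estimate g alone
      g <- mean(I) / V[1]
      E <- 0
    }
    pars$g_nS[sw] <- g
    pars$E_mV[sw] <- E
    out$current[, sw] <- recording$current[, sw] - g * (recording$voltage[, sw] - E)
  }
  attr(out, "leak") <- pars
  out
}

#' Isochronal current at the end of an epoch
#'
#' Mean current over the final `window_ms` of a trace segment, the standard
#' quantification point for inhibition measurements.
#'
#' @param trace numeric current vector (pA) covering one epoch.
#' @param dt sampling interval (ms).
#' @param window_ms averaging window length (ms), default 5; must not exceed
#'   the epoch duration.
#' @return mean current (pA).
#' @export
isochronal_current <- function(trace, dt, window_ms = 5) {
  n <- length(trace)
  if (window_ms > n * dt + 1e-9) stop("window longer than epoch")
  k <- max(1L, floor(window_ms / dt + 1e-9))
  mean(trace[(n - k + 1):n])
}

#' Isochronal current of a recording epoch, per sweep
#'
#' @param recording an [hv_recording()] carrying its protocol.
#' @param epoch epoch index within the protocol.
#' @param window_ms averaging window (ms).
#' @return numeric vector, one value per sweep.
#' @export
epoch_isochronal <- function(recording, epoch, window_ms = 5) {
  if (is.null(recording$protocol)) stop("recording carries no protocol")
  idx <- epoch_index(recording$protocol, epoch)
  apply(recording$current[idx, , drop = FALSE], 2, isochronal_current,
        dt = recording$dt, window_ms = window_ms)
}

#' Rundown correction against a reference depolarization step
#'
#' Excised-patch recordings lose current amplitude across sweeps (rundown).
#' Each sweep is rescaled by the ratio of the first sweep's isochronal
#' current in a fixed reference epoch to the same measurement in that sweep,
#' so that the reference response is constant across the recording.
#'
#' @param recording an [hv_recording()] with a protocol.
#' @param reference_epoch index of the reference depolarization epoch.
#' @param window_ms isochronal window at the end of the reference epoch (ms).
#' @param noise_floor smallest |reference current| (pA) regarded as
#'   distinguishable from zero.
#' @return the corrected [hv_recording()]; per-sweep scale factors in
#'   attribute `"rundown_scale"`.
#' @export
correct_rundown <- function(recording, reference_epoch, window_ms = 5,
                            noise_floor = 1e-6) {
  ref <- epoch_isochronal(recording, reference_epoch, window_ms)
  if (any(abs(ref) < noise_floor))
    stop("reference current indistinguishable from zero in at least one sweep")
  scale <- ref[1] / ref
  out <- recording
  out$current <- sweep(recording$current, 2, scale, "*")
  attr(out, "rundown_scale") <- scale
  out
}

#' Extract a steady-state current-voltage relation from a step family
#'
#' Takes the isochronal current at the end of the incremented test epoch of
#' each sweep, paired with that epoch's command voltage.
#'
#' @param recording an [hv_recording()] with a protocol whose `sweep_epoch`
#'   (or `epoch`) steps across sweeps.
#' @param epoch test epoch index; defaults to the protocol's incremented
#'   epoch.
#' @param window_ms isochronal window (ms).
#' @return an `hv_iv` object (data.frame with `voltage`, `current`) of kind
#'   `"steady"`.
#' @export
steady_iv <- function(recording, epoch = NULL, window_ms = 5) {
  if (is.null(recording$protocol)) stop("recording carries no protocol")
  p <- recording$protocol
  if (is.null(epoch)) epoch <- p$sweep_epoch
  if (is.na(epoch)) stop("no test epoch designated")
  idx <- epoch_index(p, epoch)
  V <- recording$voltage[idx[1], ]
  I <- epoch_isochronal(recording, epoch, window_ms)
  hv_iv(V, I, kind = "steady")
}

#' Extract an instantaneous tail current-voltage relation
#'
#' Measures the current immediately after repolarization (after a capacitive
#' blanking window) in the designated tail epoch of each sweep, paired with
#' the tail voltage. With `extrapolate = TRUE` a single-exponential fit to
#' the early tail is extrapolated back to the repolarization onset, removing
#' the bias from decay during the blanking window.
#'
#' @param recording an [hv_recording()] with a protocol.
#' @param epoch tail epoch index; defaults to the protocol's incremented
#'   epoch.
#' @param blank_ms capacitive blanking window after the voltage change (ms).
#' @param extrapolate logical; extrapolate an exponential fit to onset.
#' @param fit_ms window used for the extrapolation fit (ms).
#' @return an `hv_iv` of kind `"instantaneous-tail"`.
#' @export
tail_iv <- function(recording, epoch = NULL, blank_ms = 0.5,
                    extrapolate = FALSE, fit_ms = 50) {
  if (is.null(recording$protocol)) stop("recording carries no protocol")
  p <- recording$protocol
  if (is.null(epoch)) epoch <- p$sweep_epoch
  if (is.na(epoch)) stop("no tail epoch designated")
  idx <- epoch_index(p, epoch)
  t0 <- recording$time[idx[1]]
  V <- recording$voltage[idx[ceiling(length(idx) / 2)], ]
  I0 <- numeric(ncol(recording$current))
  for (sw in seq_along(I0)) {
    tt <- recording$time[idx] - t0
    keep <- tt >= blank_ms - 1e-9
    y <- recording$current[idx[keep], sw]
    x <- tt[keep]
    if (!extrapolate) {
      I0[sw] <- y[1]
    } else {
      xw <- x[x <= blank_ms + fit_ms]
      yw <- y[seq_along(xw)]
      f <- tryCatch(
        minpack.lm::nlsLM(yw ~ a * exp(-xw / tau) + c0,
                          start = list(a = yw[1] - yw[length(yw)],
                                       tau = max(diff(range(xw)) / 3, 1e-3),
                                       c0 = yw[length(yw)])),
        error = function(e) NULL)
      I0[sw] <- if (is.null(f)) y[1] else
        sum(stats::coef(f)[c("a", "c0")])   # a * exp(0) + c0
    }
  }
  hv_iv(V, I0, kind = "instantaneous-tail")
}

#' Current-voltage relation
#'
#' @param voltage voltages (mV).
#' @param current currents (pA).
#' @param kind `"steady"`, `"instantaneous-tail"`, or `"ramp"`; ramp IVs
#'   must have strictly ordered voltages.
#' @return an `hv_iv` data.frame.
#' @export
hv_iv <- function(voltage, current, kind = c("steady", "instantaneous-tail", "ramp")) {
  kind <- match.arg(kind)
  if (length(voltage) != length(current)) stop("voltage and current lengths differ")
  if (kind == "ramp" && !(all(diff(voltage) > 0) || all(diff(voltage) < 0)))
    stop("ramp IV voltages must be strictly ordered")
  structure(data.frame(voltage = voltage, current = current),
            kind = kind, class = c("hv_iv", "data.frame"))
}
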