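#' Episodic voltage protocol
#'
#' An ordered list of epochs, each a hold, step, or ramp, repeated over
#' `n_sweeps` sweeps with an optional per-sweep voltage increment applied to
#' one designated epoch (the usual step-family protocol).
#'
#' @param segments a list of epochs, each created by [protocol_epoch()], or a
#'   data.frame with columns `kind`, `V_start`, `V_end`, `duration`.
#' @param n_sweeps number of sweeps (>= 1).
#' @param sweep_increment per-sweep voltage increment (mV) applied to the
#'   epoch indexed by `sweep_epoch`.
#' @param sweep_epoch index of the incremented epoch (NA for none).
#' @param dt sampling interval (ms).
#' @return an object of class `hv_protocol`.
#' @export
hv_protocol <- function(segments, n_sweeps = 1, sweep_increment = 0,
                        sweep_epoch = NA_integer_, dt = 1) {
  if (is.data.frame(segments)) {
    segments <- lapply(seq_len(nrow(segments)), function(i)
      protocol_epoch(segments$kind[i], segments$V_start[i], segments$V_end[i],
                     segments$duration[i]))
  }
  if (length(segments) < 1) stop("protocol needs at least one epoch")
  if (dt <= 0) stop("dt must be positive")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  if (!is.na(sweep_epoch) && (sweep_epoch < 1 || sweep_epoch > length(segments)))
    stop("sweep_epoch out of range")
  structure(list(segments = segments, n_sweeps = as.integer(n_sweeps),
                 sweep_increment = sweep_increment,
                 sweep_epoch = as.integer(sweep_epoch), dt = dt),
            class = "hv_protocol")
}

#' @rdname hv_protocol
#' @param kind `"hold"`, `"step"` (both constant voltage) or `"ramp"`.
#' @param V_start,V_end epoch voltages (mV); for hold/step `V_end` defaults
#'   to `V_start`.
#' @param duration epoch duration (ms), > 0.
#' @export
protocol_epoch <- function(kind = c("hold", "step", "ramp"), V_start,
                           V_end = V_start, duration) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("epoch duration must be positive")
  if (kind != "ramp" && V_end != V_start) stop("hold/step epochs are constant-voltage")
  list(kind = kind, V_start = V_start, V_end = V_end, duration = duration)
}

#' @export
print.hv_protocol <- function(x, ...) {
  cat(sprintf("hv_protocol: %d epoch(s), %d sweep(s), dt = %g ms\n",
              length(x$segments), x$n_sweeps, x$dt))
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    inc <- if (!is.na(x$sweep_epoch) && i == x$sweep_epoch)
      sprintf(" (+%g mV/sweep)", x$sweep_increment) else ""
    cat(sprintf("  [%d] %-4s %g -> %g mV, %g ms%s\n", i, s$kind,
                s$V_start, s$V_end, s$duration, inc))
  }
  invisible(x)
}

## Epoch boundaries (ms from sweep start), length n_epochs + 1
.epoch_bounds <- function(protocol) {
  c(0, cumsum(vapply(protocol$segments, function(s) s$duration, numeric(1))))
}

## Number of samples per sweep
.n_samples <- function(protocol) {
  total <- sum(vapply(protocol$segments, function(s) s$duration, numeric(1)))
  floor(total / protocol$dt + 1e-9)
}

## Command voltage and epoch index at each sample of a given sweep (1-based)
.build_command <- function(protocol, sweep) {
  dt <- protocol$dt
  n <- .n_samples(protocol)
  t <- (seq_len(n) - 1) * dt
  bounds <- .epoch_bounds(protocol)
  epoch <- findInterval(t, bounds, rightmost.closed = FALSE)
  epoch[epoch > length(protocol$segments)] <- length(protocol$segments)
  V <- numeric(n)
  for (i in seq_along(protocol$segments)) {
    s <- protocol$segments[[i]]
    v0 <- s$V_start
    v1 <- s$V_end
    if (!is.na(protocol$sweep_epoch) && i == protocol$sweep_epoch) {
      inc <- protocol$sweep_increment * (sweep - 1)
      v0 <- v0 + inc
      v1 <- v1 + inc
    }
    idx <- which(epoch == i)
    if (!length(idx)) next
    if (s$kind == "ramp") {
      frac <- (t[idx] - bounds[i]) / s$duration
      V[idx] <- v0 + frac * (v1 - v0)
    } else {
      V[idx] <- v0
    }
  }
  list(t = t, V = V, epoch = epoch, bounds = bounds)
}

#' Sample indices of a protocol epoch
#'
#' Indices (into a sweep's sample vector) belonging to epoch `k`, optionally
#' restricted to the final `last_ms` of the epoch.
#'
#' @param protocol an [hv_protocol()].
#' @param k epoch index.
#' @param last_ms if given, keep only samples within the last `last_ms` ms.
#' @return integer sample indices.
#' @export
epoch_index <- function(protocol, k, last_ms = NULL) {
  if (k < 1 || k > length(protocol$segments)) stop("epoch index out of range")
  cmd <- .build_command(protocol, 1)
  idx <- which(cmd$epoch == k)
  if (!is.null(last_ms)) {
    t_end <- cmd$bounds[k + 1]
    idx <- idx[cmd$t[idx] >= t_end - last_ms - 1e-9]
  }
  idx
}

#' Standard step-family protocol
#'
#' Hold, optional fixed reference depolarization (for rundown correction),
#' interpulse hold, incremented test step, and repolarization tail - the
#' protocol used to build steady-state G-V curves.
#'
#' @param hold_mV,hold_ms initial holding epoch.
#' @param ref_mV,ref_ms optional fixed reference step (NULL to omit).
#' @param inter_ms interpulse hold duration (used only with a reference
#'   step).
#' @param step_from,step_inc,step_ms test-step start voltage, per-sweep
#'   increment, and duration.
#' @param n_sweeps sweeps in the family.
#' @param tail_mV,tail_ms repolarization tail epoch.
#' @param dt sampling interval (ms).
#' @return an [hv_protocol()]; the test step is the incremented epoch.
#' @export
step_family_protocol <- function(hold_mV = -80, hold_ms = 100,
                                 ref_mV = NULL, ref_ms = 300, inter_ms = 200,
                                 step_from = -20, step_inc = 10, step_ms = 2000,
                                 n_sweeps = 9, tail_mV = -80, tail_ms = 500,
                                 dt = 1) {
  segs <- list(protocol_epoch("hold", hold_mV, duration = hold_ms))
  if (!is.null(ref_mV)) {
    segs <- c(segs, list(protocol_epoch("step", ref_mV, duration = ref_ms),
                         protocol_epoch("hold", hold_mV, duration = inter_ms)))
  }
  step_i <- length(segs) + 1L
  segs <- c(segs, list(protocol_epoch("step", step_from, duration = step_ms),
                       protocol_epoch("step", tail_mV, duration = tail_ms)))
  hv_protocol(segs, n_sweeps = n_sweeps, sweep_increment = step_inc,
              sweep_epoch = step_i, dt = dt)
}

#' Tail-family protocol for reversal-potential measurements
#'
#' A fixed activating prepulse followed by a tail epoch whose voltage steps
#' across sweeps; the instantaneous tail currents locate the reversal
#' potential.
#'
#' @param hold_mV,hold_ms holding epoch.
#' @param pre_mV,pre_ms activating prepulse (e.g. a depolarization to
#'   100 mV).
#' @param tail_from,tail_inc,tail_ms tail start voltage, per-sweep
#'   increment, duration.
#' @param n_sweeps sweeps.
#' @param dt sampling interval (ms).
#' @return an [hv_protocol()]; the tail is the incremented epoch.
#' @export
tail_family_protocol <- function(hold_mV = -80, hold_ms = 100,
                                 pre_mV = 100, pre_ms = 2000,
                                 tail_from = -60, tail_inc = 10, tail_ms = 300,
                                 n_sweeps = 9, dt = 1) {
  segs <- list(protocol_epoch("hold", hold_mV, duration = hold_ms),
               protocol_epoch("step", pre_mV, duration = pre_ms),
               protocol_epoch("step", tail_from, duration = tail_ms))
  hv_protocol(segs, n_sweeps = n_sweeps, sweep_increment = tail_inc,
              sweep_epoch = 3L, dt = dt)
}

#' Slow-ramp protocol for limiting-slope measurements
#'
#' Optional maximal-activation prepulse (to measure G_max), recovery hold,
#' then a slow depolarizing ramp through the low-open-probability range.
#'
#' @param hold_mV,hold_ms holding epoch.
#' @param pre_mV,pre_ms optional maximal-activation prepulse (NULL to omit).
#' @param rec_ms recovery hold after the prepulse.
#' @param ramp_from,ramp_to,ramp_ms ramp limits and duration.
#' @param dt sampling interval (ms).
#' @return an [hv_protocol()] with a single sweep.
#' @export
ramp_protocol <- function(hold_mV = -80, hold_ms = 200,
                          pre_mV = 60, pre_ms = 500, rec_ms = 300,
                          ramp_from = -80, ramp_to = 0, ramp_ms = 8000,
                          dt = 2) {
  segs <- list(protocol_epoch("hold", hold_mV, duration = hold_ms))
  if (!is.null(pre_mV))
    segs <- c(segs, list(protocol_epoch("step", pre_mV, duration = pre_ms),
                         protocol_epoch("hold", hold_mV, duration = rec_ms)))
  segs <- c(segs, list(protocol_epoch("ramp", ramp_from, ramp_to, ramp_ms)))
  hv_protocol(segs, n_sweeps = 1, dt = dt)
}
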