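#' Noise, leak, and rundown settings for the simulator
#'
#' Artifact model applied on top of the deterministic channel current:
#' additive Gaussian current noise, an ohmic leak conductance, and a
#' geometric per-sweep rundown of the channel conductance.
#'
#' @param sigma_I Gaussian current noise s.d. (pA), >= 0.
#' @param rundown_per_sweep multiplicative conductance retention per sweep,
#'   in (0, 1]; sweep k (1-based) is scaled by `rundown_per_sweep^(k-1)`.
#' @param g_leak ohmic leak conductance (nS).
#' @param E_leak leak reversal potential (mV).
#' @param seed integer random seed; identical seeds give identical recordings.
#' @return an object of class `hv_noise`.
#' @export
hv_noise <- function(sigma_I = 0, rundown_per_sweep = 1, g_leak = 0,
                     E_leak = 0, seed = 0) {
  if (sigma_I < 0) stop("sigma_I must be non-negative")
  if (rundown_per_sweep <= 0 || rundown_per_sweep > 1)
    stop("rundown_per_sweep must be in (0, 1]")
  structure(list(sigma_I = sigma_I, rundown_per_sweep = rundown_per_sweep,
                 g_leak = g_leak, E_leak = E_leak, seed = as.integer(seed)),
            class = "hv_noise")
}

## Generator matrix of the linear scheme at voltage V (dP/dt = Q P).
## Forward rate of transition i: rate0 * exp( z/2 (V-vm)/kT );
## backward:                     rate0 * exp(-z/2 (V-vm)/kT ).
.rate_matrix <- function(scheme, V, vm, kT) {
  n <- scheme$n_states
  x <- scheme$z_step * (V - vm) / kT / 2
  if (any(!is.finite(x))) stop("non-finite transition rates")
  a <- scheme$rate0 * exp(pmin(x, 300))
  b <- scheme$rate0 * exp(pmin(-x, 300))
  Q <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Q[i, i] <- Q[i, i] - a[i]
    Q[i + 1, i] <- Q[i + 1, i] + a[i]
    Q[i + 1, i + 1] <- Q[i + 1, i + 1] - b[i]
    Q[i, i + 1] <- Q[i, i + 1] + b[i]
  }
  Q
}

## Equilibrium occupancy at voltage V
.eq_occupancy <- function(scheme, V, vm, kT) {
  logw <- c(0, cumsum(scheme$z_step * (V - vm) / kT))
  w <- exp(logw - max(logw))
  w / sum(w)
}

## Occupancies at `times` (>= 0) after starting from p0 under constant Q.
## Eigendecomposition when well conditioned, Matrix::expm otherwise.
## Returns list(P = n x length(times) matrix, p_end = occupancy at max(times)).
.propagate_const <- function(Q, p0, times) {
  n <- nrow(Q)
  if (!length(times)) return(list(P = matrix(numeric(0), n, 0), p_end = p0))
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- !is.null(ev) &&
    is.finite(rk <- tryCatch(rcond(abs(ev$vectors) + diag(1e-300, n)), error = function(e) NA)) &&
    !is.na(rk) && rk > 1e-10
  if (use_eigen) {
    coef <- tryCatch(solve(ev$vectors, p0), error = function(e) NULL)
    use_eigen <- !is.null(coef)
  }
  if (use_eigen) {
    E <- exp(outer(ev$values, times))
    P <- Re(ev$vectors %*% (coef * E))
  } else {
    P <- matrix(0, n, length(times))
    ord <- order(times)
    p <- p0
    t_prev <- 0
    for (j in ord) {
      dtj <- times[j] - t_prev
      if (dtj > 0) p <- as.numeric(Matrix::expm(Q * dtj) %*% p)
      P[, j] <- p
      t_prev <- times[j]
    }
  }
  P <- pmax(P, 0)
  P <- sweep(P, 2, colSums(P), "/")
  list(P = P, p_end = P[, which.max(times)])
}

#' Simulate an episodic voltage-clamp recording
#'
#' Integrates the linear scheme's master equation along the voltage protocol
#' and assembles the current at each sample as
#' \deqn{I = g_{leak}(V - E_{leak}) + r^{k-1} g_{max} P_O(t)(V - E_H) + \epsilon}
#' where \eqn{r} is the per-sweep rundown factor, \eqn{E_H} the proton Nernst
#' potential of the solutions, and \eqn{\epsilon} Gaussian noise. Constant
#' voltage epochs are propagated analytically by matrix exponential; ramps
#' are integrated piecewise with sub-steps of at most 1 ms (bounded at 20000
#' sub-steps per epoch, where slow ramps are quasi-static). Occupancies start
#' at the equilibrium for the first epoch's voltage and sum to one at every
#' sample. Schemes with more than two states show the characteristic
#' sigmoidal activation lag.
#'
#' @param model an [hv_model()].
#' @param protocol an [hv_protocol()].
#' @param solutions an [hv_solutions()].
#' @param noise an [hv_noise()]; default noiseless, leakless, no rundown.
#' @param return_occupancy if TRUE, attach the full state-occupancy array
#'   (`n_states x n_samples x n_sweeps`) as attribute `"occupancy"` and the
#'   open probability matrix as attribute `"po"`.
#' @return an [hv_recording()].
#' @export
simulate_recording <- function(model, protocol, solutions = hv_solutions(),
                               noise = hv_noise(), return_occupancy = FALSE) {
  stopifnot(inherits(model, "hv_model"), inherits(protocol, "hv_protocol"),
            inherits(solutions, "hv_solutions"), inherits(noise, "hv_noise"))
  kT <- thermal_voltage(solutions$T)
  vh <- effective_v_half(model, solutions)
  scheme <- model$scheme
  vm <- .scheme_vm(scheme, vh, kT)
  e_h <- nernst_potential(solutions$pH_i, solutions$pH_o, solutions$T)
  n_sw <- protocol$n_sweeps
  ns <- .n_samples(protocol)
  n_states <- scheme$n_states

  set.seed(noise$seed)
  current <- voltage <- matrix(NA_real_, ns, n_sw)
  po <- matrix(NA_real_, ns, n_sw)
  occ <- if (return_occupancy) array(NA_real_, c(n_states, ns, n_sw)) else NULL

  for (sw in seq_len(n_sw)) {
    cmd <- .build_command(protocol, sw)
    voltage[, sw] <- cmd$V
    p <- .eq_occupancy(scheme, cmd$V[1], vm, kT)
    for (i in seq_along(protocol$segments)) {
      seg <- protocol$segments[[i]]
      idx <- which(cmd$epoch == i)
      t0 <- cmd$bounds[i]
      t_loc <- cmd$t[idx] - t0
      if (seg$kind != "ramp") {
        vconst <- seg$V_start +
          if (!is.na(protocol$sweep_epoch) && i == protocol$sweep_epoch)
            protocol$sweep_increment * (sw - 1) else 0
        Q <- .rate_matrix(scheme, vconst, vm, kT)
        ## sample occupancies, then carry the state to the epoch end
        res <- .propagate_const(Q, p, c(t_loc, seg$duration))
        if (length(idx)) {
          P <- res$P[, seq_along(t_loc), drop = FALSE]
          po[idx, sw] <- P[n_states, ]
          if (return_occupancy) occ[, idx, sw] <- P
        }
        p <- res$P[, length(t_loc) + 1]
      } else {
        v0 <- seg$V_start
        v1 <- seg$V_end
        if (!is.na(protocol$sweep_epoch) && i == protocol$sweep_epoch) {
          inc <- protocol$sweep_increment * (sw - 1)
          v0 <- v0 + inc; v1 <- v1 + inc
        }
        rate <- (v1 - v0) / seg$duration
        h_target <- max(1, seg$duration / 20000)   # sub-step length (ms)
        events <- sort(unique(c(t_loc, seg$duration)))
        tau <- 0
        for (te in events) {
          gap <- te - tau
          if (gap > 1e-12) {
            m <- max(1L, ceiling(gap / h_target))
            h <- gap / m
            for (k in seq_len(m)) {
              vmid <- v0 + rate * (tau + (k - 0.5) * h)
              Q <- .rate_matrix(scheme, vmid, vm, kT)
              p <- .propagate_const(Q, p, h)$p_end
            }
            tau <- te
          }
          j <- idx[match(te, t_loc)]
          if (!is.na(j)) {
            po[j, sw] <- p[n_states]
            if (return_occupancy) occ[, j, sw] <- p
          }
        }
      }
    }
    g <- model$g_max * noise$rundown_per_sweep^(sw - 1)
    current[, sw] <- noise$g_leak * (voltage[, sw] - noise$E_leak) +
      g * po[, sw] * (voltage[, sw] - e_h)
    if (noise$sigma_I > 0)
      current[, sw] <- current[, sw] + stats::rnorm(ns, 0, noise$sigma_I)
  }

  rec <- hv_recording(dt = protocol$dt, current = current, voltage = voltage,
                      solutions = solutions, protocol = protocol,
                      labels = model$label, seed = noise$seed)
  if (return_occupancy) {
    attr(rec, "occupancy") <- occ
    attr(rec, "po") <- po
  }
  rec
}
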