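## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## Exhaustive global-alignment score: enumerates every gapped alignment of
## a and b (no gap-both columns) and scores runs with affine penalties
## open + extend * (L - 1). Feasible for sequences up to ~6 residues.
brute_force_align_score <- function(a, b, mat, open = 8, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, score + mat[A[i], B[j]], "none")
    if (j <= length(B))   # consume b, gap in row a
      rec(i, j + 1, score - if (identical(state, "gap_a")) extend else open, "gap_a")
    if (i <= length(A))   # consume a, gap in row b
      rec(i + 1, j, score - if (identical(state, "gap_b")) extend else open, "gap_b")
  }
  rec(1, 1, 0, "none")
  best
}

## Equilibrium open probability of a linear scheme from the null space of
## the generator matrix (detailed balance not assumed by the method).
nullspace_po <- function(z_step, vm, V, kT) {
  n <- length(z_step) + 1
  a <- exp(z_step * (V - vm) / kT / 2)
  b <- exp(-z_step * (V - vm) / kT / 2)
  Q <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Q[i, i] <- Q[i, i] - a[i]
    Q[i + 1, i] <- Q[i + 1, i] + a[i]
    Q[i + 1, i + 1] <- Q[i + 1, i + 1] - b[i]
    Q[i, i + 1] <- Q[i, i + 1] + b[i]
  }
  ## solve Q p = 0 with sum(p) = 1 by replacing one row
  M <- rbind(Q[-n, , drop = FALSE], rep(1, n))
  p <- solve(M, c(rep(0, n - 1), 1))
  p[n]
}

## Direct partition-function enumeration of the same occupancy
enumeration_po <- function(z_step, vm, V, kT) {
  w <- 1
  ws <- numeric(length(z_step) + 1)
  ws[1] <- w
  for (i in seq_along(z_step)) {
    w <- w * exp(z_step[i] * (V - vm) / kT)
    ws[i + 1] <- w
  }
  ws[length(ws)] / sum(ws)
}

## Grid-search least-squares single-exponential fit (oracle for
## fit_activation on lagged waveforms): fits a exp(-(t-t0)/tau) + c over a
## tau grid with linear parameters profiled out.
grid_exp_fit <- function(t, y, t0, taus = exp(seq(log(0.5), log(500), length.out = 400))) {
  keep <- t >= t0
  tt <- t[keep] - t0
  yy <- y[keep]
  best <- c(tau = NA, rss = Inf)
  for (tau in taus) {
    X <- cbind(1, exp(-tt / tau))
    fit <- stats::lm.fit(X, yy)
    rss <- sum(fit$residuals^2)
    if (rss < best["rss"]) best <- c(tau = tau, rss = rss)
  }
  best[["tau"]]
}

## Noisy normalized G-V replicate on a voltage grid (mirrors how synthetic
## replicates are produced throughout)
noisy_gv <- function(V, V_half, s, sd = 0.03, seed = 0) {
  set.seed(seed)
  data.frame(voltage = V,
             G_norm = eval_boltzmann(V, V_half, s) + stats::rnorm(length(V), 0, sd))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
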