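test_that("proton Nernst potential matches the analytic form", {
  expect_equal(nernst_potential(6.0, 6.0, 297), 0)
  expect_equal(nernst_potential(6.0, 7.0, 297), -58.9, tolerance = 0.001)
  expect_equal(nernst_potential(5.5, 6.5, 297), -58.9, tolerance = 0.001)
  expect_equal(nernst_potential(5.0, 7.0, 297), -117.9, tolerance = 0.001)
  ## sign convention: acid-outside gradients give positive E_H
  expect_gt(nernst_potential(7.0, 6.0, 297), 0)
  expect_error(nernst_potential(0, 6), "pH")
  expect_error(hv_solutions(T = -1), "T must be")
})

test_that("effective V_1/2 follows the linear pH coupling", {
  m <- hv_preset("SlHv1")
  expect_equal(effective_v_half(m, hv_solutions(6, 6)), m$V_half_ref)
  m85 <- hv_model(c_dpH = -85, c_sym = 0, V_half_ref = 40)
  expect_equal(effective_v_half(m85, hv_solutions(6, 7)), 40 - 85)
  ## symmetric pH 5.5 vs 6.5 differ by the 19 mV/pH coupling
  d <- effective_v_half(m, hv_solutions(6.5, 6.5)) -
       effective_v_half(m, hv_solutions(5.5, 5.5))
  expect_equal(d, 19)
})

test_that("steady-state open probability reduces to the Boltzmann and matches enumeration", {
  m <- hv_preset("SlHv1")
  vh <- effective_v_half(m, hv_solutions())
  expect_equal(steady_state_po(vh, m), 0.5, tolerance = 1e-12)
  expect_equal(steady_state_po(50, m), 0.613, tolerance = 1e-3)
  ## n-state occupancy equals independent partition-function and null-space oracles
  sch <- hv_scheme(3, z_step = c(1.4, 2.1), rate0 = 0.1)
  m3 <- hv_model(scheme = sch, V_half_ref = 10, s = 8)
  kT <- thermal_voltage(297)
  vm <- hvgating:::.scheme_vm(sch, 10, kT)
  for (V in c(-40, -10, 10, 35)) {
    expect_equal(steady_state_po(V, m3), enumeration_po(c(1.4, 2.1), vm, V, kT),
                 tolerance = 1e-12)
    expect_equal(steady_state_po(V, m3), nullspace_po(c(1.4, 2.1), vm, V, kT),
                 tolerance = 1e-9)
  }
})

test_that("Boltzmann evaluation reproduces the reference-voltage readouts", {
  expect_equal(eval_boltzmann(46.5, 46.5, 7.6), 0.5)
  expect_equal(round(eval_boltzmann(50, 46.5, 7.6), 2), 0.61)
  expect_equal(round(eval_boltzmann(-10, -13.9, 7.4), 2), 0.63)
  expect_error(eval_boltzmann(0, 0, 0), "non-zero")
  ## strictly increasing in V for s > 0
  V <- seq(-100, 100, 1)
  expect_true(all(diff(eval_boltzmann(V, 20, 8)) > 0))
})

test_that("two-state presets tie the gating charge to the slope factor", {
  for (nm in c("SlHv1", "AoHv1", "hHv1")) {
    m <- hv_preset(nm)
    expect_equal(sum(m$scheme$z_step), thermal_voltage(297) / m$s,
                 tolerance = 1e-10)
  }
  expect_equal(sum(hv_preset("SlHv1")$scheme$z_step), 3.37, tolerance = 0.01)
})

test_that("blockers act on conductance or gating as their mechanism dictates", {
  m <- hv_preset("AoHv1")
  expect_identical(apply_blocker(m, hv_blocker("open-channel", 0, 50))$g_max, m$g_max)
  ob <- apply_blocker(m, hv_blocker("open-channel", conc = 50, Kd = 50))
  expect_equal(ob$g_max, m$g_max / 2)
  expect_identical(ob$scheme$rate0, m$scheme$rate0)      # kinetics untouched
  expect_identical(ob$V_half_ref, m$V_half_ref)
  cb <- apply_blocker(m, hv_blocker("closed-state", conc = 100, Kd = 100,
                                    dV_half = 30, slow_factor = 3))
  expect_equal(cb$V_half_ref, m$V_half_ref + 15)         # half-saturating shift
  expect_equal(cb$scheme$rate0, m$scheme$rate0 / 3)
  expect_identical(cb$g_max, m$g_max)                    # conductance untouched
  expect_error(hv_blocker("open-channel", conc = -1, Kd = 10), "non-negative")
})

test_that("simulated recordings honour the generative current equation", {
  sol <- hv_solutions()
  prot <- step_family_protocol(step_from = 30, step_inc = 10, n_sweeps = 3,
                               step_ms = 3500, dt = 2)
  ## channel-free limit: pure ohmic leak
  m0 <- hv_model(g_max = 1e-12, V_half_ref = 300)
  r0 <- simulate_recording(m0, prot, sol, hv_noise(g_leak = 0.5, E_leak = -10))
  expect_equal(r0$current, 0.5 * (r0$voltage - (-10)), tolerance = 1e-6)
  ## terminal current of a long step approaches g_max * P_O * (V - E_H)
  m <- hv_preset("SlHv1")
  r <- simulate_recording(m, prot, sol, hv_noise(seed = 1))
  iv <- steady_iv(r)
  pred <- m$g_max * steady_state_po(iv$voltage, m, sol) * iv$voltage
  expect_equal(iv$current, pred, tolerance = 0.01)
})

test_that("two-state relaxation time equals 1/(alpha + beta)", {
  m <- hv_preset("AoHv1")
  V <- 30
  kT <- thermal_voltage(297)
  z <- m$scheme$z_step
  x <- z * (V - m$V_half_ref) / kT / 2
  tau_true <- 1 / (m$scheme$rate0 * (exp(x) + exp(-x)))
  prot <- hv_protocol(list(protocol_epoch("hold", -80, duration = 40),
                           protocol_epoch("step", V, duration = 600)),
                      dt = 0.5)
  r <- simulate_recording(m, prot, hv_solutions(), hv_noise())
  f <- fit_activation(r$current[epoch_index(prot, 2), 1], 0.5, blank_ms = 0)
  expect_equal(f$tau_on, tau_true, tolerance = 0.02)
})

test_that("state occupancies are conserved at every sample", {
  prots <- list(
    step_family_protocol(step_from = 0, step_inc = 20, n_sweeps = 3,
                         step_ms = 400, dt = 2),
    ramp_protocol(pre_mV = NULL, ramp_from = -80, ramp_to = 40,
                  ramp_ms = 500, dt = 2))
  for (nm in c("SlHv1_seq", "AoHv1")) {
    m <- hv_preset(nm)
    for (p in prots) {
      r <- simulate_recording(m, p, hv_solutions(), hv_noise(seed = 7),
                              return_occupancy = TRUE)
      occ <- attr(r, "occupancy")
      sums <- apply(occ, c(2, 3), sum)
      expect_true(all(abs(sums - 1) < 1e-9))
    }
  }
})

test_that("simulated tail currents reverse at the Nernst potential", {
  m <- hv_preset("AoHv1")
  for (d in c(-0.5, 0, 0.5, 1)) {
    sol <- hv_solutions(6.0, 6.0 + d)
    vh <- effective_v_half(m, sol)
    prot <- tail_family_protocol(pre_mV = vh + 60, pre_ms = 900,
                                 tail_from = nernst_potential(sol$pH_i, sol$pH_o) - 40,
                                 tail_inc = 10, n_sweeps = 9, dt = 1)
    r <- simulate_recording(m, prot, sol, hv_noise(seed = 11))
    vrev <- estimate_reversal(tail_iv(r, blank_ms = 1))
    expect_equal(vrev, nernst_potential(sol$pH_i, sol$pH_o, sol$T),
                 tolerance = 0.5, expected.label = "E_H")
  }
})

test_that("identical seeds give identical recordings, different seeds differ", {
  m <- hv_preset("SlHv1")
  prot <- step_family_protocol(step_from = 20, step_inc = 20, n_sweeps = 2,
                               step_ms = 300, dt = 2)
  r1 <- simulate_recording(m, prot, hv_solutions(), hv_noise(sigma_I = 2, seed = 5))
  r2 <- simulate_recording(m, prot, hv_solutions(), hv_noise(sigma_I = 2, seed = 5))
  r3 <- simulate_recording(m, prot, hv_solutions(), hv_noise(sigma_I = 2, seed = 6))
  expect_identical(r1$current, r2$current)
  expect_false(identical(r1$current, r3$current))
  ## byte-identical files too
  f1 <- tempfile(); f2 <- tempfile()
  write_recording(r1, f1); write_recording(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("multi-state schemes show an activation lag, two-state schemes do not", {
  prot <- hv_protocol(list(protocol_epoch("hold", -80, duration = 50),
                           protocol_epoch("step", 60, duration = 300)),
                      dt = 0.5)
  idx <- epoch_index(prot, 2)
  sol <- hv_solutions()
  m3 <- hv_model(scheme = hv_scheme(3, z_step = c(1.7, 1.7), rate0 = 0.02),
                 V_half_ref = 20, s = 8)
  po3 <- attr(simulate_recording(m3, prot, sol, hv_noise(),
                                 return_occupancy = TRUE), "po")[idx, 1]
  ## sigmoidal rise: initial slope is an order of magnitude below the maximal slope
  d3 <- diff(po3) / max(diff(po3))
  expect_lt(d3[1], 0.1)
  m2 <- hv_preset("AoHv1")
  po2 <- attr(simulate_recording(m2, prot, sol, hv_noise(),
                                 return_occupancy = TRUE), "po")[idx, 1]
  d2 <- diff(po2) / max(diff(po2))
  expect_gt(d2[1], 0.5)   # exponential rise starts at maximal slope
})
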