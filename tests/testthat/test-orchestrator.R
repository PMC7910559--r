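small_config <- function(seed = 3) {
  list(input = list(preset = "SlHv1", pH_i = 6.0, pH_o = 6.0),
       seed = seed,
       simulate = list(n_sweeps = 8, step_from = 10, step_inc = 10,
                       step_ms = 2500, dt = 2, sigma_I = 0.5,
                       rundown_per_sweep = 0.98, ref_mV = 80),
       analysis = list(leak_window_ms = c(0, 99)))
}

test_that("configuration-driven runs equal direct module calls", {
  bundle <- run_config(small_config())
  expect_s3_class(bundle$boltzmann, "hv_boltzmann")
  expect_equal(bundle$boltzmann$V_half, 46.5, tolerance = 0.05)
  ## reproduce by hand with the same stages
  cfg <- small_config()
  sol <- hv_solutions(6, 6)
  prot <- step_family_protocol(ref_mV = 80, step_from = 10, step_inc = 10,
                               step_ms = 2500, n_sweeps = 8, dt = 2)
  rec <- simulate_recording(hv_preset("SlHv1"), prot, sol,
                            hv_noise(sigma_I = 0.5, rundown_per_sweep = 0.98,
                                     seed = 3))
  rec <- subtract_leak(rec, c(0, 99))
  rec <- correct_rundown(rec, 2)
  direct <- fit_boltzmann(derive_gv(steady_iv(rec), V_rev = 0))
  expect_equal(bundle$boltzmann$V_half, direct$V_half, tolerance = 1e-10)
  expect_equal(bundle$boltzmann$s, direct$s, tolerance = 1e-10)
})

test_that("identical configuration and seed give byte-identical outputs", {
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  run_config(small_config(), out_dir = d1)
  run_config(small_config(), out_dir = d2)
  for (f in c("recording.txt", "gv_points.csv", "report.txt", "manifest.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  ## manifest records seed and parameters
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(man$seed, 3)
  expect_equal(man$simulate$step_ms, 2500)
})

test_that("configs referencing unknown presets fail by name", {
  cfg <- small_config()
  cfg$input$preset <- "NoSuchChannel"
  expect_error(run_config(cfg), "NoSuchChannel")
  expect_error(run_config(list(input = list(file = "absent.txt"), seed = 1)),
               "load")
})

test_that("the fixture suite is deterministic and matches its presets", {
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  f1 <- generate_fixture_suite(seed = 1, out_dir = d1,
                               presets = c("SlHv1", "AoHv1"), dpH = 0,
                               n_sweeps = 8, step_ms = 2500, dt = 2)
  f2 <- generate_fixture_suite(seed = 1, out_dir = d2,
                               presets = c("SlHv1", "AoHv1"), dpH = 0,
                               n_sweeps = 8, step_ms = 2500, dt = 2)
  expect_length(f1, 2 + 4 + 2)    # recordings + blocker conditions + seq/structure stubs
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  ## the SlHv1 fixture refits to its preset parameters
  rec <- read_recording(file.path(d1, "SlHv1_dpH+0.txt"))
  rec <- subtract_leak(rec, c(0, 99))
  fit <- fit_boltzmann(derive_gv(steady_iv(rec), V_rev = 0))
  expect_equal(fit$V_half, 46.5, tolerance = 0.05)
  expect_equal(fit$s, 7.6, tolerance = 0.05)
  ## AoHv1 carries inward current at its half-activation voltage
  m <- hv_preset("AoHv1")
  i_at_vhalf <- m$g_max * 0.5 * (m$V_half_ref - 0)
  expect_lt(i_at_vhalf, 0)
})
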