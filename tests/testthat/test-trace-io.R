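make_rec <- function(n_sweeps = 3, n = 40, seed = 1) {
  set.seed(seed)
  prot <- step_family_protocol(step_from = 0, step_inc = 10, step_ms = 30,
                               hold_ms = 10, tail_ms = 10, n_sweeps = n_sweeps,
                               dt = 1)
  hv_recording(dt = 1,
               current = matrix(rnorm(50 * n_sweeps), 50, n_sweeps),
               voltage = matrix(rep(c(rep(-80, 10), rep(0, 30), rep(-80, 10)), n_sweeps),
                                50, n_sweeps),
               solutions = hv_solutions(5.5, 6.5, 296),
               protocol = prot, labels = c("toy", "unit-test"), seed = 42L)
}

test_that("write/read round-trip preserves the recording", {
  rec <- make_rec()
  path <- tempfile(fileext = ".txt")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$current, rec$current, ignore_attr = TRUE)
  expect_equal(back$voltage, rec$voltage, ignore_attr = TRUE)
  expect_identical(back$dt, rec$dt)
  expect_equal(back$solutions$pH_i, 5.5)
  expect_equal(back$solutions$pH_o, 6.5)
  expect_equal(back$solutions$T, 296)
  expect_identical(back$labels, rec$labels)
  expect_identical(back$seed, rec$seed)
  ## protocol survives serialization
  expect_equal(back$protocol$segments, rec$protocol$segments)
  expect_identical(back$protocol$sweep_epoch, rec$protocol$sweep_epoch)
  ## write(read(x)) is byte-identical to write(x)
  path2 <- tempfile()
  write_recording(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("sweep counts come through the file", {
  prot <- step_family_protocol(step_from = 0, step_inc = 10, step_ms = 20,
                               hold_ms = 10, tail_ms = 10, n_sweeps = 9, dt = 2)
  rec <- simulate_recording(hv_preset("AoHv1"), prot, hv_solutions(), hv_noise())
  path <- tempfile()
  write_recording(rec, path)
  dat <- read.table(path, comment.char = "#")
  expect_identical(sort(unique(dat$V1)), 0:8)
  expect_identical(ncol(read_recording(path)$current), 9L)
})

test_that("a hand-written toy file parses to exact values", {
  path <- tempfile()
  writeLines(c("#format_version=1", "#dt=0.5", "#units_current=pA",
               "#units_voltage=mV", "#pH_i=6", "#pH_o=7", "#temperature_K=297",
               "#n_sweeps=1",
               "0 0 -80 -1.25", "0 0.5 40 512.5", "0 1 40 600"), path)
  rec <- read_recording(path)
  expect_identical(as.numeric(rec$current), c(-1.25, 512.5, 600))
  expect_identical(as.numeric(rec$voltage), c(-80, 40, 40))
  expect_identical(rec$dt, 0.5)
  expect_equal(rec$solutions$dpH, 1)
})

test_that("constructor and parser reject malformed recordings", {
  expect_error(hv_recording(1, matrix(1, 2, 2), matrix(1, 3, 2)), "identical dimensions")
  expect_error(hv_recording(0, matrix(1, 2, 2), matrix(1, 2, 2)), "dt")
  rec <- make_rec(n_sweeps = 2)
  path <- tempfile()
  write_recording(rec, path)
  lines <- readLines(path)
  corruptions <- list(
    missing_dt = lines[!grepl("^#dt=", lines)],
    missing_pH = lines[!grepl("^#pH_i=", lines)],
    bad_units = sub("^#units_current=pA$", "#units_current=nA", lines),
    ragged = lines[-length(lines)],                  # drop one sample of last sweep
    wrong_count = sub("^#n_sweeps=2$", "#n_sweeps=5", lines),
    shuffled_time = {
      l <- lines
      i <- grep("^0 ", l)[1:2]
      l[i] <- l[rev(i)]
      l
    })
  for (nm in names(corruptions)) {
    bad <- tempfile()
    writeLines(corruptions[[nm]], bad)
    expect_error(read_recording(bad), regexp = ".", info = nm)
  }
  expect_error(read_recording(tempfile()), "no such file")
})
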