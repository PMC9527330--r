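test_that("baseline correction subtracts the five post-zero samples and is idempotent", {
  tr <- raw_trace(seq(0, 80, 0.5), c(0, 1, 2, 3, 4, 5, rep(10, 155)))
  bc <- baseline_correct(tr)
  expect_equal(bc$voltage_uV[1], -3)      # mean(1:5) = 3 subtracted everywhere
  expect_equal(bc$voltage_uV[7], 7)
  const <- raw_trace(seq(0, 80, 0.5), rep(7, 161))
  expect_equal(baseline_correct(const)$voltage_uV, rep(0, 161))
  expect_equal(baseline_correct(bc), bc)  # idempotence
  expect_error(baseline_correct(raw_trace(c(0, 1, 2), 1:3)), ">= 5 samples")
})

test_that("baseline post-condition holds on random traces", {
  withr::with_seed(1, {
    for (i in 1:20) {
      tr <- raw_trace(GRID, rnorm(161, sd = 50) + runif(1, -100, 100))
      bc <- baseline_correct(tr)
      expect_lt(abs(mean(bc$voltage_uV[2:6])), 1e-9)
    }
  })
})

test_that("resampling is linear interpolation onto the 161-point grid", {
  on_grid <- raw_trace(GRID, flash_model())
  expect_equal(resample_std(on_grid)$voltage_uV, flash_model())
  t <- seq(0, 81, by = 0.37)
  lin <- resample_std(raw_trace(t, 2 * t))
  expect_equal(lin$voltage_uV, 2 * GRID)  # linearity preserved exactly
  expect_length(lin$voltage_uV, 161)
  expect_error(resample_std(raw_trace(seq(0, 60, 0.5), seq(0, 60, 0.5))),
               "extrapolation")
})

test_that("MSE triple selection matches the exhaustive oracle and flags n = 2", {
  withr::with_seed(7, {
    base <- flash_model()
    v <- sapply(1:5, function(i) base + rnorm(161, sd = 4))
    v[, 2] <- v[, 2] + 300 * exp(-(GRID - 30)^2 / 200)  # blink
    v[, 5] <- v[, 5] + 300 * exp(-(GRID - 55)^2 / 200)
    sel <- select_traces_mse(v)
    expect_equal(sel$index, c(1, 3, 4))   # the clean repeats
    expect_equal(sel$index, mse_oracle(v))
  })
  v3 <- sapply(1:3, function(i) flash_model())
  expect_equal(select_traces_mse(v3)$index, 1:3)
  ident <- sapply(1:6, function(i) flash_model())
  expect_equal(select_traces_mse(ident)$index, 1:3)  # tie-break by index
  v2 <- ident[, 1:2]
  s2 <- select_traces_mse(v2)
  expect_equal(s2$index, 1:2)
  expect_equal(s2$flag, "two_repeats_only")
  expect_error(select_traces_mse(ident[, 1, drop = FALSE]), ">= 2 repeats")
})

test_that("flicker selection takes the top-3 30 Hz magnitudes", {
  v <- sapply(1:4, function(a) a * sin(2 * pi * 30 * GRID / 1000))
  expect_equal(select_traces_flicker(v)$index, 2:4)
  ## magnitude agrees with a direct sine/cosine quadrature oracle
  withr::with_seed(3, {
    x <- rnorm(161, sd = 20)
    mag <- fferg:::flicker_signal(x, GRID)
    qc <- sqrt(sum(x * cos(2 * pi * 30 * GRID / 1000))^2 +
                 sum(x * sin(2 * pi * 30 * GRID / 1000))^2) / length(x)
    expect_equal(mag, qc, tolerance = 1e-9)
  })
  expect_equal(select_traces_flicker(v[, 1:3])$index, 1:3)
})

test_that("component detection recovers the noiseless model and flags flat traces", {
  ## DA10-like two-lobe model with known extrema
  v <- flash_model(250, 15, 400, 45, 4, 12)
  det <- detect_components(std_trace(v), "DA10")
  expect_equal(det$quality, "ok")
  expect_lte(abs(det$a_time_ms - GRID[which.min(v)]), 0.5)
  expect_lte(abs(det$b_time_ms - GRID[which.max(v)]), 0.5)
  expect_equal(det$a_amp_uV, abs(v[1] - min(v)), tolerance = 0.02)
  expect_equal(det$b_amp_uV, max(v) - min(v), tolerance = 0.02)
  expect_gt(det$b_time_ms, det$a_time_ms)

  flat <- detect_components(std_trace(rep(0, 161)), "DA10")
  expect_equal(flat$quality, "unmeasurable")
  expect_true(is.na(flat$a_amp_uV))

  ## measurement convention: baseline-to-trough and trough-to-peak
  v2 <- -100 * exp(-(GRID - 20)^2 / (2 * 25)) +
    200 * exp(-(GRID - 50)^2 / (2 * 64))
  det2 <- detect_components(std_trace(v2), "DA10")
  expect_equal(det2$a_amp_uV, 100, tolerance = 0.01)
  expect_equal(det2$b_amp_uV, 300, tolerance = 0.01)
})

test_that("minimum-time cutoffs suppress early artifactual extrema", {
  ## an artifactual dip at 3 ms must not be taken as the a-wave
  v <- flash_model(250, 15, 400, 45, 4, 12) -
    80 * exp(-(GRID - 3)^2 / (2 * 1.5^2))
  det <- detect_components(std_trace(v), "DA10")
  expect_gt(det$a_time_ms, 8)
  expect_lte(abs(det$a_time_ms - 15), 1.5)
})

test_that("peak-time estimates are unbiased under zero-phase filtering", {
  ## Monte-Carlo: mean detection error under white noise (sd 5 uV) within
  ## half a grid step
  withr::with_seed(99, {
    v0 <- flash_model(250, 15, 400, 45, 4, 12)
    true_a <- GRID[which.min(v0)]; true_b <- GRID[which.max(v0)]
    errs <- t(replicate(500, {
      det <- detect_components(std_trace(v0 + rnorm(161, sd = 5)), "DA10")
      c(det$a_time_ms - true_a, det$b_time_ms - true_b)
    }))
    expect_lte(abs(mean(errs[, 1])), 0.5)  # one grid step, inclusive: the
    expect_lte(abs(mean(errs[, 2])), 0.5)  # composite trough sits mid-sample
  })
})

test_that("patient summaries average eyes and flag missing stimuli", {
  eye <- data.frame(patient_id = c("P1", "P1"), eye = c("L", "R"),
                    stimulus = "DA10", n_traces = 3L,
                    a_amp_uV = c(100, 110), a_time_ms = c(15, 15),
                    b_amp_uV = c(100, 110), b_time_ms = c(45, 47),
                    peak_amp_uV = NA_real_, peak_time_ms = NA_real_,
                    quality = "ok", stringsAsFactors = FALSE)
  pat <- summarize_patient(eye)
  expect_equal(pat$b_amp_uV, 105)
  expect_equal(pat$b_time_ms, 46)
  expect_equal(pat$n_eyes, 2L)
  ## identical eyes equal either eye; single missing eye uses the other
  eye2 <- eye; eye2$b_amp_uV <- c(100, 100)
  expect_equal(summarize_patient(eye2)$b_amp_uV, 100)
  eye3 <- eye; eye3$quality <- c("missing", "ok"); eye3$b_amp_uV[1] <- NA
  expect_equal(summarize_patient(eye3)$b_amp_uV, 110)
})

test_that("measure_cohort emits b_time > a_time and plausible flags", {
  sim <- generate_cohort(8, wave = default_wave_params(n_repeats = c(3L, 5L)),
                         seed = 21)
  meas <- measure_cohort(sim$traces)
  flash <- meas$eye[meas$eye$stimulus %in% c("DA10", "LA3") &
                      !is.na(meas$eye$b_time_ms), ]
  expect_true(all(flash$b_time_ms > flash$a_time_ms))
  expect_true(all(flash$a_amp_uV >= 0))
  expect_true(all(meas$eye$quality %in%
                    c("ok", "partial", "missing", "two_repeats_only",
                      "single_repeat")))
  ## per-patient rows: one per stimulus per patient
  expect_equal(nrow(meas$patient), 8 * 3)
})
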