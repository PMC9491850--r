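# Synthetic sEMG generator: determinism, envelope structure, planted
# dominant muscles, spectral content, SNR control.

test_that("identical configs give bit-identical recordings and activations", {
  cfg <- synth_config(duration = 4, seed = 11)
  expect_identical(generate_recording(cfg), generate_recording(cfg))
  expect_identical(
    generate_activation("flexion", 10, 1000, seed = 1),
    generate_activation("flexion", 10, 1000, seed = 1)
  )
})

test_that("activation envelopes are bounded, rest at zero, and slow", {
  env <- generate_activation("flexion", 10, 1000, seed = 2)
  expect_true(all(env >= 0 & env <= 1))
  # rest occupies the first 2 s of each 4 s cycle
  expect_true(all(env[1:2000, ] == 0))
  expect_true(all(env[4001:6000, ] == 0))
  expect_gt(max(env), 0)
  # smoothness: >= 99% of envelope power below 5 Hz
  sp <- power_spectrum(env[, 1], 1000, segment_s = 4)
  expect_gt(band_power_fraction(sp, 5), 0.99)
})

test_that("unknown task errors and names the valid tasks", {
  expect_error(generate_activation("wiggle", 10, 1000, 1), "flexion")
  expect_error(synth_config(task = "wiggle"), "supination")
})

test_that("planted dominant channel maximizes mean envelope x weight", {
  for (task in c("flexion", "extension", "pronation", "supination")) {
    w <- task_weights(task)
    env <- generate_activation(task, 20, 1000, seed = 3)
    expect_equal(which.max(colMeans(env) * w), which.max(w),
                 ignore_attr = TRUE)
  }
})

test_that("channel spectra match the configured structure", {
  rec <- fixture_recording()
  fs <- attr(rec, "fs")
  sp <- power_spectrum(rec$BB, fs)
  expect_true(detect_interference(sp, 50)$detected)
  expect_lt(abs(detect_interference(sp, 50)$peak_hz - 50), 1)
  expect_true(detect_interference(sp, 110)$detected)

  clean_cfg <- synth_config(duration = 8, seed = 1, powerline_amplitude = 0,
                            ecg_amplitude = 0)
  rec2 <- generate_recording(clean_cfg)
  expect_gt(band_power_fraction(power_spectrum(rec2$BB, fs), 150), 0.7)
})

test_that("measured SNR matches the configured snr_db within 1 dB", {
  cfg <- synth_config(duration = 30, seed = 5, snr_db = 12)
  cfg_clean <- synth_config(duration = 30, seed = 5, snr_db = Inf)
  noisy <- generate_recording(cfg)
  clean <- generate_recording(cfg_clean)
  for (ch in attr(noisy, "channel_labels")) {
    expect_lt(abs(measure_snr(clean[[ch]], noisy[[ch]]) - 12), 1)
  }
})

test_that("force is invariant to permuting channels with the weight vector", {
  cfg1 <- synth_config(duration = 6, seed = 9)
  perm <- c(2, 4, 1, 3)
  cfg2 <- synth_config(duration = 6, seed = 9,
                       channel_labels = cfg1$channel_labels[perm],
                       weight_vector = cfg1$weight_vector[perm])
  r1 <- generate_recording(cfg1)
  r2 <- generate_recording(cfg2)
  expect_equal(r1$force, r2$force, tolerance = 1e-12)
})

test_that("task suite has four recordings with per-task planted dominants", {
  suite <- generate_task_suite(synth_config(duration = 4, seed = 13))
  expect_named(suite, c("flexion", "extension", "pronation", "supination"))
  durs <- vapply(suite, nrow, integer(1))
  expect_true(all(durs == durs[1]))
  doms <- vapply(names(suite), function(task) {
    names(which.max(task_weights(task)))
  }, character(1))
  expect_equal(unname(doms), c("BB", "TB", "BRD", "BR"))
  # distinct seeds per task produce distinct signals
  expect_false(identical(suite$flexion$BB, suite$extension$BB))
  for (task in names(suite)) {
    w <- attr(suite[[task]], "truth")$weight_vector
    labels <- attr(suite[[task]], "truth")$channel_labels
    expect_equal(labels[which.max(w)], unname(doms[task]))
  }
})

test_that("recording constructor validates shapes", {
  expect_error(new_recording(matrix(0, 5, 2), numeric(4), 100, c("a", "b")),
               "identical length")
  expect_error(new_recording(matrix(0, 5, 2), numeric(5), 100, "a"),
               "labels")
  expect_error(new_recording(matrix(0, 5, 2), numeric(5), 0, c("a", "b")),
               "fs")
  expect_error(generate_recording(synth_config(duration = -1)), "positive")
})
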