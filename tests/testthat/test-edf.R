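test_that("EDF round trip preserves sample count and values to quantization", {
  sim <- generate_recording(sim_config(n_epochs_per_stage = 1, seed = 5,
                                       drift_amplitude = 0))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  rec <- load_recording(paths["edf"], "EEG Fpz-Cz")
  expect_length(rec$samples, length(sim$recording$samples))
  expect_equal(rec$sampling_rate, 100)
  # 16-bit quantization: half a step of the symmetric physical range
  pm <- max(1, ceiling(max(abs(sim$recording$samples))))
  qstep <- 2 * pm / 65535
  expect_lt(max(abs(rec$samples - sim$recording$samples)), qstep)
})

test_that("absent channels and missing files produce informative errors", {
  sim <- generate_recording(sim_config(n_epochs_per_stage = 1, seed = 5))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  expect_error(load_recording(paths["edf"], "EEG Pz-Oz"),
               "available: EEG Fpz-Cz")
  expect_error(load_recording(file.path(d, "nope.edf")), "not found")
})

test_that("a 200 Hz recording is resampled to 100 Hz preserving band power", {
  set.seed(31)
  t200 <- seq_len(12000) / 200            # 60 s at 200 Hz
  x <- 40 * sin(2 * pi * 10 * t200) + 15 * sin(2 * pi * 3 * t200) +
    rnorm(12000, sd = 0.5)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, signals = list(list(samples = x, sampling_rate = 200,
                                   label = "EEG Fpz-Cz")))
  rec <- load_recording(f, "EEG Fpz-Cz")
  expect_length(rec$samples, 6000)
  expect_equal(rec$sampling_rate, 100)
  # band power below the new Nyquist must be preserved (brute-force
  # periodogram of the pre-write signal as oracle)
  for (b in list(c(8, 12), c(2, 4))) {
    # |fft|^2 scales with n^2 for a line component; normalize it away
    p_orig <- band_power_abs(x, b[1], b[2], rate = 200) / 12000^2
    p_new <- band_power_abs(rec$samples, b[1], b[2], rate = 100) / 6000^2
    expect_equal(p_new, p_orig, tolerance = 0.05)
  }
})

test_that("EDF+ annotations round-trip through the annotation track", {
  sim <- generate_recording(sim_config(n_epochs_per_stage = 2, seed = 8))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  rec <- load_recording(paths["edf"])
  expect_equal(rec$annotations$onset_s, sim$annotations$onset_s)
  expect_equal(rec$annotations$duration_s, sim$annotations$duration_s)
  expect_identical(rec$annotations$raw_stage, sim$annotations$raw_stage)
})

test_that("the mne EDF reader agrees with the writer (independent oracle)", {
  sim <- generate_recording(sim_config(n_epochs_per_stage = 1, seed = 13))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d, basename = "oracle")
  script <- sprintf(paste0(
    "import mne, numpy as np, json\n",
    "raw = mne.io.read_raw_edf(%s, preload=True, verbose='error')\n",
    "x = raw.get_data()[0] * 1e6\n",
    "print(json.dumps({'sfreq': raw.info['sfreq'], 'n': int(raw.n_times),\n",
    "  'first': list(np.round(x[:10], 3)),\n",
    "  'ann': [[a['onset'], a['duration'], a['description']]\n",
    "          for a in raw.annotations]}))\n"),
    deparse(unname(paths["edf"])))
  out <- system2("python", "-", stdout = TRUE, stderr = FALSE, input = script)
  res <- jsonlite::fromJSON(out[length(out)])
  expect_equal(res$sfreq, 100)
  expect_equal(res$n, length(sim$recording$samples))
  expect_equal(res$first, round(sim$recording$samples[1:10], 3),
               tolerance = 0.02)
  expect_equal(res$ann[, 1], as.character(sim$annotations$onset_s))
  expect_identical(res$ann[, 3], sim$annotations$raw_stage)
})

test_that("hypnogram expansion distributes durations and merges stages", {
  ann <- data.frame(onset_s = c(0, 60), duration_s = c(60, 30),
                    raw_stage = c("Sleep stage 3", "Sleep stage 4"))
  out <- expand_hypnogram(ann, total_epochs = 3)
  expect_identical(out$stage, c("N3", "N3", "N3"))
  expect_identical(out$epoch_index, 0:2)

  one <- expand_hypnogram(data.frame(onset_s = 0, duration_s = 30,
                                     raw_stage = "Sleep stage W"),
                          total_epochs = 1)
  expect_identical(one$stage, "W")
  mov <- expand_hypnogram(data.frame(onset_s = 0, duration_s = 30,
                                     raw_stage = "Movement time"),
                          total_epochs = 1)
  expect_identical(mov$stage, "DROP")
})

test_that("hypnogram expansion rejects gaps, overlaps and unknown tokens", {
  gap <- data.frame(onset_s = c(0, 90), duration_s = c(30, 30),
                    raw_stage = c("Sleep stage W", "Sleep stage 1"))
  expect_error(expand_hypnogram(gap, total_epochs = 4), "gap.*30.*90")
  bad <- data.frame(onset_s = 0, duration_s = 30, raw_stage = "stageX")
  expect_error(expand_hypnogram(bad, total_epochs = 1), "stageX")
  short <- data.frame(onset_s = 0, duration_s = 60,
                      raw_stage = "Sleep stage W")
  expect_error(expand_hypnogram(short, total_epochs = 4), "covers only 2")
  # output always covers each epoch exactly once
  ann <- data.frame(onset_s = c(0, 30), duration_s = c(30, 90),
                    raw_stage = c("Sleep stage W", "Sleep stage 2"))
  out <- expand_hypnogram(ann, total_epochs = 4)
  expect_identical(out$epoch_index, 0:3)
  expect_false(any(duplicated(out$epoch_index)))
})

test_that("hypnogram CSV dialect round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  stages <- c("W", "N1", "N2", "N3", "REM", "N2")
  write_hypnogram_csv(f, stages)
  back <- read_hypnogram_csv(f)
  expect_identical(back$stage, stages)
  expect_identical(back$epoch_index, 0:5)
})

test_that("epoch dataset container round-trips", {
  ds <- tiny_dataset(n_per_stage = 1)
  stem <- file.path(withr::local_tempdir(), "ds")
  write_epoch_dataset(ds, stem)
  back <- read_epoch_dataset(stem)
  expect_equal(length(back$epochs), length(ds$epochs))
  expect_identical(vapply(back$epochs, `[[`, "", "label"),
                   vapply(ds$epochs, `[[`, "", "label"))
  expect_equal(back$epochs[[3]]$samples, ds$epochs[[3]]$samples)
})
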