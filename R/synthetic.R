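# Synthetic polysomnography generator. Emulates the stage-dependent
# spectral structure of single-channel sleep EEG (delta-dominant N3,
# alpha-dominant relaxed wake, theta N1, spindle-marked N2, mixed
# low-amplitude REM with a slow sawtooth component) plus slow baseline
# drift, so the full preprocessing/training pipeline is testable
# without real recordings. Not a physiological simulator: only the
# band-power statistics the encoder and the preprocessing act on.

EPOCH_SAMPLES <- 3000L
SAMPLING_RATE <- 100

#' Default per-stage spectral parameterizations
#'
#' Each stage is described by a set of oscillatory band components
#' `(low Hz, high Hz, relative amplitude)`, a broadband Gaussian noise
#' level, and an overall amplitude scale in microvolts. The dominant
#' band is unique per stage: alpha (8-13 Hz) for W, theta (4-8 Hz) for
#' N1, theta plus 12-14 Hz spindle bursts for N2, high-amplitude delta
#' (0.5-4 Hz) for N3, and low-amplitude mixed theta with a 2-3 Hz
#' sawtooth component for REM.
#'
#' @return Named list (W, N1, N2, N3, REM) of `stage_spectrum` lists
#'   with fields `stage`, `bands` (matrix with columns low, high,
#'   amplitude), `noise_sd`, `amplitude`, and for N2 a `spindle` spec.
#' @export
default_stage_spectra <- function() {
  spec <- function(stage, bands, noise_sd, amplitude, spindle = NULL,
                   sawtooth = NULL) {
    b <- matrix(unlist(bands), ncol = 3, byrow = TRUE,
                dimnames = list(NULL, c("low", "high", "amplitude")))
    stopifnot(all(b[, "low"] > 0), all(b[, "high"] < 50))
    structure(list(stage = stage, bands = b, noise_sd = noise_sd,
                   amplitude = amplitude, spindle = spindle,
                   sawtooth = sawtooth),
              class = "stage_spectrum")
  }
  # Dominant bands are pairwise distinct so stages are separable by
  # band power alone: alpha (W), theta (N1), sigma/spindle (N2), delta
  # (N3), and a slow 2-3 Hz sawtooth with moderate theta (REM).
  list(
    W   = spec("W",   list(c(8, 13, 1.0), c(18, 30, 0.3)),
               noise_sd = 0.45, amplitude = 30),
    N1  = spec("N1",  list(c(4, 8, 1.0), c(8, 13, 0.3)),
               noise_sd = 0.45, amplitude = 35),
    N2  = spec("N2",  list(c(12, 14, 1.0), c(4, 8, 0.4)),
               noise_sd = 0.40, amplitude = 45,
               spindle = list(low = 12, high = 14, amplitude = 1.6,
                              dur_range_s = c(0.5, 1.0), rate_per_epoch = 4)),
    N3  = spec("N3",  list(c(0.5, 4, 1.0), c(4, 8, 0.15)),
               noise_sd = 0.30, amplitude = 110),
    REM = spec("REM", list(c(4, 8, 0.6)),
               noise_sd = 0.50, amplitude = 25,
               sawtooth = list(low = 2, high = 3, amplitude = 1.0))
  )
}

#' Dominant spectral band of a stage spectrum
#'
#' The band component with the largest relative amplitude among the
#' sustained components (oscillatory bands plus, for REM, the slow
#' sawtooth); transient spindle packets are not counted as sustained.
#'
#' @param spectrum A `stage_spectrum` from [default_stage_spectra()].
#' @return Numeric `c(low, high)` in Hz.
#' @export
dominant_band <- function(spectrum) {
  stopifnot(inherits(spectrum, "stage_spectrum"))
  bands <- spectrum$bands[, , drop = FALSE]
  lows <- bands[, "low"]; highs <- bands[, "high"]; amps <- bands[, "amplitude"]
  if (!is.null(spectrum$sawtooth)) {
    lows <- c(lows, spectrum$sawtooth$low)
    highs <- c(highs, spectrum$sawtooth$high)
    amps <- c(amps, spectrum$sawtooth$amplitude)
  }
  k <- which.max(amps)
  c(low = unname(lows[k]), high = unname(highs[k]))
}

# sum of a few random-phase sinusoids spanning a band
.band_oscillator <- function(n, rate, low, high, amplitude, n_comp = 4L) {
  t <- seq_len(n) / rate
  freqs <- stats::runif(n_comp, low, high)
  phases <- stats::runif(n_comp, 0, 2 * pi)
  amps <- amplitude * (0.5 + stats::runif(n_comp)) / n_comp
  x <- numeric(n)
  for (i in seq_len(n_comp)) {
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
  }
  x
}

#' Generate one synthetic 30-s EEG epoch
#'
#' Draws a 3000-sample signal (30 s at 100 Hz) as a sum of random-phase
#' band oscillators plus Gaussian broadband noise, parameterized by the
#' stage's spectrum; N2 additionally receives Hann-windowed 12-14 Hz
#' spindle packets and REM a slow sawtooth component. Uses the current
#' global RNG state, so results are reproducible under [set.seed()].
#'
#' @param stage Stage name, one of [stage_levels()].
#' @param spectra Spectra map as from [default_stage_spectra()].
#' @return List with `samples` (numeric length 3000, microvolts) and
#'   `label` (the stage name).
#' @export
generate_epoch <- function(stage, spectra = default_stage_spectra()) {
  sp <- spectra[[stage]]
  if (is.null(sp)) stop("unknown stage: ", stage)
  n <- EPOCH_SAMPLES
  x <- numeric(n)
  for (i in seq_len(nrow(sp$bands))) {
    b <- sp$bands[i, ]
    x <- x + .band_oscillator(n, SAMPLING_RATE, b["low"], b["high"],
                              b["amplitude"])
  }
  if (!is.null(sp$spindle)) {
    k <- stats::rpois(1, sp$spindle$rate_per_epoch)
    for (j in seq_len(k)) {
      dur <- stats::runif(1, sp$spindle$dur_range_s[1], sp$spindle$dur_range_s[2])
      len <- round(dur * SAMPLING_RATE)
      start <- sample.int(n - len, 1)
      f <- stats::runif(1, sp$spindle$low, sp$spindle$high)
      tt <- seq_len(len) / SAMPLING_RATE
      packet <- sp$spindle$amplitude *
        sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)) *
        (0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1)))  # Hann
      x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] + packet
    }
  }
  if (!is.null(sp$sawtooth)) {
    f <- stats::runif(1, sp$sawtooth$low, sp$sawtooth$high)
    ph <- stats::runif(1)
    tt <- seq_len(n) / SAMPLING_RATE
    x <- x + sp$sawtooth$amplitude * (2 * ((f * tt + ph) %% 1) - 1)
  }
  x <- x + stats::rnorm(n, sd = sp$noise_sd)
  list(samples = sp$amplitude * x, label = stage)
}

#' Simulation configuration
#'
#' @param n_epochs_per_stage Epochs generated per stage when no
#'   explicit `stage_sequence` is given.
#' @param seed Integer seed; a fixed seed makes the whole recording
#'   byte-reproducible.
#' @param drift_amplitude Microvolts of slow sinusoidal baseline drift
#'   (plus a linear ramp of the same scale across the recording).
#' @param drift_period_s Drift period in seconds (default 50 s,
#'   i.e. 0.02 Hz).
#' @param stage_sequence Optional explicit per-epoch stage name vector;
#'   overrides `n_epochs_per_stage`.
#' @param shuffle Shuffle the default stage plan (TRUE) or keep stages
#'   blocked in code order.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_epochs_per_stage = 20L, seed = 1L,
                       drift_amplitude = 50, drift_period_s = 50,
                       stage_sequence = NULL, shuffle = TRUE) {
  structure(list(n_epochs_per_stage = as.integer(n_epochs_per_stage),
                 seed = as.integer(seed),
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 stage_sequence = stage_sequence,
                 shuffle = isTRUE(shuffle)),
            class = "sim_config")
}

#' Generate a stage-labelled synthetic recording
#'
#' Concatenates per-stage epochs along a (shuffled or explicit)
#' hypnogram, adds slow sinusoidal-plus-ramp baseline drift, and
#' returns the raw signal together with hypnogram annotations in which
#' consecutive same-stage epochs are merged into single entries.
#'
#' @param config A [sim_config()].
#' @param spectra Spectra map, default [default_stage_spectra()].
#' @return List with `recording` (list: samples, sampling_rate,
#'   channel_name, start_time), `annotations` (data frame onset_s,
#'   duration_s, raw_stage), `stages` (per-epoch stage names) and
#'   `config`.
#' @export
generate_recording <- function(config = sim_config(),
                               spectra = default_stage_spectra()) {
  stages <- config$stage_sequence
  if (is.null(stages)) {
    if (config$n_epochs_per_stage < 1L) stop("empty simulation plan")
    stages <- rep(stage_levels(), each = config$n_epochs_per_stage)
  }
  if (length(stages) == 0L) stop("empty simulation plan")
  if (!all(stages %in% stage_levels())) stop("invalid stage in sequence")
  set.seed(config$seed)
  if (is.null(config$stage_sequence) && config$shuffle) {
    stages <- sample(stages)
  }
  n_ep <- length(stages)
  samples <- numeric(n_ep * EPOCH_SAMPLES)
  for (i in seq_len(n_ep)) {
    ep <- generate_epoch(stages[i], spectra)
    samples[((i - 1L) * EPOCH_SAMPLES + 1L):(i * EPOCH_SAMPLES)] <- ep$samples
  }
  if (config$drift_amplitude > 0) {
    t <- seq_along(samples) / SAMPLING_RATE
    drift <- config$drift_amplitude *
      (sin(2 * pi * t / config$drift_period_s) + t / max(t) - 0.5)
    samples <- samples + drift
  }
  # merge consecutive identical stages into annotation runs
  r <- rle(stages)
  ends <- cumsum(r$lengths)
  onsets <- (ends - r$lengths) * 30
  ann <- data.frame(onset_s = onsets, duration_s = r$lengths * 30,
                    raw_stage = stage_to_token(r$values),
                    stringsAsFactors = FALSE)
  list(recording = list(samples = samples, sampling_rate = SAMPLING_RATE,
                        channel_name = "EEG Fpz-Cz", start_time = 0),
       annotations = ann, stages = stages, config = config)
}

#' Write a simulated recording to disk
#'
#' Writes the EDF (with the hypnogram embedded as an EDF+ annotation
#' track), a 2-column hypnogram CSV (`epoch_index,stage`) and a JSON
#' manifest recording the seed and configuration.
#'
#' @param sim Result of [generate_recording()].
#' @param dir Output directory, created if missing.
#' @param basename File stem for the three outputs.
#' @return Invisibly, named paths `edf`, `hypnogram`, `manifest`.
#' @export
write_simulation <- function(sim, dir, basename = "synthetic_psg") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edf_path <- file.path(dir, paste0(basename, ".edf"))
  csv_path <- file.path(dir, paste0(basename, "_hypnogram.csv"))
  man_path <- file.path(dir, paste0(basename, "_manifest.json"))
  write_edf(edf_path,
            signals = list(list(samples = sim$recording$samples,
                                sampling_rate = sim$recording$sampling_rate,
                                label = sim$recording$channel_name,
                                physical_dim = "uV")),
            annotations = sim$annotations)
  write_hypnogram_csv(csv_path, sim$stages)
  cfg <- sim$config
  cfg$stage_sequence <- NULL
  jsonlite::write_json(list(tool = "sleepcontrast",
                            version = as.character(utils::packageVersion("sleepcontrast")),
                            seed = cfg$seed, config = unclass(cfg),
                            n_epochs = length(sim$stages)),
                       man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(edf = edf_path, hypnogram = csv_path, manifest = man_path))
}

#' Generate a model-ready synthetic epoch dataset in memory
#'
#' Convenience wrapper: simulates epochs (no drift, no trimming) and
#' packages them as the epoch dataset used by training. Epochs are
#' z-scored like the preprocessing output.
#'
#' @param n_epochs_per_stage Epochs per stage.
#' @param seed Integer seed.
#' @param spectra Spectra map.
#' @return An `epoch_dataset` (see [build_dataset()]).
#' @export
simulate_dataset <- function(n_epochs_per_stage = 20L, seed = 1L,
                             spectra = default_stage_spectra()) {
  set.seed(seed)
  stages <- sample(rep(stage_levels(), each = n_epochs_per_stage))
  eps <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    ep <- generate_epoch(stages[i], spectra)
    eps[[i]] <- list(samples = .zscore_epoch(ep$samples), label = stages[i],
                     source_epoch_index = i - 1L)
  }
  .new_epoch_dataset(eps)
}
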