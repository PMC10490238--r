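# EDF/EDF+ input and output, hypnogram expansion, and epoch-dataset
# serialization.
#
# EDF stores each signal as 16-bit integers in fixed-duration data
# records, with ASCII headers of 256 bytes plus 256 per signal. EDF+
# adds an "EDF Annotations" signal whose payload is a sequence of
# time-stamped annotation lists (TALs): "+onset\x15duration\x14text\x14\x00",
# each record opening with a bare "+onset\x14\x14\x00" timestamp. Only
# the subset needed for single-channel PSG work is implemented:
# continuous (EDF+C) recordings, one annotation track, 16-bit samples.

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width)
}

.num_ascii <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  if (nchar(s) > 8) s <- substr(format(x, scientific = FALSE, digits = 7), 1, 8)
  s
}

#' Write an EDF or EDF+ file
#'
#' Writes one or more uniformly sampled signals as 16-bit EDF with
#' 1-second data records. When `annotations` is supplied, an
#' "EDF Annotations" track is appended and the file is marked EDF+C,
#' so hypnograms round-trip through the annotation channel.
#'
#' @param path Output file path.
#' @param signals List of signals, each a list with `samples` (numeric
#'   vector), `sampling_rate` (integer Hz; the sample count must be a
#'   multiple of it), `label` (channel name) and optional
#'   `physical_dim` (default "uV").
#' @param annotations Optional data frame with columns `onset_s`,
#'   `duration_s`, `raw_stage` (annotation text).
#' @param start_datetime POSIXct recording start (header only).
#' @return Invisibly, `path`.
#' @export
write_edf <- function(path, signals, annotations = NULL,
                      start_datetime = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  stopifnot(length(signals) >= 1)
  rates <- vapply(signals, function(s) s$sampling_rate, numeric(1))
  lens <- vapply(signals, function(s) length(s$samples), numeric(1))
  if (any(lens %% rates != 0)) {
    stop("signal lengths must be whole seconds (multiple of sampling rate)")
  }
  n_records <- unique(lens / rates)
  if (length(n_records) != 1) stop("all signals must span the same duration")
  n_records <- as.integer(n_records)

  # digitize each ordinary signal to int16 with a symmetric physical range
  dig <- lapply(signals, function(s) {
    pm <- max(1, ceiling(max(abs(s$samples))))
    d <- as.integer(round((s$samples + pm) * 65535 / (2 * pm)) - 32768)
    d[d > 32767L] <- 32767L; d[d < -32768L] <- -32768L
    list(d = d, phys_min = -pm, phys_max = pm)
  })

  # annotation track: all annotation TALs live in the first record
  has_ann <- !is.null(annotations) && nrow(annotations) > 0
  ann_payload <- NULL
  if (has_ann) {
    tal_raw <- function(s) c(charToRaw(s), as.raw(0))  # NUL-terminated TAL
    tals <- do.call(c, lapply(seq_len(nrow(annotations)), function(i) {
      tal_raw(paste0("+", .num_ascii(annotations$onset_s[i]), "\x15",
                     .num_ascii(annotations$duration_s[i]), "\x14",
                     annotations$raw_stage[i], "\x14"))
    }))
    recs <- lapply(seq_len(n_records), function(r) {
      c(tal_raw(paste0("+", .num_ascii(r - 1), "\x14\x14")),
        if (r == 1L) tals else raw(0))
    })
    max_bytes <- max(lengths(recs))
    spr_ann <- as.integer(ceiling(max_bytes / 2))
    ann_payload <- lapply(recs, function(b) c(b, raw(2L * spr_ann - length(b))))
  }

  ns <- length(signals) + has_ann
  header_bytes <- 256L * (1L + ns)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(.pad(s, w)), con)
  wr("0", 8)
  wr("X X X X", 80)                                   # local patient id
  wr("Startdate X X X X", 80)                         # local recording id
  wr(format(start_datetime, "%d.%m.%y"), 8)
  wr(format(start_datetime, "%H.%M.%S"), 8)
  wr(header_bytes, 8)
  wr(if (has_ann) "EDF+C" else "", 44)
  wr(n_records, 8)
  wr("1", 8)                                          # record duration, s
  wr(ns, 4)

  labels <- c(vapply(signals, `[[`, "", "label"),
              if (has_ann) "EDF Annotations")
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                   # transducer
  for (i in seq_len(ns)) {
    wr(if (i <= length(signals))
         (signals[[i]]$physical_dim %||% "uV") else "", 8)
  }
  for (i in seq_len(ns)) wr(if (i <= length(signals)) dig[[i]]$phys_min else -1, 8)
  for (i in seq_len(ns)) wr(if (i <= length(signals)) dig[[i]]$phys_max else 1, 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)                   # prefilter
  sprs <- c(as.integer(rates), if (has_ann) spr_ann)
  for (s in sprs) wr(s, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_records)) {
    for (i in seq_along(signals)) {
      idx <- ((r - 1L) * rates[i] + 1L):(r * rates[i])
      writeBin(dig[[i]]$d[idx], con, size = 2L, endian = "little")
    }
    if (has_ann) writeBin(ann_payload[[r]], con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an EDF or EDF+ file
#'
#' Parses the header, all ordinary signals (scaled to physical units)
#' and, if present, the "EDF Annotations" track as a data frame of
#' annotations.
#'
#' @param path Path to an EDF/EDF+ file.
#' @return List with `header` (n_records, record_duration_s,
#'   start_date, start_time, reserved), `signals` (list per channel:
#'   `label`, `sampling_rate`, `samples`, `physical_dim`) and
#'   `annotations` (data frame onset_s, duration_s, raw_stage; zero
#'   rows when absent).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  rd(80); rd(80)
  start_date <- rd(8); start_time <- rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  phys_dim <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  data <- readBin(con, "raw", n = 2L * n_records * sum(spr))
  offsets <- c(0L, cumsum(2L * spr))
  rec_bytes <- 2L * sum(spr)

  signals <- list()
  annotations_raw <- raw(0)
  for (i in seq_len(ns)) {
    chunks <- lapply(seq_len(n_records) - 1L, function(r) {
      a <- r * rec_bytes + offsets[i]
      data[(a + 1L):(a + 2L * spr[i])]
    })
    bytes <- do.call(c, chunks)
    if (is_ann[i]) {
      annotations_raw <- bytes
    } else {
      d <- readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                   endian = "little", signed = TRUE)
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      signals[[length(signals) + 1L]] <- list(
        label = labels[i],
        sampling_rate = spr[i] / record_dur,
        samples = (d - dig_min[i]) * gain + phys_min[i],
        physical_dim = phys_dim[i])
    }
  }

  ann <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                    raw_stage = character(0), stringsAsFactors = FALSE)
  if (length(annotations_raw)) ann <- .parse_tals(annotations_raw)

  list(header = list(n_records = n_records, record_duration_s = record_dur,
                     start_date = start_date, start_time = start_time,
                     reserved = reserved),
       signals = signals, annotations = ann)
}

# Split a raw TAL stream into (onset, duration, text) records.
.parse_tals <- function(bytes) {
  # TALs are NUL-terminated; split on NUL before any string conversion
  nul <- which(bytes == as.raw(0))
  bounds <- c(0L, nul)
  parts <- character(0)
  for (j in seq_len(length(bounds) - 1L)) {
    a <- bounds[j] + 1L; b <- bounds[j + 1L] - 1L
    parts <- c(parts, if (b >= a) rawToChar(bytes[a:b]) else "")
  }
  out <- list()
  for (p in parts) {
    if (!nzchar(p)) next
    fields <- strsplit(p, "\x14", fixed = TRUE)[[1]]
    head <- fields[1]
    texts <- fields[-1]
    texts <- texts[nzchar(texts)]
    if (!length(texts)) next                     # bare timestamp TAL
    od <- strsplit(head, "\x15", fixed = TRUE)[[1]]
    onset <- as.numeric(od[1])
    dur <- if (length(od) > 1) as.numeric(od[2]) else 0
    for (tx in texts) {
      out[[length(out) + 1L]] <- data.frame(onset_s = onset, duration_s = dur,
                                            raw_stage = tx,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      raw_stage = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Load one EEG channel from an EDF recording
#'
#' Extracts the named channel and resamples it to 100 Hz (polyphase
#' resampling via [signal::resample()]) when the native rate differs.
#' All downstream architecture constants (0.64 s and 5.12 s convolution
#' windows, 3000-sample epochs) assume 100 Hz.
#'
#' @param path EDF/EDF+ file path.
#' @param channel Channel label, e.g. `"EEG Fpz-Cz"`.
#' @return List with `samples`, `sampling_rate` (always 100),
#'   `channel_name`, `start_time` (0) and `annotations` from the file.
#' @export
load_recording <- function(path, channel = "EEG Fpz-Cz") {
  edf <- read_edf(path)
  labs <- vapply(edf$signals, `[[`, "", "label")
  k <- match(channel, labs)
  if (is.na(k)) {
    stop("channel '", channel, "' not found; available: ",
         paste(labs, collapse = ", "))
  }
  sig <- edf$signals[[k]]
  x <- sig$samples
  rate <- sig$sampling_rate
  if (rate != SAMPLING_RATE) {
    if (rate %% 1 != 0) stop("non-integer sampling rate not supported")
    g <- .gcd(SAMPLING_RATE, as.integer(rate))
    x <- .resample_poly(x, SAMPLING_RATE / g, as.integer(rate) / g)
    rate <- SAMPLING_RATE
  }
  list(samples = as.numeric(x), sampling_rate = rate,
       channel_name = channel, start_time = 0,
       annotations = edf$annotations)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# Polyphase rational resampling by p/q: zero-stuff by p, apply a
# windowed-sinc FIR low-pass (cut just below the narrower Nyquist,
# designed with signal::fir1), decimate by q. Reflection padding
# suppresses edge transients and the FIR group delay is compensated,
# so output sample j sits at time (j-1)*q/(p*rate_in) like the input's
# own clock.
.resample_poly <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  n_out <- round(length(x) * p / q)
  ord <- 2L * 30L * max(p, q)
  h <- p * signal::fir1(ord, 0.98 / max(p, q))
  xu <- numeric(length(x) * p)
  xu[seq(1L, length(xu), by = p)] <- x
  pad <- ord
  xp <- c(rev(xu[2:(pad + 1L)]), xu,
          rev(xu[(length(xu) - pad):(length(xu) - 1L)]))
  yf <- signal::fftfilt(h, c(xp, numeric(ord)))
  yc <- yf[(ord / 2 + pad + 1L):(ord / 2 + pad + length(xu))]
  yc[seq(1L, length(xu), by = q)][seq_len(n_out)]
}

#' Expand hypnogram annotations to per-epoch labels
#'
#' Each annotation of duration D contributes floor(D / epoch_s)
#' consecutive epoch labels, with stages 3 and 4 merged into N3 and
#' movement/unscored tokens mapped to `"DROP"`. Annotations must be
#' sorted, non-overlapping and gap-free, and must cover all
#' `total_epochs` epochs.
#'
#' @param annotations Data frame with columns `onset_s`, `duration_s`,
#'   `raw_stage`.
#' @param epoch_s Epoch length in seconds (default 30).
#' @param total_epochs Number of epochs to label.
#' @return Data frame `epoch_index` (0-based), `stage` (stage name or
#'   `"DROP"`).
#' @export
expand_hypnogram <- function(annotations, epoch_s = 30, total_epochs) {
  stopifnot(total_epochs >= 1)
  if (nrow(annotations) == 0) stop("no annotations")
  o <- order(annotations$onset_s)
  annotations <- annotations[o, ]
  if (any(annotations$duration_s <= 0)) stop("non-positive annotation duration")
  ends <- annotations$onset_s + annotations$duration_s
  starts <- annotations$onset_s
  if (nrow(annotations) > 1) {
    gap <- which(abs(starts[-1] - ends[-nrow(annotations)]) > 1e-9)
    if (length(gap)) {
      if (starts[gap[1] + 1] < ends[gap[1]]) {
        stop(sprintf("overlapping annotations at %g s", starts[gap[1] + 1]))
      }
      stop(sprintf("gap in hypnogram between %g s and %g s",
                   ends[gap[1]], starts[gap[1] + 1]))
    }
  }
  stages <- stage_from_token(annotations$raw_stage)  # errors on unknown token
  labels <- rep(stages, times = floor(annotations$duration_s / epoch_s))
  if (length(labels) < total_epochs) {
    stop(sprintf("hypnogram covers only %d of %d epochs (gap from %g s)",
                 length(labels), total_epochs, ends[nrow(annotations)]))
  }
  data.frame(epoch_index = seq_len(total_epochs) - 1L,
             stage = labels[seq_len(total_epochs)],
             stringsAsFactors = FALSE)
}

#' Read and write the 2-column hypnogram CSV dialect
#'
#' The CSV has a header row and columns `epoch_index` (0-based,
#' complete and consecutive) and `stage` (any token accepted by
#' [stage_from_token()]).
#'
#' @param path CSV file path.
#' @param stages Character vector of per-epoch stage names (or
#'   `"DROP"`) to write, in epoch order.
#' @return `read_hypnogram_csv()`: data frame `epoch_index`, `stage`
#'   with stage names normalized via the dialect mapping.
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV needs columns epoch_index,stage")
  }
  df <- df[order(df$epoch_index), ]
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)) - 1L)) {
    stop("epoch_index must be consecutive starting at 0")
  }
  data.frame(epoch_index = as.integer(df$epoch_index),
             stage = stage_from_token(as.character(df$stage)),
             stringsAsFactors = FALSE)
}

#' @rdname read_hypnogram_csv
#' @export
write_hypnogram_csv <- function(path, stages) {
  utils::write.csv(data.frame(epoch_index = seq_along(stages) - 1L,
                              stage = stages),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize and restore an epoch dataset
#'
#' Container format v1: `<stem>.csv` holds one row per epoch
#' (`epoch_index`, `stage_code`), `<stem>.bin` the concatenated epoch
#' samples as little-endian float64, and `<stem>.json` a manifest with
#' the format version and epoch geometry.
#'
#' @param dataset An `epoch_dataset` (see [build_dataset()]).
#' @param stem Path stem; three files are written next to it.
#' @return `write_epoch_dataset()` invisibly returns the stem;
#'   `read_epoch_dataset()` returns the restored `epoch_dataset`.
#' @export
write_epoch_dataset <- function(dataset, stem) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  labs <- vapply(dataset$epochs, `[[`, "", "label")
  idx <- vapply(dataset$epochs, `[[`, 0L, "source_epoch_index")
  utils::write.csv(data.frame(epoch_index = idx, stage_code = stage_code(labs)),
                   paste0(stem, ".csv"), row.names = FALSE, quote = FALSE)
  con <- file(paste0(stem, ".bin"), "wb")
  for (e in dataset$epochs) writeBin(e$samples, con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(format = "sleepcontrast-epochs", version = 1L,
                            n_epochs = length(dataset$epochs),
                            epoch_samples = EPOCH_SAMPLES),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_epoch_dataset
#' @export
read_epoch_dataset <- function(stem) {
  man <- jsonlite::read_json(paste0(stem, ".json"))
  if (!identical(man$format, "sleepcontrast-epochs") || man$version != 1) {
    stop("unrecognized epoch dataset container")
  }
  meta <- utils::read.csv(paste0(stem, ".csv"))
  con <- file(paste0(stem, ".bin"), "rb")
  x <- readBin(con, "double", n = man$n_epochs * man$epoch_samples,
               size = 8, endian = "little")
  close(con)
  eps <- lapply(seq_len(man$n_epochs), function(i) {
    list(samples = x[((i - 1) * man$epoch_samples + 1):(i * man$epoch_samples)],
         label = stage_name(meta$stage_code[i]),
         source_epoch_index = as.integer(meta$epoch_index[i]))
  })
  .new_epoch_dataset(eps)
}
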