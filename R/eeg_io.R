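#' Continuous multichannel EEG record
#'
#' The package-internal container for continuous EEG. All readers produce it
#' and every downstream stage consumes it. Data are stored in microvolts as a
#' channels x samples matrix; event onsets are 0-based sample offsets into the
#' record (the convention of both EDF+ annotations and BrainVision markers as
#' read by this package).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in samples/second.
#' @param channel_names Character vector of unique 10-20 channel labels.
#' @param events Tibble with columns `sample` (0-based integer offset) and
#'   `code` (character), or `NULL` for none.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(data, rate, channel_names, events = NULL) {
  data <- as.matrix(data)
  assert_that(is.numeric(data), "data must be a numeric matrix")
  assert_that(all(is.finite(data)), "data contains non-finite values",
              class = "format_error")
  assert_that(length(rate) == 1 && rate > 0, "rate must be a positive scalar")
  assert_that(length(channel_names) == nrow(data),
              "one channel name per data row is required")
  assert_that(!anyDuplicated(norm_channel(channel_names)),
              "channel names must be unique")
  if (is.null(events)) {
    events <- tibble::tibble(sample = integer(), code = character())
  }
  events <- tibble::as_tibble(events)
  assert_that(all(c("sample", "code") %in% names(events)),
              "events need columns sample and code")
  assert_that(all(events$sample >= 0 & events$sample < ncol(data)),
              "event sample offsets must lie within [0, n_samples)")
  structure(
    list(data = data, rate = rate,
         channel_names = as.character(channel_names), events = events),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Look up a channel index by name
#'
#' Matching is case-insensitive and ignores whitespace.
#' @param record A [signal_record()].
#' @param channel Channel label.
#' @return Integer index into the record's rows.
#' @export
channel_index <- function(record, channel) {
  idx <- match(norm_channel(channel), norm_channel(record$channel_names))
  assert_that(!is.na(idx), sprintf("channel '%s' not found", channel),
              class = "lookup_error")
  idx
}

# ---------------------------------------------------------------------------
# EDF / EDF+
# ---------------------------------------------------------------------------

edf_field <- function(raw, off, len) chr_trim(rawToChar(raw[(off + 1):(off + len)]))

edf_num <- function(raw, off, len, what) {
  s <- edf_field(raw, off, len)
  v <- suppressWarnings(as.numeric(s))
  assert_that(length(v) == 1 && !is.na(v),
              sprintf("EDF header field '%s' is not numeric ('%s')", what, s),
              class = "format_error")
  v
}

unit_scale <- function(dim) {
  d <- tolower(chr_trim(dim))
  if (d %in% c("uv", "µv", "microvolt", "microvolts", "")) 1
  else if (d == "mv") 1e3
  else if (d == "v") 1e6
  else 1
}

#' Read an EDF/EDF+ file
#'
#' Reads continuous 16-bit EDF data, converting to microvolts with the header
#' scaling. An "EDF Annotations" signal, if present, is parsed into events
#' (onset seconds are converted to 0-based sample offsets at the data rate).
#' All ordinary signals must share one sampling rate.
#'
#' @param path Path to an EDF file.
#' @return A [signal_record()].
#' @export
read_edf <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              class = "io_error")
  raw <- readBin(path, "raw", n = file.size(path))
  assert_that(length(raw) >= 256, "EDF header truncated", class = "format_error")
  version <- edf_field(raw, 0, 8)
  assert_that(version == "0",
              sprintf("EDF header field 'version' must be '0', got '%s'", version),
              class = "format_error")
  header_bytes <- edf_num(raw, 184, 8, "header bytes")
  n_records <- edf_num(raw, 236, 8, "number of data records")
  record_dur <- edf_num(raw, 244, 8, "record duration")
  ns <- edf_num(raw, 252, 4, "number of signals")
  assert_that(ns >= 1, "EDF file declares no signals", class = "format_error")
  ns <- as.integer(ns)

  # per-signal header fields are stored field-major; byte offsets of each
  # field block relative to byte 256: label 16, transducer 80, dim 8,
  # phys_min/max 8+8, dig_min/max 8+8, prefilter 80, samples-per-record 8
  field_off <- c(label = 0, transducer = 16, dim = 96, phys_min = 104,
                 phys_max = 112, dig_min = 120, dig_max = 128,
                 prefilter = 136, spr = 216)
  getf <- function(name, len, numeric = FALSE) {
    base <- 256 + field_off[[name]] * ns
    vapply(seq_len(ns) - 1L, function(s) {
      if (numeric) edf_num(raw, base + s * len, len, name)
      else edf_field(raw, base + s * len, len)
    }, if (numeric) numeric(1) else character(1))
  }
  labels <- getf("label", 16L)
  dims <- getf("dim", 8L)
  phys_min <- getf("phys_min", 8L, TRUE)
  phys_max <- getf("phys_max", 8L, TRUE)
  dig_min <- getf("dig_min", 8L, TRUE)
  dig_max <- getf("dig_max", 8L, TRUE)
  spr <- as.integer(getf("spr", 8L, TRUE))

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  assert_that(length(sig_idx) >= 1, "EDF file has no data signals",
              class = "format_error")
  assert_that(record_dur > 0, "EDF header field 'record duration' must be > 0",
              class = "format_error")
  rates <- spr[sig_idx] / record_dur
  assert_that(length(unique(rates)) == 1,
              "signals with differing sampling rates are not supported",
              class = "format_error")
  rate <- rates[1]

  n_records <- as.integer(n_records)
  rec_words <- sum(spr)
  data_raw <- raw[(header_bytes + 1):length(raw)]
  ints <- readBin(data_raw, "integer", n = n_records * rec_words, size = 2,
                  signed = TRUE, endian = "little")
  assert_that(length(ints) >= n_records * rec_words,
              "EDF data section shorter than the header promises",
              class = "format_error")
  offs <- c(0L, cumsum(spr))
  n_samples <- n_records * spr[sig_idx[1]]
  data <- matrix(0, nrow = length(sig_idx), ncol = n_samples)
  gains <- (phys_max - phys_min) / (dig_max - dig_min)
  scales <- vapply(dims, unit_scale, numeric(1))
  for (r in seq_len(n_records) - 1L) {
    base <- r * rec_words
    for (j in seq_along(sig_idx)) {
      s <- sig_idx[j]
      seg <- ints[(base + offs[s] + 1):(base + offs[s] + spr[s])]
      phys <- (gains[s] * (seg - dig_min[s]) + phys_min[s]) * scales[s]
      data[j, (r * spr[s] + 1):(r * spr[s] + spr[s])] <- phys
    }
  }

  events <- tibble::tibble(sample = integer(), code = character())
  if (any(is_ann)) {
    s <- which(is_ann)[1]
    ev <- list()
    for (r in seq_len(n_records) - 1L) {
      base_b <- header_bytes + (r * rec_words + offs[s]) * 2
      chunk <- raw[(base_b + 1):(base_b + spr[s] * 2)]
      for (tal in split_raw(chunk, as.raw(0L))) {
        if (length(tal) == 0) next
        fields <- split_raw(tal, as.raw(20L))
        if (length(fields) < 2 || length(fields[[2]]) == 0) next  # timestamp TAL
        onset_raw <- split_raw(fields[[1]], as.raw(21L))[[1]]
        onset <- suppressWarnings(as.numeric(rawToChar(onset_raw)))
        if (is.na(onset)) next
        ev[[length(ev) + 1]] <- tibble::tibble(
          sample = as.integer(round(onset * rate)),
          code = rawToChar(fields[[2]]))
      }
    }
    if (length(ev)) events <- dplyr::bind_rows(ev)
  }
  signal_record(data, rate, chr_trim(labels[sig_idx]), events)
}

pad_field <- function(x, len) {
  x <- as.character(x)
  assert_that(nchar(x) <= len, sprintf("EDF field too long: '%s'", x))
  formatC(x, width = -len, flag = " ")
}

#' Write a signal record to EDF/EDF+
#'
#' 16-bit EDF with a shared symmetric physical range across channels; events
#' are written as an EDF+ annotations signal. Values are quantized to the
#' 16-bit digital range, so a round trip reproduces samples to within half a
#' quantization step.
#'
#' @param record A [signal_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  data <- record$data
  n <- ncol(data)
  rate <- record$rate
  if (rate == round(rate) && n %% rate == 0) {
    spr_data <- as.integer(rate); record_dur <- 1
  } else {
    spr_data <- n; record_dur <- n / rate
  }
  n_rec <- n %/% spr_data
  pmax_v <- max(1e-9, max(abs(data)))
  # the physical range must round-trip through its 8-char header field, so
  # format it first and use the parsed-back value for scaling
  fmt8 <- function(v) {
    for (d in 7:1) {
      s <- sprintf("%.*g", d, v)
      if (nchar(s) <= 7) return(s)   # leave room for the sign
    }
    stop_frustbci("cannot format physical range", "format_error")
  }
  repeat {
    pmax_str <- fmt8(pmax_v)
    if (as.numeric(pmax_str) >= max(abs(data))) break
    pmax_v <- pmax_v * 1.001
  }
  pmax_v <- as.numeric(pmax_str)
  dig <- 32767
  gain <- pmax_v / dig
  quantized <- matrix(as.integer(pmin(dig, pmax(-dig, round(data / gain)))),
                      nrow = nrow(data))

  # one EDF+ annotations signal: a timestamp TAL per record plus event TALs
  sep14 <- as.raw(20L); nul <- as.raw(0L)
  tals <- lapply(seq_len(n_rec) - 1L, function(r) {
    t0 <- r * record_dur
    out <- c(charToRaw(sprintf("+%g", t0)), sep14, sep14, nul)
    sel <- which(record$events$sample >= r * spr_data &
                   record$events$sample < (r + 1) * spr_data)
    for (i in sel) {
      out <- c(out,
               charToRaw(sprintf("+%.6f", record$events$sample[i] / rate)),
               sep14, charToRaw(record$events$code[i]), sep14, nul)
    }
    out
  })
  ann_bytes <- max(vapply(tals, length, 1L))
  spr_ann <- as.integer(ceiling(ann_bytes / 2))

  ns <- nrow(data) + 1L
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, len) writeBin(charToRaw(pad_field(x, len)), con)
  wr("0", 8); wr("anonymous", 80); wr("frustbci export", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("EDF+C", 44)
  wr(n_rec, 8); wr(format(record_dur, digits = 8), 8); wr(ns, 4)
  labs <- c(record$channel_names, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(if (i < ns) "uV" else "", 8)  # dimension
  for (i in seq_len(ns)) wr(if (i < ns) paste0("-", pmax_str) else -1, 8)
  for (i in seq_len(ns)) wr(if (i < ns) pmax_str else 1, 8)
  for (i in seq_len(ns)) wr(-dig, 8)
  for (i in seq_len(ns)) wr(dig, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  for (i in seq_len(ns)) wr(if (i < ns) spr_data else spr_ann, 8)
  for (i in seq_len(ns)) wr("", 32)                       # reserved

  for (r in seq_len(n_rec) - 1L) {
    cols <- (r * spr_data + 1):((r + 1) * spr_data)
    for (ch in seq_len(nrow(data))) {
      writeBin(quantized[ch, cols], con, size = 2, endian = "little")
    }
    tb <- tals[[r + 1]]
    writeBin(c(tb, raw(spr_ann * 2 - length(tb))), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# BrainVision
# ---------------------------------------------------------------------------

bv_parse_ini <- function(lines) {
  lines <- sub("\r$", "", lines)
  sec <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\s*[;#]", ln) || !nzchar(chr_trim(ln))) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]\\s*$", ln))[[1]]
    if (length(m) == 2) { sec <- m[2]; next }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) == 3) out[[sec]][[chr_trim(kv[2])]] <- kv[3]
  }
  out
}

#' Read a BrainVision recording (.vhdr/.eeg/.vmrk)
#'
#' Supports binary data in `INT_16` or `IEEE_FLOAT_32` format, multiplexed or
#' vectorized orientation. Marker positions are taken as 0-based sample
#' offsets; markers with a non-empty description become events.
#'
#' @param header_path Path to the `.vhdr` header file.
#' @return A [signal_record()].
#' @export
read_brainvision <- function(header_path) {
  assert_that(file.exists(header_path),
              sprintf("file not found: %s", header_path), class = "io_error")
  ini <- bv_parse_ini(readLines(header_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  assert_that(!is.null(ci), "missing [Common Infos] section", class = "format_error")
  dir <- dirname(header_path)
  data_file <- file.path(dir, ci$DataFile)
  assert_that(!is.null(ci$DataFile) && file.exists(data_file),
              sprintf("referenced data file not found: %s", ci$DataFile %||% "<missing>"),
              class = "format_error")
  n_ch <- as.integer(ci$NumberOfChannels)
  si_us <- as.numeric(ci$SamplingInterval)
  assert_that(!is.na(n_ch) && n_ch > 0, "invalid NumberOfChannels", class = "format_error")
  assert_that(!is.na(si_us) && si_us > 0, "invalid SamplingInterval", class = "format_error")
  rate <- 1e6 / si_us
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  fmt <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")

  chs <- ini[["Channel Infos"]]
  names_res <- lapply(seq_len(n_ch), function(k) {
    spec <- chs[[paste0("Ch", k)]] %||% sprintf("Ch%d,,1", k)
    parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
    res <- suppressWarnings(as.numeric(parts[3]))
    list(name = parts[1],
         res = if (length(parts) >= 3 && !is.na(res)) res else 1,
         unit = if (length(parts) >= 4) parts[4] else "µV")
  })
  ch_names <- vapply(names_res, `[[`, "", "name")
  res <- vapply(names_res, `[[`, 1, "res")
  usc <- vapply(vapply(names_res, `[[`, "", "unit"), unit_scale, 1)

  sz <- file.size(data_file)
  if (fmt == "INT_16") {
    vals <- readBin(data_file, "integer", n = sz / 2, size = 2,
                    signed = TRUE, endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    vals <- readBin(data_file, "numeric", n = sz / 4, size = 4, endian = "little")
  } else {
    stop_frustbci(sprintf("unsupported BinaryFormat '%s'", fmt), "format_error")
  }
  n_samp <- length(vals) %/% n_ch
  vals <- vals[seq_len(n_samp * n_ch)]
  data <- if (orientation == "MULTIPLEXED") {
    matrix(vals, nrow = n_ch)
  } else if (orientation == "VECTORIZED") {
    t(matrix(vals, ncol = n_ch))
  } else {
    stop_frustbci(sprintf("unsupported DataOrientation '%s'", orientation),
                  "format_error")
  }
  data <- data * res * usc

  events <- tibble::tibble(sample = integer(), code = character())
  if (!is.null(ci$MarkerFile)) {
    marker_file <- file.path(dir, ci$MarkerFile)
    assert_that(file.exists(marker_file),
                sprintf("referenced marker file not found: %s", ci$MarkerFile),
                class = "format_error")
    mk <- bv_parse_ini(readLines(marker_file, warn = FALSE))[["Marker Infos"]]
    ev <- list()
    for (key in names(mk)) {
      parts <- strsplit(mk[[key]], ",", fixed = TRUE)[[1]]
      if (length(parts) < 3 || !nzchar(parts[2])) next
      ev[[length(ev) + 1]] <- tibble::tibble(
        sample = as.integer(parts[3]), code = parts[2])
    }
    if (length(ev)) events <- dplyr::arrange(dplyr::bind_rows(ev), sample)
  }
  signal_record(data, rate, ch_names, events)
}

#' Write a signal record in BrainVision format
#'
#' @param record A [signal_record()].
#' @param base_path Output path without extension; `.vhdr`, `.eeg` and `.vmrk`
#'   files are written next to each other.
#' @param orientation `"MULTIPLEXED"` or `"VECTORIZED"`.
#' @param binary_format `"IEEE_FLOAT_32"` or `"INT_16"`.
#' @return The header path, invisibly.
#' @export
write_brainvision <- function(record, base_path,
                              orientation = c("MULTIPLEXED", "VECTORIZED"),
                              binary_format = c("IEEE_FLOAT_32", "INT_16")) {
  orientation <- match.arg(orientation)
  binary_format <- match.arg(binary_format)
  base <- basename(base_path)
  hdr <- paste0(base_path, ".vhdr")
  res <- if (binary_format == "INT_16") {
    max(1e-9, max(abs(record$data))) / 32767
  } else 1
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    paste0("NumberOfChannels=", nrow(record$data)),
    paste0("SamplingInterval=", format(1e6 / record$rate, digits = 12)),
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "[Channel Infos]",
    vapply(seq_len(nrow(record$data)), function(k) {
      sprintf("Ch%d=%s,,%.12g,µV", k, record$channel_names[k], res)
    }, "")
  ), hdr, useBytes = TRUE)

  x <- record$data / res
  vals <- if (orientation == "MULTIPLEXED") as.vector(x) else as.vector(t(x))
  con <- file(paste0(base_path, ".eeg"), "wb")
  if (binary_format == "INT_16") {
    writeBin(as.integer(round(vals)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  close(con)

  mk_lines <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]")
  if (nrow(record$events)) {
    mk_lines <- c(mk_lines, vapply(seq_len(nrow(record$events)), function(i) {
      sprintf("Mk%d=Stimulus,%s,%d,1,0", i,
              record$events$code[i], record$events$sample[i])
    }, ""))
  }
  writeLines(mk_lines, paste0(base_path, ".vmrk"), useBytes = TRUE)
  invisible(hdr)
}

# ---------------------------------------------------------------------------
# Trial tables and epoch extraction
# ---------------------------------------------------------------------------

#' Validate a trial table
#'
#' A trial table has one row per trial with columns `subject_id`, `trial_id`,
#' `onset_sample` (0-based), `duration_samples`, `mi_label` (`left`/`right`),
#' `state_label` (`low`/`mid`/`high`/`none`) and `stage` (1 or 2). Stage-1
#' (calibration) rows must carry `state_label = "none"`; stage-2 rows carry an
#' induced frustration level. Trials of one subject must not overlap.
#'
#' @param table A data frame.
#' @return The table as a validated tibble.
#' @export
trial_table <- function(table) {
  tb <- tibble::as_tibble(table)
  need <- c("subject_id", "trial_id", "onset_sample", "duration_samples",
            "mi_label", "state_label", "stage")
  missing <- setdiff(need, names(tb))
  assert_that(length(missing) == 0,
              paste("trial table is missing columns:", paste(missing, collapse = ", ")),
              class = "validation_error")
  assert_that(all(tb$mi_label %in% c("left", "right")),
              "mi_label must be 'left' or 'right'", class = "validation_error")
  assert_that(all(tb$state_label %in% c("low", "mid", "high", "none")),
              "state_label must be low/mid/high/none", class = "validation_error")
  assert_that(all(tb$stage %in% c(1L, 2L)), "stage must be 1 or 2",
              class = "validation_error")
  assert_that(all(tb$state_label[tb$stage == 1] == "none"),
              "stage-1 rows must have state_label 'none'", class = "validation_error")
  assert_that(all(tb$state_label[tb$stage == 2] %in% c("low", "mid", "high")),
              "stage-2 rows must have state_label low/mid/high",
              class = "validation_error")
  assert_that(all(tb$duration_samples > 0), "durations must be positive",
              class = "validation_error")
  for (subj in unique(tb$subject_id)) {
    rows <- dplyr::arrange(tb[tb$subject_id == subj, ], .data$onset_sample)
    if (nrow(rows) > 1) {
      ends <- rows$onset_sample + rows$duration_samples
      assert_that(all(rows$onset_sample[-1] >= ends[-nrow(rows)]),
                  sprintf("overlapping trials for subject %s", subj),
                  class = "validation_error")
    }
  }
  tb
}

#' Read / write a trial table as CSV
#' @param path CSV path.
#' @return For the reader, a validated trial-table tibble.
#' @export
read_trial_table <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              class = "io_error")
  trial_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trial_table
#' @param table A trial table.
#' @export
write_trial_table <- function(table, path) {
  utils::write.csv(trial_table(table), path, row.names = FALSE)
  invisible(path)
}

#' Extract labeled trial epochs from a continuous record
#'
#' Slices `record$data` at each trial's `[onset, onset + duration)` interval
#' (0-based onsets). The record is not modified.
#'
#' @param record A [signal_record()].
#' @param table A trial table (see [trial_table()]).
#' @return A tibble with one row per trial, the epoch matrices in the `data`
#'   list-column, plus all label columns.
#' @export
extract_trials <- function(record, table) {
  tb <- trial_table(table)
  n <- ncol(record$data)
  epochs <- vector("list", nrow(tb))
  for (i in seq_len(nrow(tb))) {
    on <- tb$onset_sample[i]
    dur <- tb$duration_samples[i]
    if (on < 0 || on + dur > n) {
      stop_frustbci(sprintf(
        "trial %s of subject %s spans [%d, %d) outside the record (0, %d)",
        tb$trial_id[i], tb$subject_id[i], on, on + dur, n), "range_error")
    }
    epochs[[i]] <- record$data[, (on + 1):(on + dur), drop = FALSE]
  }
  dplyr::mutate(tb, data = epochs, rate = record$rate)
}

# ---------------------------------------------------------------------------
# Internal dataset bundles
# ---------------------------------------------------------------------------

#' Write / read an internal dataset bundle
#'
#' A single-file snapshot (R native serialization) of any package object plus
#' provenance: the seed that produced it, a hash of its configuration and the
#' package version, so preprocessed experiments can be reloaded exactly.
#'
#' @param x Object to store (cohort, window set, classifier bank, report).
#' @param path Output path.
#' @param seed Seed used to produce `x`, if any.
#' @param config Configuration object used to produce `x`, if any.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(x, path, seed = NULL, config = NULL) {
  obj <- structure(list(
    payload = x,
    provenance = list(seed = seed,
                      config_hash = rlang::hash(config),
                      package = "frustbci",
                      version = as.character(utils::packageVersion("frustbci")))),
    class = "frustbci_bundle")
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              class = "io_error")
  obj <- readRDS(path)
  assert_that(inherits(obj, "frustbci_bundle"), "not a frustbci bundle",
              class = "format_error")
  obj
}
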