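test_that("EDF round trip preserves shape, rate, channel order and samples", {
  set.seed(1)
  data <- matrix(rnorm(2 * 1000, sd = 30), 2)
  rec <- signal_record(data, 1000, c("C3", "C4"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(dim(back$data), c(2L, 1000L))
  expect_equal(back$rate, 1000)
  expect_identical(back$channel_names, c("C3", "C4"))
  quant <- max(abs(data)) / 32767
  expect_lt(max(abs(back$data - data)), quant)  # within one 16-bit step
})

test_that("EDF preserves a [C3, C4, Oz] montage in order and a sine amplitude", {
  t <- seq_len(1000) / 1000
  sine <- 50 * sin(2 * pi * 10 * t)
  rec <- signal_record(rbind(sine, 0.5 * sine, 0.1 * sine), 1000,
                       c("C3", "C4", "Oz"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$channel_names, c("C3", "C4", "Oz"))
  quant <- 50 / 32767
  expect_lt(max(abs(back$data[1, ] - sine)), quant)
  expect_equal(max(back$data[1, ]), 50, tolerance = 1e-3)
})

test_that("EDF events round trip and errors are classed and informative", {
  rec <- signal_record(matrix(rnorm(3000), 1), 1000, "Cz",
                       tibble::tibble(sample = c(100L, 2500L),
                                      code = c("MI/left", "STATE/high")))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$events$sample, c(100L, 2500L))
  expect_equal(back$events$code, c("MI/left", "STATE/high"))

  expect_error(read_edf(file.path(tempdir(), "nope.edf")),
               class = "frustbci_io_error")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw(strrep("X", 300)), bad)
  expect_error(read_edf(bad), regexp = "version",
               class = "frustbci_format_error")
})

test_that("BrainVision round trips across orientations and binary formats", {
  set.seed(2)
  data <- matrix(rnorm(3 * 700, sd = 40), 3)
  rec <- signal_record(data, 500, c("C3", "C4", "Oz"),
                       tibble::tibble(sample = 500L, code = "S  1"))
  for (orient in c("MULTIPLEXED", "VECTORIZED")) {
    for (fmt in c("IEEE_FLOAT_32", "INT_16")) {
      base <- withr::local_tempfile()
      write_brainvision(rec, base, orientation = orient, binary_format = fmt)
      back <- read_brainvision(paste0(base, ".vhdr"))
      tol <- if (fmt == "INT_16") max(abs(data)) / 32767 else 1e-4
      expect_lt(max(abs(back$data - data)), tol)
      expect_identical(back$channel_names, rec$channel_names)
      expect_equal(back$rate, 500)
      expect_equal(back$events$sample, 500L)
      expect_equal(back$events$code, "S  1")
    }
  }
})

test_that("BrainVision reports dangling file references as format errors", {
  hdr <- withr::local_tempfile(fileext = ".vhdr")
  writeLines(c("[Common Infos]", "DataFile=missing.eeg",
               "NumberOfChannels=1", "SamplingInterval=1000"), hdr)
  expect_error(read_brainvision(hdr), class = "frustbci_format_error")
})

test_that("extract_trials slices epochs per the table and leaves the record alone", {
  set.seed(3)
  data <- matrix(rnorm(2 * 10000), 2)
  rec <- signal_record(data, 1000, c("C3", "C4"))
  tbl <- tibble::tibble(
    subject_id = "s1", trial_id = c("a", "b"),
    onset_sample = c(0L, 5000L), duration_samples = c(4000L, 4000L),
    mi_label = c("left", "right"), state_label = c("none", "none"),
    stage = c(1L, 1L))
  eps <- extract_trials(rec, tbl)
  expect_equal(nrow(eps), 2)
  expect_identical(dim(eps$data[[1]]), c(2L, 4000L))
  expect_identical(eps$trial_id, c("a", "b"))
  # slicing oracle: epoch equals the manual slice
  expect_identical(eps$data[[2]], data[, 5001:9000])
  expect_identical(rec$data, data)

  tbl$onset_sample[2] <- 7000L
  expect_error(extract_trials(rec, tbl), regexp = "trial b",
               class = "frustbci_range_error")
})

test_that("trial tables enforce the stage/state and no-overlap invariants", {
  tbl <- tibble::tibble(
    subject_id = "s1", trial_id = c("a", "b"),
    onset_sample = c(0L, 5000L), duration_samples = c(4000L, 4000L),
    mi_label = c("left", "right"), state_label = c("low", "mid"),
    stage = c(2L, 2L))
  expect_s3_class(trial_table(tbl), "tbl_df")
  bad_stage <- dplyr::mutate(tbl, stage = c(1L, 2L))
  expect_error(trial_table(bad_stage), class = "frustbci_validation_error")
  overlap <- dplyr::mutate(tbl, onset_sample = c(0L, 3000L))
  expect_error(trial_table(overlap), regexp = "overlap",
               class = "frustbci_validation_error")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tbl, path)
  expect_equal(read_trial_table(path)$trial_id, c("a", "b"))
})

test_that("bundles round trip payloads with provenance", {
  path <- withr::local_tempfile(fileext = ".bundle")
  cfg <- list(a = 1, b = "x")
  write_bundle(list(x = 1:10), path, seed = 7, config = cfg)
  back <- read_bundle(path)
  expect_equal(back$payload$x, 1:10)
  expect_equal(back$provenance$seed, 7)
  expect_equal(back$provenance$config_hash, rlang::hash(cfg))
  expect_error(read_bundle(file.path(tempdir(), "no.bundle")),
               class = "frustbci_io_error")
})
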