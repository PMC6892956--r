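test_that("EDF round trip preserves shape, rate and signal", {
  set.seed(1)
  fs <- 256
  x <- matrix(rnorm(6 * fs * 3, sd = 30), 6)
  rec <- ts_recording(x, fs, sprintf("C%d", 1:6), "eeg")
  path <- tempfile(fileext = ".edf")
  write_eeg_edf(rec, path)
  got <- read_eeg_edf(path)
  expect_equal(got$eeg$fs, fs)
  expect_equal(got$eeg$channel_labels, rec$channel_labels)
  expect_equal(dim(got$eeg$data), dim(x))
  # 16-bit quantization: worst case error = range / 65535
  expect_lt(max(abs(got$eeg$data - x)), diff(range(x)) / 65535 * 1.01)
  expect_null(got$eog)
})

test_that("EOG channels split into a companion recording by label pattern", {
  set.seed(2)
  rec <- ts_recording(matrix(rnorm(64 * 512), 64), 256,
                      sprintf("E%02d", 1:64), "eeg")
  eog <- ts_recording(matrix(rnorm(2 * 512), 2), 256, c("HEOG", "VEOG"), "eog")
  path <- tempfile(fileext = ".edf")
  write_eeg_edf(rec, path, eog = eog)
  got <- read_eeg_edf(path)
  expect_length(got$eeg$channel_labels, 64)
  expect_equal(got$eog$channel_labels, c("HEOG", "VEOG"))
  expect_equal(nrow(got$eog$data), 2)
})

test_that("malformed EDF headers are rejected", {
  path <- tempfile(fileext = ".edf")
  writeBin(charToRaw(paste(rep("x", 300), collapse = "")), path)
  expect_error(read_eeg_edf(path), class = "nvf_format_error")
  expect_error(read_eeg_edf(tempfile()), class = "nvf_format_error")
})

test_that("fNIRS table round trips and orders rows channel-major", {
  set.seed(3)
  h <- hemodynamic_series(matrix(rnorm(42) / 10, 3), matrix(rnorm(42) / 20, 3),
                          fs = 50, channel_labels = c("ch1", "ch2", "ch3"))
  od <- forward_mbll(h)
  path <- tempfile(fileext = ".tsv")
  write_fnirs_table(od, path)
  got <- read_fnirs_table(path)
  expect_equal(got$fs, 50)
  expect_equal(got$channel_labels,
               c("ch1@690", "ch1@830", "ch2@690", "ch2@830", "ch3@690", "ch3@830"))
  expect_equal(got$data, od$data, tolerance = 1e-12)
})

test_that("fNIRS table rejects missing partners and implausible time units", {
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(time = (0:49) / 50, "a@690" = rnorm(50), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_fnirs_table(path), class = "nvf_format_error")

  tab <- data.frame(time = (0:49) * 20,         # milliseconds: fs = 0.05 Hz
                    "a@690" = rnorm(50), "a@830" = rnorm(50), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_fnirs_table(path), class = "nvf_format_error")

  tab <- data.frame(time = c(0, 0.02, 0.05, 0.06), "a@690" = rnorm(4),
                    "a@830" = rnorm(4), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_fnirs_table(path), "non-uniform")
})

test_that("shipped montage is complete and carries the reported coordinates", {
  m <- read_montage()
  expect_equal(sum(m$modality == "eeg"), 64)
  expect_equal(sum(m$modality == "eog"), 2)
  expect_equal(sum(m$modality == "fnirs"), 14)
  af4 <- m[m$label == "AF4", ]
  expect_equal(unlist(af4[, c("x", "y", "z")], use.names = FALSE), c(31, 61, 26))
  # every PFC ROI covered in both modalities
  for (roi in c("L-dlPFC", "L-FP", "R-FP", "R-dlPFC")) {
    expect_true(any(m$roi == roi & m$modality == "eeg"))
    expect_true(any(m$roi == roi & m$modality == "fnirs"))
  }
})

test_that("montage validation rejects duplicates, bad rois, uncovered fNIRS", {
  m <- read_montage()
  path <- tempfile(fileext = ".tsv")
  bad <- m; bad$label[2] <- bad$label[1]
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_montage(path), class = "nvf_validation_error")
  bad <- m; bad$roi[1] <- "dlPFC-left"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_montage(path), "unknown roi")
  bad <- m; bad$roi[bad$modality == "fnirs"][1] <- "other"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_montage(path), class = "nvf_validation_error")
})

test_that("result bundles write labeled TSVs and round trip to 1e-12", {
  set.seed(4)
  v <- matrix(rnorm(14 * 14), 14); v <- (v + t(v)) / 2; diag(v) <- 1
  v[abs(v) > 1] <- 0.9; v <- (v + t(v)) / 2; diag(v) <- 1
  cm <- connectivity_matrix(v, "pearson_r", sprintf("ch%d", 1:14))
  g <- threshold_top_fraction(cm, 0.05)
  dir <- tempfile()
  bundle <- list(matrices = list(hbo = cm), graphs = list(net = g),
                 scalars = list(p = 0.015), provenance = list(seed = 1))
  paths <- write_results(bundle, dir)
  expect_equal(length(readLines(file.path(dir, "hbo.tsv"))), 15)
  back <- read_matrix_tsv(file.path(dir, "hbo.tsv"), metric = "pearson_r")
  expect_equal(back$values, cm$values, tolerance = 1e-12)
  expect_equal(back$labels, cm$labels)
  # refuses to clobber without the flag
  expect_error(write_results(bundle, dir), class = "nvf_refusal_error")
  expect_silent(write_results(bundle, dir, overwrite = TRUE))
  # empty bundle still writes provenance
  dir2 <- tempfile()
  write_results(list(provenance = list(seed = 2)), dir2)
  expect_true(file.exists(file.path(dir2, "summary.txt")))
})
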