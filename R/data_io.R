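#' Multichannel time-series recording
#'
#' The raw substrate of both pipelines: a channels x samples matrix with a
#' sampling rate, ordered unique channel labels, and a modality tag.  EEG is
#' carried in microvolts, fNIRS as unitless optical-density change.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one unique label per row.
#' @param modality one of `"eeg"`, `"eog"`, `"fnirs_od"`.
#' @param t0 offset of the first retained sample in seconds from the start
#'   of the original recording.
#' @return An object of class `ts_recording`.
#' @export
ts_recording <- function(data, fs, channel_labels, modality, t0 = 0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    nvf_stop("nvf_validation_error", "fs must be a single positive number")
  }
  if (length(channel_labels) != nrow(data)) {
    nvf_stop("nvf_validation_error", "number of labels (", length(channel_labels),
             ") != number of data rows (", nrow(data), ")")
  }
  if (anyDuplicated(channel_labels)) {
    nvf_stop("nvf_validation_error", "channel labels must be unique")
  }
  if (!modality %in% .nvf_modalities) {
    nvf_stop("nvf_validation_error", "unknown modality '", modality, "'")
  }
  if (ncol(data) < 1) nvf_stop("nvf_validation_error", "recording needs >= 1 sample")
  if (!all(is.finite(data))) {
    nvf_stop("nvf_validation_error", "recording contains non-finite values")
  }
  structure(list(data = data, fs = fs, channel_labels = as.character(channel_labels),
                 modality = modality, t0 = t0),
            class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

## ---------------------------------------------------------------------------
## EDF (European Data Format) -- minimal reader/writer, 16-bit LE samples.
## No EDF package ships with the supported environment; the format is a
## fixed-layout ASCII header plus int16 data records.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to an EDF file
#'
#' Writes one EDF file with 1-second data records.  Physical scaling is set
#' per channel from the data range, so round-trips are exact to the 16-bit
#' quantization step.  Used by the synthetic generator and by tests; real
#' amplifier exports are read with [read_eeg_edf()].
#'
#' @param rec,eog a `ts_recording` (EEG, in microvolts) and an optional EOG
#'   companion recording at the same rate, appended as extra channels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(rec, path, eog = NULL) {
  data <- rec$data
  labels <- rec$channel_labels
  if (!is.null(eog)) {
    if (eog$fs != rec$fs) nvf_stop("nvf_format_error", "EOG rate differs from EEG rate")
    data <- rbind(data, eog$data)
    labels <- c(labels, eog$channel_labels)
  }
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) nvf_stop("nvf_format_error", "EDF writer needs integer Hz")
  fs <- round(fs)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) nvf_stop("nvf_format_error", "recording shorter than one 1-s record")
  data <- data[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(data)

  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_field("0", 8),
                edf_field("X X X X", 80),
                edf_field("Startdate X X X X", 80),
                edf_field("01.01.20", 8), edf_field("00.00.00", 8),
                edf_field(256 * (1 + ns), 8),
                edf_field("", 44),
                edf_field(n_rec, 8),
                edf_field(1, 8),
                edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  wr <- function(vals, width) writeChar(paste0(vapply(vals, edf_field, "", width = width),
                                               collapse = ""), con, eos = NULL)
  wr(labels, 16)
  wr(rep("", ns), 80)
  wr(rep("uV", ns), 8)
  wr(formatC(pmin_, format = "g", digits = 7), 8)
  wr(formatC(pmax_, format = "g", digits = 7), 8)
  wr(rep(dmin, ns), 8)
  wr(rep(dmax, ns), 8)
  wr(rep("", ns), 80)
  wr(rep(fs, ns), 8)
  wr(rep("", ns), 32)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round(sweep(sweep(data, 1, pmin_), 1, scale, "/")) + dmin
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_raw <- function(path) {
  if (!file.exists(path)) nvf_stop("nvf_format_error", "no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) nvf_stop("nvf_format_error", "not an EDF file (version field '", version, "')")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1) nvf_stop("nvf_format_error", "EDF header declares ", ns, " signals")
  if (is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0 || is.na(hdr_bytes)) {
    nvf_stop("nvf_format_error", "malformed EDF header")
  }
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (any(is.na(c(pmin_, pmax_, dmin, dmax, spr)))) {
    nvf_stop("nvf_format_error", "malformed EDF signal headers")
  }
  total <- n_rec * sum(spr)
  raw_ <- readBin(con, "integer", n = total, size = 2, endian = "little")
  if (length(raw_) < total) nvf_stop("nvf_format_error", "EDF data truncated")
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  # channels may in principle have distinct rates; unpack record by record
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  for (s in seq_len(ns)) {
    idx <- as.vector(outer((offs[s] + 1L):offs[s + 1L], (seq_len(n_rec) - 1L) * per_rec, "+"))
    vals <- raw_[sort(idx)]
    if (spr[s] != spr[1]) next  # handled by caller as unsupported layout
    data[s, ] <- pmin_[s] + (vals - dmin[s]) * (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
  }
  list(data = data, labels = labels, spr = spr, fs = spr / rec_dur)
}

#' Read an EEG recording from EDF
#'
#' Scalp channels become a `modality = "eeg"` recording; channels whose label
#' matches `eog_pattern` are split into a companion `modality = "eog"`
#' recording.  All scalp channels must share one sampling rate.
#'
#' @param path EDF/EDF+ file.
#' @param eog_pattern regular expression identifying EOG channels by label.
#' @return list with elements `eeg` and `eog` (the latter `NULL` when no
#'   label matches).
#' @export
read_eeg_edf <- function(path, eog_pattern = "(H|V)EOG") {
  raw_ <- read_edf_raw(path)
  if (length(unique(raw_$spr)) != 1) {
    nvf_stop("nvf_unsupported_layout", "mixed per-channel sampling rates in EDF")
  }
  is_eog <- grepl(eog_pattern, raw_$labels)
  if (all(is_eog)) nvf_stop("nvf_format_error", "all channels match the EOG pattern")
  eeg <- ts_recording(raw_$data[!is_eog, , drop = FALSE], fs = raw_$fs[1],
                      channel_labels = raw_$labels[!is_eog], modality = "eeg")
  eog <- NULL
  if (any(is_eog)) {
    eog <- ts_recording(raw_$data[is_eog, , drop = FALSE], fs = raw_$fs[1],
                        channel_labels = raw_$labels[is_eog], modality = "eog")
  }
  list(eeg = eeg, eog = eog)
}

## ---------------------------------------------------------------------------
## fNIRS optical density tables

#' Read an fNIRS optical-density table
#'
#' Expects a delimited table with a `time` column (seconds, constant step)
#' and one column per channel/wavelength pair named `<chan>@690` /
#' `<chan>@830`.  Returns a `modality = "fnirs_od"` recording whose rows are
#' channel-major: `ch1@690, ch1@830, ch2@690, ...`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param fs_bounds plausibility bounds on the inferred sampling rate in Hz;
#'   a time column in the wrong unit is caught here.
#' @return a `ts_recording`.
#' @export
read_fnirs_table <- function(path, sep = "\t", fs_bounds = c(1, 1e4)) {
  if (!file.exists(path)) nvf_stop("nvf_format_error", "no such file: ", path)
  tab <- read.delim(path, sep = sep, check.names = FALSE)
  if (!"time" %in% names(tab)) nvf_stop("nvf_format_error", "missing 'time' column")
  tcol <- tab$time
  if (length(tcol) < 2) nvf_stop("nvf_format_error", "need >= 2 time points")
  dt <- diff(tcol)
  if (max(abs(dt - dt[1])) > 1e-6) {
    nvf_stop("nvf_format_error", "non-uniform time step in fNIRS table")
  }
  fs <- 1 / dt[1]
  if (fs < fs_bounds[1] || fs > fs_bounds[2]) {
    nvf_stop("nvf_format_error", sprintf(
      "implausible sampling rate %g Hz (bounds %g-%g); check time units", fs,
      fs_bounds[1], fs_bounds[2]))
  }
  sig_cols <- setdiff(names(tab), "time")
  m <- regmatches(sig_cols, regexec("^(.*)@(690|830)$", sig_cols))
  bad <- vapply(m, length, 1L) != 3
  if (any(bad)) nvf_stop("nvf_format_error", "unrecognized column(s): ",
                         paste(sig_cols[bad], collapse = ", "))
  chan <- vapply(m, `[`, "", 2)
  wl <- vapply(m, `[`, "", 3)
  channels <- unique(chan)  # preserve file order
  for (ch in channels) {
    have <- sort(wl[chan == ch])
    if (!identical(have, c("690", "830"))) {
      nvf_stop("nvf_format_error", "channel '", ch, "' lacks a wavelength partner column")
    }
  }
  ord_labels <- as.vector(rbind(paste0(channels, "@690"), paste0(channels, "@830")))
  data <- t(as.matrix(tab[, ord_labels, drop = FALSE]))
  dimnames(data) <- NULL
  ts_recording(data, fs = fs, channel_labels = ord_labels, modality = "fnirs_od",
               t0 = tcol[1])
}

#' Write an fNIRS optical-density recording as a delimited table
#' @param rec a `modality = "fnirs_od"` recording.
#' @param path,sep output file and separator.
#' @export
write_fnirs_table <- function(rec, path, sep = "\t") {
  stopifnot(rec$modality == "fnirs_od")
  tab <- data.frame(time = rec$t0 + (seq_len(ncol(rec$data)) - 1) / rec$fs,
                    t(rec$data), check.names = FALSE)
  names(tab) <- c("time", rec$channel_labels)
  write.table(format(tab, digits = 17, trim = TRUE), path, sep = sep,
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Montage

#' Read a montage table
#'
#' Delimited table with columns `label`, `modality`, `x`, `y`, `z` (MNI mm)
#' and `roi` (one of `L-dlPFC`, `L-FP`, `R-FP`, `R-dlPFC`, `other`).  Every
#' fNIRS channel must carry a PFC ROI, and each of the four PFC ROIs must be
#' covered by at least one EEG electrode and one fNIRS channel.
#'
#' @param path file path (default: the montage shipped with the package).
#' @return a `data.frame` of class `montage`, row order as in the file.
#' @export
read_montage <- function(path = system.file("extdata", "default_montage.tsv",
                                            package = "nvfusion")) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "modality", "x", "y", "z", "roi")
  if (!all(need %in% names(tab))) {
    nvf_stop("nvf_validation_error", "montage must have columns ",
             paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$label)) {
    nvf_stop("nvf_validation_error", "duplicate montage label: ",
             tab$label[anyDuplicated(tab$label)])
  }
  bad_roi <- setdiff(unique(tab$roi), .nvf_rois)
  if (length(bad_roi)) nvf_stop("nvf_validation_error", "unknown roi token: ",
                                paste(bad_roi, collapse = ", "))
  bad_mod <- setdiff(unique(tab$modality), c("eeg", "eog", "fnirs"))
  if (length(bad_mod)) nvf_stop("nvf_validation_error", "unknown modality: ",
                                paste(bad_mod, collapse = ", "))
  fn <- tab[tab$modality == "fnirs", ]
  if (any(fn$roi == "other")) {
    nvf_stop("nvf_validation_error", "fNIRS channel without PFC roi: ",
             paste(fn$label[fn$roi == "other"], collapse = ", "))
  }
  for (roi in setdiff(.nvf_rois, "other")) {
    if (!any(tab$roi == roi & tab$modality == "fnirs") ||
        !any(tab$roi == roi & tab$modality == "eeg")) {
      nvf_stop("nvf_validation_error", "roi ", roi,
               " lacks an EEG electrode or an fNIRS channel")
    }
  }
  class(tab) <- c("montage", "data.frame")
  tab
}

#' Electrodes/channels belonging to a region of interest
#' @param montage a `montage`.
#' @param roi one of the four PFC ROI tokens, or `"whole_pfc"` for their union.
#' @param modality `"eeg"` or `"fnirs"`.
#' @return character vector of labels, montage order.
#' @export
roi_labels <- function(montage, roi, modality) {
  stopifnot(modality %in% c("eeg", "fnirs"))
  sel <- if (identical(roi, "whole_pfc")) montage$roi != "other" else montage$roi == roi
  montage$label[sel & montage$modality == modality]
}

## ---------------------------------------------------------------------------
## Result bundles

#' Write a result bundle to a directory
#'
#' Matrices go out as labeled TSV, graphs as edge-list TSV
#' (`node_a`, `node_b`, `weight`), scalars and provenance as one structured
#' text summary.  Refuses to clobber an existing manifest unless
#' `overwrite = TRUE`.
#'
#' @param bundle a list with optional named elements `matrices` (list of
#'   `connectivity_matrix`), `graphs` (list of `network_graph`), `scalars`
#'   (named numeric), `provenance` (named list).
#' @param directory output directory (created if missing).
#' @param overwrite allow replacing a previous bundle.
#' @return character vector of written paths (the manifest), invisibly.
#' @export
write_results <- function(bundle, directory, overwrite = FALSE) {
  manifest_path <- file.path(directory, "MANIFEST")
  if (file.exists(manifest_path) && !overwrite) {
    nvf_stop("nvf_refusal_error", "bundle already present in ", directory,
             " (use overwrite = TRUE)")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in names(bundle$matrices)) {
    p <- file.path(directory, paste0(nm, ".tsv"))
    write_matrix_tsv(bundle$matrices[[nm]], p)
    written <- c(written, p)
  }
  for (nm in names(bundle$graphs)) {
    g <- bundle$graphs[[nm]]
    p <- file.path(directory, paste0(nm, "_edges.tsv"))
    ed <- g$edges
    out <- data.frame(node_a = g$labels[ed$i], node_b = g$labels[ed$j],
                      weight = ed$weight)
    write.table(format(out, digits = 17, trim = TRUE), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  }
  p <- file.path(directory, "summary.txt")
  lines <- c("# nvfusion result bundle")
  for (nm in names(bundle$scalars)) {
    lines <- c(lines, sprintf("scalar\t%s\t%.17g", nm, bundle$scalars[[nm]]))
  }
  for (nm in names(bundle$provenance)) {
    lines <- c(lines, sprintf("provenance\t%s\t%s", nm,
                              paste(format(bundle$provenance[[nm]]), collapse = " ")))
  }
  writeLines(lines, p)
  written <- c(written, p)
  writeLines(basename(written), manifest_path)
  invisible(c(written, manifest_path))
}

write_matrix_tsv <- function(cm, path) {
  m <- cm$values
  tab <- data.frame(label = cm$labels, m, check.names = FALSE)
  names(tab) <- c("label", cm$labels)
  write.table(format(tab, digits = 17, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled matrix TSV written by [write_results()]
#' @param path file path.
#' @param metric metric tag to attach.
#' @return a `connectivity_matrix`.
#' @export
read_matrix_tsv <- function(path, metric = "sl") {
  tab <- read.delim(path, sep = "\t", check.names = FALSE)
  labels <- as.character(tab$label)
  m <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(m) <- list(labels, labels)
  connectivity_matrix(m, metric = metric, labels = labels)
}
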