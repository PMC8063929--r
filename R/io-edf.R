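# Minimal European Data Format (EDF) support: enough of the 16-bit integer
# format to export epoched recordings (trials concatenated as data records,
# channels as signals) and read them back. Physical range is set per channel
# from the data; values are quantised to the EDF 16-bit grid.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an epoched recording to an EDF file
#'
#' Each trial becomes one EDF data record; each channel one EDF signal with
#' `samples` values per record. Amplitudes are quantised to the 16-bit
#' integer grid over each channel's observed physical range, the usual EDF
#' precision loss.
#'
#' @param recording An [epoched_recording()].
#' @param path Output `.edf` file.
#' @export
write_edf <- function(recording, path) {
  d <- dim(recording$data)           # trials x channels x samples
  nt <- d[1]; nc <- d[2]; ns <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  dig_min <- -32768; dig_max <- 32767
  phys_min <- apply(recording$data, 2, min)
  phys_max <- apply(recording$data, 2, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste("X X X", recording$subject_id), 80),
    edf_pad(paste("Startdate X X X", recording$condition), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * nc, 8), edf_pad("", 44),
    edf_pad(nt, 8),
    edf_pad(format(ns / recording$fs, digits = 8), 8),
    edf_pad(nc, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(seq_len(nc), function(i) edf_pad(sprintf("EEG %03d", i), 16), ""),
    rep(edf_pad("", 80), nc),
    rep(edf_pad("uV", 8), nc),
    vapply(phys_min, function(v) edf_pad(format(v, digits = 7), 8), ""),
    vapply(phys_max, function(v) edf_pad(format(v, digits = 7), 8), ""),
    rep(edf_pad(dig_min, 8), nc),
    rep(edf_pad(dig_max, 8), nc),
    rep(edf_pad("", 80), nc),
    rep(edf_pad(ns, 8), nc),
    rep(edf_pad("", 32), nc))
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      dig <- round((recording$data[tr, ch, ] - phys_min[ch]) * scale[ch]) +
        dig_min
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path `.edf` file.
#' @param t0 Stimulus-onset sample index to attach.
#' @return An [epoched_recording()].
#' @export
read_edf <- function(path, t0 = 101L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); subj <- sub("^X X X ", "", rd(80)); cond <- sub(".*X X X ", "", rd(80))
  rd(8); rd(8); rd(8); rd(44)
  nt <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  rd(16 * nc); rd(80 * nc); rd(8 * nc)
  phys_min <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(80 * nc)
  ns <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))[1]
  rd(32 * nc)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  a <- array(0, c(nt, nc, ns))
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      dig <- readBin(con, "integer", n = ns, size = 2, endian = "little",
                     signed = TRUE)
      a[tr, ch, ] <- (dig - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }
  epoched_recording(subj, cond, a, fs = ns / dur, t0 = t0)
}

#' Export every recording of a cohort as EDF files plus a manifest
#'
#' Files are named `<subject>_<condition>.edf`; the manifest CSV lists
#' `subject_id`, `group`.
#'
#' @param cohort An `erp_cohort`.
#' @param dir Output directory.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in cohort$recordings)
    write_edf(r, file.path(dir, sprintf("%s_%s.edf", r$subject_id,
                                        r$condition)))
  data.table::fwrite(cohort$labels[, c("subject_id", "group")],
                     file.path(dir, "manifest.csv"))
  invisible(dir)
}
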