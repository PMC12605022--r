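#' Read a recording from EDF or TSV
#'
#' TSV files are sample-per-row matrices with a header row of channel
#' names (microvolts); the sampling rate must be supplied. EDF files are
#' the continuous 16-bit EDF flavour written by [write_recording()]; the
#' sampling rate and physical scaling come from the header. Channels are
#' matched to the montage by label, case-insensitively, and reordered to
#' the montage order.
#'
#' @param path recording file (`.edf` or anything else treated as TSV).
#' @param montage an `eeg_montage`, or a path to an `.sfp` file.
#' @param sfreq sampling rate in Hz (required for TSV, ignored for EDF).
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, montage, sfreq = NULL) {
  if (is.character(montage)) montage <- read_montage(montage)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- read_edf(path)
    data <- edf$data
    sfreq <- edf$sfreq
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    if (is.null(sfreq)) stopf("sfreq must be supplied for TSV recordings")
    data <- t(as.matrix(tab))
  }
  got <- rownames(data)
  idx <- match(tolower(montage$channel_names), tolower(got))
  if (anyNA(idx)) {
    missing <- montage$channel_names[is.na(idx)]
    stopf("channel(s) %s not present in %s",
          paste(missing, collapse = ", "), path)
  }
  extra <- setdiff(tolower(got), tolower(montage$channel_names))
  if (length(extra))
    stopf("unknown channel label(s) in %s: %s", path,
          paste(got[tolower(got) %in% extra], collapse = ", "))
  eeg_recording(data[idx, , drop = FALSE], sfreq, montage)
}

#' Write a recording as TSV or EDF
#'
#' @param rec an `eeg_recording`.
#' @param path output path; `.edf` selects EDF, anything else TSV.
#' @return the path, invisibly.
#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(rec, path)
  } else {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$montage$channel_names
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---- Minimal continuous EDF (16-bit) ---------------------------------
# Data records of 1 s; requires an integer sampling rate and truncates a
# trailing partial second (with a warning). Physical range is symmetric
# per channel; digital range is the full int16 span.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(rec, path) {
  sfreq <- rec$sfreq
  if (abs(sfreq - round(sfreq)) > 1e-9)
    stopf("EDF export needs an integer sampling rate, got %g", sfreq)
  sfreq <- as.integer(round(sfreq))
  ns <- n_channels(rec)
  n_rec <- n_samples(rec) %/% sfreq
  if (n_rec < 1) stopf("record shorter than one EDF data record (1 s)")
  if (n_rec * sfreq < n_samples(rec))
    warning("EDF export truncated a trailing partial second")
  X <- rec$data[, seq_len(n_rec * sfreq), drop = FALSE]
  pmax_ <- pmax(apply(abs(X), 1, max), 1e-6)
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32768L; dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("synthetic subject", 80), pad("synthetic recording", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * ns, 8), pad("", 44), pad(n_rec, 8), pad("1", 8),
    pad(ns, 4)), con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(rec$montage$channel_names, 16)
  fld(rep("", ns), 80)                         # transducer
  fld(rep("uV", ns), 8)                        # physical dimension
  fld(formatC(phys_min, digits = 6, format = "g"), 8)
  fld(formatC(phys_max, digits = 6, format = "g"), 8)
  fld(rep(dig_min, ns), 8)
  fld(rep(dig_max, ns), 8)
  fld(rep("", ns), 80)                         # prefiltering
  fld(rep(sfreq, ns), 8)
  fld(rep("", ns), 32)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * sfreq + 1):(r * sfreq)
    for (ch in seq_len(ns)) {
      dig <- round((X[ch, cols] - phys_min[ch]) / scale[ch]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stopf("malformed EDF header: bad version field %s", version)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1)
    stopf("malformed EDF header in %s", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  dims <- rdv(8)
  if (!all(tolower(dims) %in% c("uv", "")))
    stopf("ambiguous units in %s: %s (expected uV)", path,
          paste(unique(dims), collapse = ", "))
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1)
    stopf("mixed per-channel rates are not supported (%s)", path)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      data[ch, cols] <- phys_min[ch] + (dig - dig_min[ch]) * scale[ch]
    }
  }
  list(data = data, sfreq = spr[1] / rec_dur, labels = labels)
}
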