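#' Electrode montage
#'
#' A montage pairs channel names with 3D positions on a unit sphere
#' (head-centred coordinates: +x through the nasion, +y through the left
#' ear, +z through the vertex; arbitrary units).
#'
#' @param channel_names character vector of unique channel labels.
#' @param positions numeric matrix with one row per channel and columns
#'   x, y, z.
#' @return an object of class `eeg_montage`.
#' @export
montage <- function(channel_names, positions) {
  channel_names <- as.character(channel_names)
  positions <- as.matrix(positions)
  if (length(channel_names) < 3)
    stopf("a montage needs at least 3 channels, got %d", length(channel_names))
  if (anyDuplicated(channel_names))
    stopf("channel names must be unique")
  if (nrow(positions) != length(channel_names) || ncol(positions) != 3)
    stopf("positions must be a %d x 3 matrix", length(channel_names))
  if (!all(is.finite(positions)))
    stopf("montage positions must be finite")
  dimnames(positions) <- list(channel_names, c("x", "y", "z"))
  structure(list(channel_names = channel_names, positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s\n", length(x$channel_names),
              paste(x$channel_names, collapse = " ")))
  invisible(x)
}

#' Standard 19-channel 10-20 montage
#'
#' Canonical spherical coordinates for the 19 electrodes of the
#' international 10-20 system, as unit-sphere positions. The same montage
#' is shipped as `inst/extdata/standard_1020_19.sfp`.
#'
#' @return an `eeg_montage` with 19 channels.
#' @export
standard_montage_1020 <- function() {
  # label, inclination from vertex (deg), azimuth from nasion (deg, +left)
  tab <- rbind(
    c("Fp1", 90,  18), c("Fp2", 90, -18),
    c("F7",  90,  54), c("F3",  62,  39), c("Fz", 45,    0),
    c("F4",  62, -39), c("F8",  90, -54),
    c("T3",  90,  90), c("C3",  45,  90), c("Cz",  0,    0),
    c("C4",  45, -90), c("T4",  90, -90),
    c("T5",  90, 126), c("P3",  62, 141), c("Pz", 45,  180),
    c("P4",  62, -141), c("T6", 90, -126),
    c("O1",  90, 162), c("O2",  90, -162))
  incl <- as.numeric(tab[, 2]) * pi / 180
  az <- as.numeric(tab[, 3]) * pi / 180
  pos <- cbind(x = sin(incl) * cos(az),
               y = sin(incl) * sin(az),
               z = cos(incl))
  montage(tab[, 1], pos)
}

#' Read / write .sfp montage files
#'
#' Plain-text electrode position files with one `label x y z` row per
#' channel (whitespace separated).
#'
#' @param path file path.
#' @return `read_montage()` returns an `eeg_montage`.
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("label", "x", "y", "z"))
  montage(tab$label, as.matrix(tab[, c("x", "y", "z")]))
}

#' @param m an `eeg_montage`.
#' @rdname read_montage
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "eeg_montage"))
  df <- data.frame(label = m$channel_names, m$positions)
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
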