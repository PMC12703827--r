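# Minimal EDF (European Data Format) I/O.
#
# Covers the plain continuous-recording subset: one fixed-length data record
# per second, all signals at the same rate, 16-bit little-endian samples with
# per-signal physical/digital scaling. Event marks travel in the cohort
# manifest, not in an annotations channel.

.edfPad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a channels-by-samples matrix to an EDF file
#'
#' @param data numeric matrix, channels x samples, physical units (uV).
#' @param fs sampling rate in Hz; must be a positive integer and divide the
#'   sample count (records are 1 s long).
#' @param labels channel labels (<= 16 characters each).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(data, fs, labels, path) {
  stopifnot(is.matrix(data), nrow(data) == length(labels))
  fs <- as.integer(fs)
  if (fs <= 0) stop("fs must be a positive integer")
  n <- ncol(data)
  if (n %% fs != 0)
    stop("sample count must be a whole number of 1 s records")
  nRec <- n %/% fs
  ns <- nrow(data)

  physMax <- max(abs(data), 1e-6)
  physMin <- -physMax
  digMax <- 32767L; digMin <- -32768L
  scale <- (digMax - digMin) / (physMax - physMin)
  dig <- round((data - physMin) * scale) + digMin
  dig <- pmin(pmax(dig, digMin), digMax)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad("X X X X", 80), .edfPad("Startdate X X X X", 80),
    .edfPad("01.01.26", 8), .edfPad("00.00.00", 8),
    .edfPad(256L * (1L + ns), 8), .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad(1L, 8), .edfPad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, .edfPad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(labels, 16)
  fld(rep("synthetic EEG", ns), 80)
  fld(rep("uV", ns), 8)
  fld(rep(format(physMin, digits = 6), ns), 8)
  fld(rep(format(physMax, digits = 6), ns), 8)
  fld(rep(digMin, ns), 8)
  fld(rep(digMax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)

  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, idx, drop = FALSE])      # per signal contiguous
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by \code{\link{writeEDF}} (or any plain
#' fixed-rate 16-bit EDF)
#'
#' @param path EDF file.
#' @return list with \code{data} (channels x samples matrix, physical
#'   units), \code{fs}, \code{labels}.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes (recomputed below)
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))               # samples per record per signal
  fld(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / recDur
  data <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- t(block)
  }
  for (s in seq_len(ns)) {
    g <- (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
    data[s, ] <- (data[s, ] - digMin[s]) * g + physMin[s]
  }
  rownames(data) <- labels
  list(data = data, fs = fs, labels = labels)
}
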