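#' EEG recording container
#'
#' A minimal container for a multichannel recording: a channels-by-samples
#' numeric matrix (microvolts), the sampling rate and ordered channel
#' labels.
#'
#' @param data numeric matrix, channels in rows.
#' @param rate_hz sampling frequency in Hz.
#' @param channel_names character vector, one label per row.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate_hz, channel_names = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_names))
    channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  stopifnot(is.numeric(data), rate_hz > 0,
            length(channel_names) == nrow(data))
  if (!all(is.finite(data))) stop("EEG data contains non-finite values")
  structure(list(data = data, rate_hz = rate_hz,
                 channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz))
  cat("Channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

# --- EDF (European Data Format, 16-bit) -------------------------------------
#
# Fixed-layout ASCII header of 256 + 256*ns bytes followed by data records
# of little-endian int16 samples, channel-major within each record.  Only
# the plain signal layout is handled (no EDF+ annotations); one data record
# per second.

pad <- function(s, width) formatC(as.character(s), width = width, flag = "-")

#' Write an EEG recording as 16-bit EDF
#'
#' Signals are scaled channel-wise onto the full digital range
#' \[-32768, 32767\] using each channel's physical min/max, the standard
#' (lossy, ~5 significant digits) EDF quantization.
#'
#' @param rec an [eeg_recording()]; total duration must be a whole number
#'   of seconds.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- rec$rate_hz  # samples per 1 s record
  if (spr != round(spr)) stop("rate_hz must be an integer for EDF output")
  n_rec <- ncol(rec$data) / spr
  if (n_rec != round(n_rec))
    stop("EDF output needs a whole number of 1 s data records")
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1  # avoid zero scale for flat channels

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * ns, 8), pad("", 44), pad(n_rec, 8), pad(1, 8),
    pad(ns, 4)), con, eos = NULL)
  field <- function(values, width)
    writeChar(paste(vapply(values, pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)                     # physical dimension
  field(sprintf("%.6g", phys_min), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep(-32768L, ns), 8)
  field(rep(32767L, ns), 8)
  field(rep("", ns), 80)                      # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                      # reserved
  scale <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((rec$data[, idx, drop = FALSE] - phys_min) / scale) - 32768
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' Parses the fixed-layout header and rescales digital samples back to
#' physical units.  Plain continuous EDF only (no EDF+ annotation channels);
#' all signals must share one sampling rate.
#'
#' @param path EDF file.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  ns <- as.integer(substr(hdr, 253, 256))
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  # per-signal field blocks, in on-disk order
  labels <- vapply(seq_len(ns) - 1L, function(i)
    trimws(substr(sig, i * 16 + 1, (i + 1) * 16)), "")
  off <- 16 * ns + 80 * ns + 8 * ns  # skip transducer + dimension
  num_block <- function(k, width) {
    start <- off + k * width * ns
    as.numeric(vapply(seq_len(ns) - 1L, function(i)
      trimws(substr(sig, start + i * width + 1,
                    start + (i + 1) * width)), ""))
  }
  phys_min <- num_block(0, 8); phys_max <- num_block(1, 8)
  dig_min <- num_block(2, 8);  dig_max <- num_block(3, 8)
  off2 <- off + 4 * 8 * ns + 80 * ns
  spr <- as.numeric(vapply(seq_len(ns) - 1L, function(i)
    trimws(substr(sig, off2 + i * 8 + 1, off2 + (i + 1) * 8)), ""))
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  p <- 0
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
      data[ch, idx] <- raw[(p + 1):(p + spr[ch])]
      p <- p + spr[ch]
    }
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- sweep(sweep(data, 1, dig_min) * scale, 1, phys_min, `+`)
  eeg_recording(data, spr[1] / rec_dur, labels)
}
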