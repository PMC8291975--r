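# Minimal EDF (European Data Format) 16-bit writer/reader.
# Signals are stored in 1-s data records; physical scaling is chosen per
# channel from the data range, so a write/read round trip reproduces each
# sample to within one quantization step of (max - min) / 65535.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write signals to an EDF file
#'
#' @param rec a `psg_recording` (all channels at the same rate).
#' @param path output file path.
#' @param start_time POSIXct recording start (defaults to a fixed origin so
#'   output is byte-reproducible).
#' @return `path`, invisibly. Samples beyond the last whole second are
#'   dropped (EDF records are 1 s long).
#' @export
write_edf <- function(rec, path,
                      start_time = as.POSIXct("2000-01-01 00:00:00",
                                              tz = "UTC")) {
  sig <- rec$signals
  ns <- length(sig)
  fs <- rec$fs
  n_rec <- min(vapply(sig, length, 1L)) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- sig[[i]][seq_len(n_rec * fs)]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    pmin_[i] <- lo; pmax_[i] <- hi
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr(format(start_time, "%d.%m.%y"), 8)
  wr(format(start_time, "%H.%M.%S"), 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)

  labels <- vapply(seq_len(ns), function(i) {
    paste(rec$roles[[names(sig)[i]]] %||% "SIG", names(sig)[i])
  }, "")
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                      # transducer
  for (i in seq_len(ns)) wr("uV", 8)                     # dimension
  for (i in seq_len(ns)) wr(formatC(pmin_[i], format = "g", digits = 7), 8)
  for (i in seq_len(ns)) wr(formatC(pmax_[i], format = "g", digits = 7), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)                      # prefilter
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_rec)) {
    sel <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      writeBin(dig[[i]][sel], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any 16-bit EDF with a
#' common sampling rate across channels)
#'
#' @param path EDF file path.
#' @return a `psg_recording` with channel names and roles recovered from
#'   the EDF labels (`"<ROLE> <name>"`).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad channel count")
  if (hdr_bytes != 256 * (ns + 1)) stop("malformed EDF: header size mismatch")

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i]) stop("malformed EDF: truncated data record")
      raw[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }

  signals <- list(); roles <- character(0)
  for (i in seq_len(ns)) {
    sc <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    x <- pmin_[i] + (raw[[i]] - dmin[i]) * sc
    parts <- strsplit(labels[i], "\\s+")[[1]]
    nm <- if (length(parts) > 1) paste(parts[-1], collapse = "_") else
      tolower(parts[1])
    signals[[nm]] <- x
    roles[nm] <- parts[1]
  }
  structure(list(signals = signals, fs = fs, roles = roles,
                 sites = NULL), class = "psg_recording")
}
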