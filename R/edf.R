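# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel recordings: ASCII header (256 bytes + 256 per signal),
# 16-bit little-endian samples, record-major with signal-major blocks
# inside each record.  Only the subset needed for plain continuous signals
# is supported (no EDF+ annotations, no per-signal sampling rates).

pad <- function(x, n) {
  s <- formatC(as.character(x), width = -n)
  if (nchar(s) > n) s <- substr(s, 1, n)
  s
}

edf_num <- function(x, n) {
  s <- formatC(x, width = -1, format = "g", digits = 8)
  if (nchar(s) > n) s <- substr(s, 1, n)
  pad(s, n)
}

write_edf <- function(record, path) {
  x <- record$samples
  n <- nrow(x); ns <- ncol(x)
  fs <- record$fs
  if (n == 0) stop("refusing to write an empty record")
  # whole-second records when possible, else one record for everything
  if (fs == round(fs) && n %% fs == 0) {
    spr <- as.integer(fs); nrec <- n %/% spr; dur <- 1
  } else {
    spr <- n; nrec <- 1L; dur <- n / fs
  }
  amax <- max(abs(x))
  pmin_ <- -1.05 * amax; pmax_ <- 1.05 * amax
  if (amax == 0) { pmin_ <- -1; pmax_ <- 1 }
  # quantize against the range as stored in the 8-char ASCII header fields,
  # so the reader reconstructs with exactly the same scale
  pmin_ <- as.numeric(edf_num(pmin_, 8))
  pmax_ <- as.numeric(edf_num(pmax_, 8))
  dmin <- -32768L; dmax <- 32767L
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- matrix(as.integer(round((x - pmin_) / scale)) + dmin, n, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic subject", 80), pad("semgrid export", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(nrec, 8),
    edf_num(dur, 8), pad(ns, 4),
    paste(vapply(record$channels, pad, "", n = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),        # transducer
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_num(pmin_, 8), ns), collapse = ""),
    paste(rep(edf_num(pmax_, 8), ns), collapse = ""),
    paste(rep(pad(dmin, 8), ns), collapse = ""),
    paste(rep(pad(dmax, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),        # prefilter
    paste(rep(pad(spr, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)           # patient/recording/date/time
  as.integer(rd(8))                      # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")       # transducer
  units <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")       # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1)
    stop("per-signal sampling rates are not supported")
  spr1 <- spr[1]
  n <- nrec * spr1
  x <- matrix(0, n, ns)
  for (r in seq_len(nrec)) {
    block <- readBin(con, integer(), n = spr1 * ns, size = 2,
                     endian = "little", signed = TRUE)
    x[((r - 1L) * spr1 + 1L):(r * spr1), ] <- matrix(block, spr1, ns)
  }
  for (s in seq_len(ns)) {
    sc <- (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
    x[, s] <- (x[, s] - dmin[s]) * sc + pmin_[s]
    u <- units[s]
    if (u %in% c("uV", "µV", "")) {
      # microvolts already
    } else if (u == "mV") {
      x[, s] <- x[, s] * 1000
    } else {
      stop("unsupported unit '", u, "' on signal ", labels[s],
           "; expected uV or mV")
    }
  }
  semg_record(x, fs = spr1 / dur, channels = labels)
}
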