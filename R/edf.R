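# Minimal EDF (European Data Format) support: continuous multi-channel
# recordings, 16-bit little-endian samples, 1-s data records, physical-unit
# scaling honored on read and write. Covers the subset of the format this
# package produces and consumes; EDF+ annotations are not supported.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

write_edf <- function(recording, path) {
  fs <- recording$fs
  n <- nrow(recording$samples)
  if (abs(n / fs - round(n / fs)) > 1e-9)
    stop("EDF writer requires a whole number of seconds (", n, " samples at ",
         fs, " Hz)")
  n_rec <- as.integer(round(n / fs))
  ns <- ncol(recording$samples)

  phys_min <- apply(recording$samples, 2, min)
  phys_max <- apply(recording$samples, 2, max)
  # widen degenerate ranges so the scale factor is finite
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  # quantize against the values as the 8-char header will carry them
  phys_min <- as.numeric(formatC(phys_min, digits = 5, format = "g"))
  phys_max <- as.numeric(formatC(phys_max, digits = 5, format = "g"))
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate 01-JAN-2000", recording$modality), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (ns + 1L), 8),
    edf_pad(paste0("modality=", recording$modality,
                   " start_time=", format(recording$start_time)), 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  unit <- switch(recording$modality, EEG = "uV", EDA = "uS", "au")
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(recording$channel_labels, 16)
  fld(rep("", ns), 80)
  fld(rep(unit, ns), 8)
  fld(formatC(phys_min, digits = 5, format = "g"), 8)
  fld(formatC(phys_max, digits = 5, format = "g"), 8)
  fld(rep(dig_min, ns), 8)
  fld(rep(dig_max, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(as.integer(fs), ns), 8)
  fld(rep("", ns), 32)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round(sweep(sweep(recording$samples, 2, phys_min), 2, scale, "/")) +
    dig_min
  dig <- matrix(as.integer(pmin(pmax(dig, dig_min), dig_max)), nrow = n)
  spr <- as.integer(fs)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(as.vector(dig[idx, , drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur))
    stop("unparseable EDF header in ", path)
  if (hdr_bytes != 256L * (ns + 1L))
    stop("corrupt EDF header (byte count mismatch) in ", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)                      # physical dimension
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)

  modality <- "EEG"; start_time <- 0
  m <- regmatches(reserved, regexec("modality=(\\S+) start_time=(\\S+)", reserved))[[1]]
  if (length(m) == 3L) { modality <- m[2]; start_time <- as.numeric(m[3]) }

  if (length(unique(spr)) != 1L)
    stop("EDF files with per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  dat <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", n = ns * spr[1], size = 2L, signed = TRUE,
                   endian = "little")
    dat[((r - 1L) * spr[1] + 1L):(r * spr[1]), ] <-
      matrix(blk, nrow = spr[1], ncol = ns)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  phys <- sweep(sweep(dat, 2, scale, "*"), 2, phys_min - dig_min * scale, "+")
  new_recording(phys, fs = fs, channel_labels = labels,
                modality = modality, start_time = start_time)
}
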