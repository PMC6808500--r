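# Minimal European Data Format (EDF) writer/reader.
#
# Supports the subset this package needs: one continuous recording, 1-second
# data records, per-signal sampling rates, 16-bit samples with per-signal
# physical scaling. Header fields follow the EDF specification (256-byte main
# header + 256 bytes per signal).

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write signals to an EDF file
#'
#' @param path Output file path.
#' @param signals List of signals, each a list with `label` (character),
#'   `fs` (integer samples/second), `data` (numeric vector), and optionally
#'   `unit`.
#' @param start Start date-time used in the header (character, informational).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, start = "01.01.26") {
  ns <- length(signals)
  fs_all <- vapply(signals, function(s) s$fs, numeric(1))
  durs <- vapply(signals, function(s) length(s$data) / s$fs, numeric(1))
  n_rec <- as.integer(ceiling(max(durs)))

  phys <- lapply(signals, function(s) {
    r <- range(s$data)
    if (diff(r) == 0) r <- r + c(-1, 1)
    r
  })

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic walkvep subject", 80),
    edf_pad("synthetic walkvep session", 80),
    edf_pad(start, 8), edf_pad("00.00.00", 8),
    edf_num(256 * (ns + 1), 8), edf_pad("", 44),
    edf_num(n_rec, 8), edf_num(1, 8), edf_num(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, width)
    writeChar(paste0(vapply(signals, f, character(1)), collapse = ""),
              con, eos = NULL)
  field(function(s) edf_pad(s$label, 16), 16)
  field(function(s) edf_pad("synthetic", 80), 80)
  field(function(s) edf_pad(s$unit %||% "uV", 8), 8)
  for (get in list(function(i) edf_num(phys[[i]][1], 8),
                   function(i) edf_num(phys[[i]][2], 8),
                   function(i) edf_num(-32768L, 8),
                   function(i) edf_num(32767L, 8)))
    writeChar(paste0(vapply(seq_len(ns), get, character(1)), collapse = ""),
              con, eos = NULL)
  field(function(s) edf_pad("", 80), 80)
  field(function(s) edf_num(s$fs, 8), 8)
  field(function(s) edf_pad("", 32), 32)

  # digitize
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- signals[[i]]$data
    length(d) <- n_rec * fs_all[i]          # zero-pad final record
    d[is.na(d)] <- phys[[i]][1]
    sc <- (d - phys[[i]][1]) / diff(phys[[i]]) * 65535 - 32768
    dig[[i]] <- as.integer(pmin(32767, pmax(-32768, round(sc))))
  }
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * fs_all[i] + 1):(r * fs_all[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any 16-bit EDF)
#'
#' @param path EDF file path.
#' @return List with `signals` (list of `label`, `fs`, `unit`, `data`) and
#'   `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  gf <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- gf(16); gf(80); units <- gf(8)
  pmin_ <- as.numeric(gf(8)); pmax_ <- as.numeric(gf(8))
  dmin <- as.numeric(gf(8)); dmax <- as.numeric(gf(8))
  gf(80)
  spr <- as.integer(gf(8))
  gf(32)

  data <- lapply(spr, function(k) numeric(k * n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      data[[i]][idx] <- (raw - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
    }
  }
  list(signals = purrr::map(seq_len(ns), function(i) {
    list(label = labels[i], fs = spr[i] / rec_dur, unit = units[i],
         data = data[[i]])
  }), n_records = n_rec)
}
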