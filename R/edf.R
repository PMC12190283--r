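# Minimal European Data Format (EDF) reader/writer.
#
# Covers the subset this pipeline needs: continuous 16-bit records, one-second
# data records, integer-second recordings, identical sampling rate across
# signals. Group and dataset labels are carried in the "local recording
# identification" header field as "grp=<g> ds=<d>".

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

# numeric to at most `width` ASCII chars, keeping as much precision as fits
edf_num <- function(x, width = 8) {
  for (d in seq(10, 1)) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stop("format error: cannot represent ", x, " in ", width, " chars")
}

#' Write a recording as an EDF file
#'
#' 16-bit EDF with one-second data records; requires an integer number of
#' seconds and an integer sampling rate. Physical ranges are per channel, so
#' round-tripping reproduces the signal to within 16-bit quantization of the
#' channel range.
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("format error: EDF writer needs integer fs")
  fs <- as.integer(round(fs))
  nsamp <- ncol(rec$data)
  if (nsamp %% fs != 0)
    stop("format error: EDF writer needs an integer number of seconds")
  nrec <- nsamp %/% fs
  ns <- nrow(rec$data)

  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  # store the (8-char-rounded) physical limits actually written, so the
  # digitization uses exactly what a reader will parse back
  pmin_s <- vapply(pmin, edf_num, "")
  pmax_s <- vapply(pmax, edf_num, "")
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  pmax[pmax - pmin <= 0] <- pmin[pmax - pmin <= 0] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id, 80))
  wr(edf_pad(sprintf("grp=%s ds=%s", rec$group, rec$dataset_id), 80))
  wr(edf_pad("01.01.26", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 + 256 * ns, 8))
  wr(edf_pad("", 44))
  wr(edf_pad(nrec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  for (fld in list(function(i) edf_pad(rec$channel_names[i], 16),
                   function(i) edf_pad("", 80),
                   function(i) edf_pad("uV", 8),
                   function(i) pmin_s[i],
                   function(i) pmax_s[i],
                   function(i) edf_pad("-32768", 8),
                   function(i) edf_pad("32767", 8),
                   function(i) edf_pad("", 80),
                   function(i) edf_pad(fs, 8),
                   function(i) edf_pad("", 32)))
    for (i in seq_len(ns)) wr(fld(i))

  scale <- (pmax - pmin) / 65535
  dig <- round(sweep(sweep(rec$data, 1, pmin), 1, scale, "/")) - 32768
  dig <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8)                                  # version
  subject_id <- trimws(rd(80))
  recid <- trimws(rd(80))
  rd(8); rd(8)                           # date, time
  num(8)                                 # header bytes
  rd(44)
  nrec <- num(8)
  recdur <- num(8)
  ns <- as.integer(num(4))
  if (is.na(nrec) || is.na(ns) || ns < 1) stop("format error: corrupt EDF header")
  ch <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # dimension
  pmin <- vapply(seq_len(ns), function(i) num(8), 0)
  pmax <- vapply(seq_len(ns), function(i) num(8), 0)
  dmin <- vapply(seq_len(ns), function(i) num(8), 0)
  dmax <- vapply(seq_len(ns), function(i) num(8), 0)
  for (i in seq_len(ns)) rd(80)          # prefilter
  spr <- vapply(seq_len(ns), function(i) num(8), 0)
  for (i in seq_len(ns)) rd(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr))))
    stop("format error: corrupt EDF signal headers")
  if (length(unique(spr)) != 1L)
    stop("format error: mixed per-signal sampling rates not supported")
  fs <- spr[1] / recdur

  data <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little", signed = TRUE)
    if (length(block) < ns * spr[1]) stop("format error: truncated EDF data")
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- t(matrix(block, nrow = spr[1]))
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  data <- sweep(sweep(data, 1, gain, "*"), 1, pmin - gain * dmin, "+")

  grp <- sub(".*grp=(\\S+).*", "\\1", recid)
  ds <- sub(".*ds=(\\S+).*", "\\1", recid)
  if (!grepl("grp=", recid)) grp <- NA_character_
  if (!grepl("ds=", recid)) ds <- NA_character_
  recording(data, fs, ch, subject_id = subject_id, group = grp,
            dataset_id = ds)
}
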