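#' Preprocessing configuration
#'
#' @param target_fs Common sampling rate in Hz after resampling (default 200).
#' @param band Band-pass edges `(low, high)` in Hz (default 0.5-45).
#' @param fir_order_window Band-pass FIR order expressed as a window length
#'   in seconds; the order is `fir_order_window * fs` samples (default 3).
#' @param transient_trim Seconds removed from the start of the filtered
#'   signal to discard the filter transient (default 3).
#' @param epoch_len Epoch length in seconds (default 3).
#' @param kaiser_fc_frac Resampler anti-aliasing cutoff as a fraction of the
#'   output Nyquist frequency (default 0.9).
#' @param kaiser_df_frac Resampler transition bandwidth as a fraction of the
#'   output Nyquist frequency (default 0.2).
#' @param artifact_hook Optional function `recording -> recording` applied
#'   after resampling and before filtering; pluggable stage for artifact
#'   removal (default identity).
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(target_fs = 200, band = c(0.5, 45),
                           fir_order_window = 3, transient_trim = 3,
                           epoch_len = 3, kaiser_fc_frac = 0.9,
                           kaiser_df_frac = 0.2, artifact_hook = NULL) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < target_fs / 2))
    stop("configuration error: need 0 < low < high < target_fs/2")
  if (epoch_len <= 0) stop("configuration error: epoch_len must be positive")
  structure(list(target_fs = target_fs, band = band,
                 fir_order_window = fir_order_window,
                 transient_trim = transient_trim, epoch_len = epoch_len,
                 kaiser_fc_frac = kaiser_fc_frac,
                 kaiser_df_frac = kaiser_df_frac,
                 artifact_hook = artifact_hook),
            class = "preproc_config")
}

#' Best rational approximation by continued fractions
#'
#' @param x Positive ratio to approximate.
#' @param max_den Largest admissible denominator (default 1000).
#' @return Integer vector `c(p, q)` with `p/q ~ x` and `q <= max_den`.
#' @export
rational_approx <- function(x, max_den = 1000L) {
  stopifnot(x > 0)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  repeat {
    a <- floor(b)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - x) < 1e-12) break
    if (b - a < 1e-12) break
    b <- 1 / (b - a)
  }
  c(p = as.integer(h1), q = as.integer(k1))
}

# Kaiser-window lowpass FIR: cutoff fc and transition width df in Hz at
# sampling rate fs; ripple `dev` sets the Kaiser beta and order by the
# standard design formulas. Returns odd-length, unit-DC-gain taps.
kaiser_lowpass <- function(fc, df, fs, dev = 0.002) {
  a_db <- -20 * log10(dev)
  beta <- if (a_db > 50) 0.1102 * (a_db - 8.7) else if (a_db >= 21)
    0.5842 * (a_db - 21)^0.4 + 0.07886 * (a_db - 21) else 0
  dw <- 2 * pi * df / fs
  n_ord <- ceiling((a_db - 7.95) / (2.285 * dw))
  len <- n_ord + 1L
  if (len %% 2L == 0L) len <- len + 1L
  mid <- (len - 1L) / 2L
  t <- seq_len(len) - 1L - mid
  fc_norm <- fc / (fs / 2)
  h <- fc_norm * sinc(fc_norm * t) * as.numeric(signal::kaiser(len, beta))
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Hamming windowed-sinc band-pass of the given order, built as the
# difference of two lowpasses each normalized to unit DC gain, so the DC
# gain of the band-pass is exactly zero.
fir_bandpass <- function(ord, f_lo, f_hi, fs) {
  len <- ord + 1L
  mid <- ord / 2
  t <- seq_len(len) - 1L - mid
  w <- as.numeric(signal::hamming(len))
  lp <- function(fc) {
    fcn <- fc / (fs / 2)
    h <- fcn * sinc(fcn * t) * w
    h / sum(h)
  }
  lp(f_hi) - lp(f_lo)
}

#' Resample a recording with a polyphase Kaiser-window FIR
#'
#' The rate ratio `target_fs / fs` is reduced to an integer fraction `p/q`
#' (falling back to the best rational approximation with denominator <= 1000,
#' with a message). The signal is upsampled by `p`, filtered with a
#' Kaiser-window anti-aliasing lowpass whose cutoff and transition width are
#' `kaiser_fc_frac` and `kaiser_df_frac` of the (lower of input/output)
#' Nyquist frequency, delay-compensated, and decimated by `q`.
#'
#' @param rec An [recording()].
#' @param target_fs Desired sampling rate in Hz.
#' @param kaiser_fc_frac,kaiser_df_frac Filter design fractions (defaults
#'   0.9 and 0.2, see [preproc_config()]).
#' @return The recording at `target_fs`.
#' @export
resample_polyphase <- function(rec, target_fs, kaiser_fc_frac = 0.9,
                               kaiser_df_frac = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"), rec$fs > 0)
  if (abs(rec$fs - target_fs) < 1e-12) return(rec)
  ratio <- target_fs / rec$fs
  pq <- rational_approx(ratio, 1000L)
  if (abs(pq[["p"]] / pq[["q"]] - ratio) > 1e-12)
    message(sprintf("resample: ratio %g approximated as %d/%d",
                    ratio, pq[["p"]], pq[["q"]]))
  p <- pq[["p"]]; q <- pq[["q"]]
  fs_up <- rec$fs * p
  nyq <- min(rec$fs, target_fs) / 2
  h <- kaiser_lowpass(kaiser_fc_frac * nyq, kaiser_df_frac * nyq, fs_up)
  mid <- (length(h) - 1L) / 2L
  n <- ncol(rec$data)
  n_out <- ceiling(n * p / q)
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    xu <- numeric(n * p + mid)
    xu[seq(1L, n * p, by = p)] <- rec$data[ch, ]
    y <- signal::fftfilt(p * h, xu)
    y <- y[(mid + 1L):(mid + n * p)]
    out[ch, ] <- y[seq(1L, n * p, by = q)][seq_len(n_out)]
  }
  recording(out, target_fs, rec$channel_names, rec$subject_id, rec$group,
            rec$dataset_id)
}

#' Band-pass filter a recording and trim the filter transient
#'
#' Causal windowed-sinc (Hamming) band-pass FIR of order
#' `fir_order_window * fs` applied per channel, then the first
#' `transient_trim` seconds are dropped, so the output is
#' `transient_trim` seconds shorter than the input.
#'
#' @param rec An [recording()] already at `cfg$target_fs`.
#' @param cfg A [preproc_config()].
#' @return The filtered, trimmed recording.
#' @export
bandpass_trim <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (abs(rec$fs - cfg$target_fs) > 1e-9)
    stop("bandpass_trim expects a recording at target_fs; resample first")
  fs <- rec$fs
  n <- ncol(rec$data)
  trim <- round(cfg$transient_trim * fs)
  if (n - trim < round(cfg$epoch_len * fs))
    stop("too-short error: recording shorter than transient_trim + one epoch")
  ord <- round(cfg$fir_order_window * fs)
  h <- fir_bandpass(ord, cfg$band[1], cfg$band[2], fs)
  out <- matrix(0, nrow(rec$data), n - trim)
  for (ch in seq_len(nrow(rec$data))) {
    y <- signal::fftfilt(h, rec$data[ch, ])
    out[ch, ] <- y[(trim + 1L):n]
  }
  recording(out, fs, rec$channel_names, rec$subject_id, rec$group,
            rec$dataset_id)
}

#' Split a recording into fixed-length non-overlapping epochs
#'
#' @param rec An [recording()].
#' @param epoch_len Epoch length in seconds (default 3).
#' @return An `eeg_epochs` object with an `epochs` array of dimension
#'   epoch x channel x sample; trailing samples that do not fill an epoch
#'   are discarded.
#' @export
epoch_recording <- function(rec, epoch_len = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_len * rec$fs)
  n <- ncol(rec$data)
  k <- n %/% len
  if (k < 1L) stop("too-short error: recording shorter than one epoch")
  ep <- array(0, dim = c(k, nrow(rec$data), len),
              dimnames = list(NULL, rec$channel_names, NULL))
  for (e in seq_len(k))
    ep[e, , ] <- rec$data[, ((e - 1L) * len + 1L):(e * len)]
  structure(list(subject_id = rec$subject_id, group = rec$group,
                 dataset_id = rec$dataset_id, fs = rec$fs,
                 channel_names = rec$channel_names, epochs = ep),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %s: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  invisible(x)
}
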