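#' Amplitude-transform specification
#'
#' The five amplitude conditions compared by the pipeline:
#' * `reference` - no transformation;
#' * `single_norm` / `global_norm` - min-max normalization to
#'   `[a_min, a_max]` with windowed-median extremes, fitted per channel
#'   (single) or over all channels jointly (global);
#' * `single_stand` / `global_stand` - standardization to zero mean and
#'   unit SD, with moments per channel (single) or pooled (global).
#'
#' @param condition One of `"reference"`, `"single_norm"`, `"global_norm"`,
#'   `"single_stand"`, `"global_stand"`.
#' @param a_min,a_max Output range of the min-max normalization
#'   (defaults -5 and +5, chosen so the normalized signal is symmetric with
#'   SD of order 1).
#' @param window_len Window length in seconds for the min-max extreme
#'   estimation (default 3).
#' @param window_stride Stride between windows in seconds; defaults to
#'   `window_len` (non-overlapping windows).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   for standardization moments.
#' @return A `transform_spec` list.
#' @export
transform_spec <- function(condition = c("reference", "single_norm",
                                         "global_norm", "single_stand",
                                         "global_stand"),
                           a_min = -5, a_max = 5, window_len = 3,
                           window_stride = window_len,
                           sd_type = c("sample", "population")) {
  condition <- match.arg(condition)
  if (a_min >= a_max) stop("configuration error: a_min must be < a_max")
  structure(list(condition = condition, a_min = a_min, a_max = a_max,
                 window_len = window_len, window_stride = window_stride,
                 sd_type = match.arg(sd_type)),
            class = "transform_spec")
}

sd_fun <- function(x, sd_type) {
  s <- sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  s
}

window_starts <- function(n, w, stride) {
  if (n < w) stop("too-short error: recording shorter than one window")
  seq(1L, n - w + 1L, by = stride)
}

#' Fit min-max normalization constants from windowed extremes
#'
#' Per window of `window_len` seconds, the maximum and minimum are taken
#' (per channel under `single_norm`; over all channels jointly under
#' `global_norm`). The fitted `x_max` and `x_min` are the medians of the
#' per-window maxima and minima, making the constants robust to isolated
#' extreme excursions.
#'
#' @param rec An [recording()] (post-filter, pre-epoching).
#' @param spec A [transform_spec()] with condition `single_norm` or
#'   `global_norm`.
#' @return A `transform_params` object holding `x_min`, `x_max`
#'   (length-n_channels vectors for single, scalars for global) and the
#'   output range.
#' @export
fit_minmax <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"),
            spec$condition %in% c("single_norm", "global_norm"))
  w <- round(spec$window_len * rec$fs)
  stride <- round(spec$window_stride * rec$fs)
  starts <- window_starts(ncol(rec$data), w, stride)
  if (spec$condition == "single_norm") {
    wmax <- vapply(starts, function(s)
      apply(rec$data[, s:(s + w - 1L), drop = FALSE], 1, max),
      numeric(nrow(rec$data)))
    wmin <- vapply(starts, function(s)
      apply(rec$data[, s:(s + w - 1L), drop = FALSE], 1, min),
      numeric(nrow(rec$data)))
    x_max <- apply(matrix(wmax, nrow = nrow(rec$data)), 1, median)
    x_min <- apply(matrix(wmin, nrow = nrow(rec$data)), 1, median)
  } else {
    wmax <- vapply(starts, function(s) max(rec$data[, s:(s + w - 1L)]), 0)
    wmin <- vapply(starts, function(s) min(rec$data[, s:(s + w - 1L)]), 0)
    x_max <- median(wmax)
    x_min <- median(wmin)
  }
  if (any(x_max - x_min <= 0))
    stop("degenerate-amplitude error: fitted x_min == x_max")
  structure(list(condition = spec$condition, x_min = x_min, x_max = x_max,
                 a_min = spec$a_min, a_max = spec$a_max,
                 subject_id = rec$subject_id,
                 channel_names = rec$channel_names),
            class = "transform_params")
}

#' Apply fitted min-max normalization
#'
#' Pure affine map `(a_max - a_min) * (x - x_min) / (x_max - x_min) + a_min`
#' using the channel's (single) or the shared (global) constants. Samples
#' outside `[x_min, x_max]` map outside `[a_min, a_max]`; no clipping is
#' performed, so the map stays affine and inter-channel correlations are
#' untouched.
#'
#' @param rec An [recording()].
#' @param params Fitted [fit_minmax()] parameters.
#' @return The normalized recording.
#' @export
apply_minmax <- function(rec, params) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(params, "transform_params"))
  nch <- nrow(rec$data)
  per_channel <- length(params$x_min) > 1L
  if (per_channel && length(params$x_min) != nch)
    stop("params error: channel count mismatch")
  span <- params$a_max - params$a_min
  if (per_channel) {
    scale <- span / (params$x_max - params$x_min)
    out <- sweep(rec$data, 1, params$x_min) * scale + params$a_min
  } else {
    out <- span * (rec$data - params$x_min) /
      (params$x_max - params$x_min) + params$a_min
  }
  recording(out, rec$fs, rec$channel_names, rec$subject_id, rec$group,
            rec$dataset_id)
}

#' Fit and apply standardization
#'
#' `(x - mean) / sd`, with moments computed over the whole recording per
#' channel (`single_stand`) or pooled over all channels (`global_stand`).
#' Single standardization leaves every channel with mean 0 and unit SD;
#' global standardization preserves the between-channel SD ratios.
#'
#' @param rec An [recording()] (post-filter, pre-epoching).
#' @param spec A [transform_spec()] with condition `single_stand` or
#'   `global_stand`.
#' @return List with elements `recording` (standardized) and `params`
#'   (a `transform_params` with `mean` and `sd`).
#' @export
fit_apply_stand <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"),
            spec$condition %in% c("single_stand", "global_stand"))
  if (spec$condition == "single_stand") {
    mu <- rowMeans(rec$data)
    s <- apply(rec$data, 1, sd_fun, sd_type = spec$sd_type)
  } else {
    mu <- mean(rec$data)
    s <- sd_fun(as.vector(rec$data), spec$sd_type)
  }
  if (any(s <= 0)) stop("degenerate-amplitude error: zero standard deviation")
  out <- if (length(s) > 1L)
    sweep(sweep(rec$data, 1, mu), 1, s, "/") else (rec$data - mu) / s
  params <- structure(list(condition = spec$condition, mean = mu, sd = s,
                           subject_id = rec$subject_id,
                           channel_names = rec$channel_names),
                      class = "transform_params")
  list(recording = recording(out, rec$fs, rec$channel_names, rec$subject_id,
                             rec$group, rec$dataset_id),
       params = params)
}

#' Apply one amplitude condition to a recording
#'
#' Dispatches on `spec$condition`; `reference` returns the input unchanged.
#' The fitted constants are attached as attribute `"transform_params"` for
#' audit (serializable with [jsonlite::write_json()]).
#'
#' @param rec An [recording()] (post-filter, pre-epoching).
#' @param spec A [transform_spec()].
#' @return The transformed recording.
#' @export
apply_condition <- function(rec, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  out <- switch(spec$condition,
    reference = rec,
    single_norm = ,
    global_norm = {
      params <- fit_minmax(rec, spec)
      r <- apply_minmax(rec, params)
      attr(r, "transform_params") <- params
      r
    },
    single_stand = ,
    global_stand = {
      fa <- fit_apply_stand(rec, spec)
      r <- fa$recording
      attr(r, "transform_params") <- fa$params
      r
    },
    stop("configuration error: unknown condition ", spec$condition))
  out
}
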