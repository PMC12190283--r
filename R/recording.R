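#' Standard 19-channel 10-20 montage
#'
#' Channel names of the 19-electrode international 10-20 scalp montage used
#' throughout the pipeline, in the conventional order.
#'
#' @return Character vector of 19 channel names.
#' @export
montage_1020 <- function() {
  c("Fp1", "F3", "C3", "P3", "O1", "Fp2", "F4", "C4", "P4", "O2",
    "F7", "T3", "T5", "F8", "T4", "T6", "FZ", "CZ", "PZ")
}

#' Construct a multichannel recording
#'
#' A recording bundles one subject's channels-by-samples signal matrix with
#' its acquisition metadata. Amplitudes are in arbitrary microvolt-like units.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id Subject identifier.
#' @param group Group label, typically `"HS"` or `"AD"`.
#' @param dataset_id Acquisition-source (site/dataset) identifier.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names,
                      subject_id = "S000", group = NA_character_,
                      dataset_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (length(channel_names) != nrow(data))
    stop("data must have length(channel_names) rows")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  if (anyNA(data)) stop("recording data must not contain NA/NaN")
  rownames(data) <- channel_names
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group),
                 dataset_id = as.character(dataset_id),
                 fs = as.numeric(fs),
                 channel_names = as.character(channel_names),
                 data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s  group=%s  dataset=%s\n",
              x$subject_id, x$group, x$dataset_id))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Subset and reorder a recording to a montage
#'
#' @param rec An `eeg_recording`.
#' @param montage Character vector of requested channel names, in the
#'   desired order.
#' @return The recording restricted to `montage`, rows in montage order.
#' @export
subset_montage <- function(rec, montage) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_ch <- setdiff(montage, rec$channel_names)
  if (length(missing_ch) > 0)
    stop("montage error: channels absent from recording: ",
         paste(missing_ch, collapse = ", "))
  idx <- match(montage, rec$channel_names)
  recording(rec$data[idx, , drop = FALSE], rec$fs, montage,
            rec$subject_id, rec$group, rec$dataset_id)
}
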