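#' Read a recording from disk
#'
#' Two on-disk formats are supported: 16-bit EDF (`format = "edf"`) and a
#' plain delimited matrix (`format = "matrix"`) of channels x samples with a
#' JSON sidecar `<path>.json` holding `fs`, `channel_names`, `subject_id`,
#' `group` and `dataset_id`.
#'
#' @param path File path.
#' @param format `"edf"` or `"matrix"`.
#' @param montage Optional character vector of channels to select and
#'   reorder; missing channels raise a montage error.
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("edf", "matrix"), montage = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: no such file: ", path)
  rec <- switch(format, edf = read_edf(path), matrix = read_matrix_rec(path))
  if (!is.null(montage)) rec <- subset_montage(rec, montage)
  rec
}

#' Write a recording as a delimited matrix plus JSON sidecar
#'
#' @param rec An [recording()].
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @param sep Field separator (default `","`).
#' @return Invisibly, `path`.
#' @export
write_matrix_rec <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(fs = rec$fs, channel_names = rec$channel_names,
               subject_id = rec$subject_id, group = rec$group,
               dataset_id = rec$dataset_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_matrix_rec <- function(path, sep = ",") {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: missing sidecar metadata ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("fs", "channel_names"))
    if (is.null(meta[[f]])) stop("format error: sidecar lacks field ", f)
  data <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  recording(data, meta$fs, meta$channel_names,
            subject_id = meta$subject_id %||% "S000",
            group = meta$group %||% NA_character_,
            dataset_id = meta$dataset_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
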