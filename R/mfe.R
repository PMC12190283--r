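#' Multiscale fuzzy entropy parameters
#'
#' @param m Embedding dimension (default 2).
#' @param n Fuzziness exponent of the membership function (default 2).
#' @param r_coef Tolerance coefficient; the tolerance is
#'   `r = r_coef * SD` of the series (default 0.2).
#' @param scales Integer scale factors for coarse-graining (default 1:20).
#' @param feature_scales Scales averaged into the long-scale feature
#'   (default 17:20).
#' @param r_convention `"fixed_from_scale1"` (default): the tolerance is
#'   computed once per epoch/channel from the SD of the unscaled (scale-1)
#'   series and reused at every scale; `"per_scale"`: recomputed from each
#'   coarse-grained series.
#' @param membership Functional form of the fuzzy membership:
#'   `"exp_d_n_over_r"` (default), `mu = exp(-d^n / r)`, under which the
#'   entropy is sensitive to amplitude scaling when `r` is proportional to
#'   the SD; or `"exp_d_over_r_n"`, `mu = exp(-(d/r)^n)`, which makes the
#'   statistic scale-invariant.
#' @return An `mfe_params` list.
#' @export
mfe_params <- function(m = 2L, n = 2, r_coef = 0.2, scales = 1:20,
                       feature_scales = 17:20,
                       r_convention = c("fixed_from_scale1", "per_scale"),
                       membership = c("exp_d_n_over_r", "exp_d_over_r_n")) {
  if (m < 1L) stop("parameter error: m must be >= 1")
  if (n <= 0 || r_coef <= 0)
    stop("parameter error: n and r_coef must be positive")
  if (!all(feature_scales %in% scales))
    stop("parameter error: feature_scales must be a subset of scales")
  structure(list(m = as.integer(m), n = n, r_coef = r_coef,
                 scales = as.integer(scales),
                 feature_scales = as.integer(feature_scales),
                 r_convention = match.arg(r_convention),
                 membership = match.arg(membership)),
            class = "mfe_params")
}

#' Coarse-grain a series
#'
#' Replaces consecutive non-overlapping blocks of `tau` samples by their
#' mean; trailing samples that do not fill a block are dropped.
#'
#' @param x Numeric series.
#' @param tau Integer scale factor (>= 1).
#' @return Series of length `floor(length(x) / tau)`.
#' @export
coarse_grain <- function(x, tau) {
  if (tau < 1 || tau != round(tau)) stop("parameter error: tau must be a positive integer")
  tau <- as.integer(tau)
  if (length(x) < tau) stop("parameter error: series shorter than tau")
  if (tau == 1L) return(x)
  k <- length(x) %/% tau
  colMeans(matrix(x[seq_len(k * tau)], nrow = tau))
}

#' Fuzzy entropy of a series
#'
#' `N - m` template vectors of length `m` and of length `m + 1` are formed,
#' each centred on its own mean; the membership of each pair is a function
#' of their Chebyshev distance, and the entropy is
#' `ln(phi^m) - ln(phi^(m+1))` (nats), where `phi` is the mean pairwise
#' membership. Returns `NaN` (with a warning) if the similarity sums
#' underflow to zero.
#'
#' @param x Numeric series of length at least `m + 2`.
#' @param m Embedding dimension.
#' @param n Fuzziness exponent.
#' @param r Tolerance (> 0).
#' @param membership Membership form, see [mfe_params()].
#' @return Entropy value in nats.
#' @export
fuzzy_entropy <- function(x, m = 2L, n = 2, r,
                          membership = c("exp_d_n_over_r", "exp_d_over_r_n")) {
  membership <- match.arg(membership)
  if (length(x) < m + 2L) stop("parameter error: series too short for m")
  if (!is.numeric(r) || r <= 0)
    stop("degenerate-tolerance error: r must be > 0")
  v <- .fuzzen_cpp(as.numeric(x), as.integer(m), n, r,
                   if (membership == "exp_d_n_over_r") 1L else 2L)
  if (is.na(v))
    warning("fuzzy_entropy degeneracy: similarity sum underflow, NaN returned")
  v
}

#' MFE curve of one epoch/channel series
#'
#' Fuzzy entropy of the coarse-grained series at each scale factor, with
#' tolerance `r = r_coef * SD` where the SD follows `params$r_convention`.
#'
#' @param x Numeric series (one epoch of one channel).
#' @param params An [mfe_params()].
#' @return Named numeric vector of entropies over `params$scales`.
#' @export
mfe_curve <- function(x, params = mfe_params()) {
  need <- max(params$scales) * (params$m + 2L)
  if (length(x) < need)
    stop("parameter error: series length must be >= max(scales) * (m + 2)")
  sd1 <- sd(x)
  if (params$r_convention == "fixed_from_scale1" && sd1 <= 0)
    stop("degenerate-tolerance error: constant series (zero SD)")
  out <- setNames(rep(NA_real_, length(params$scales)),
                  paste0("scale", params$scales))
  for (i in seq_along(params$scales)) {
    tau <- params$scales[[i]]
    y <- coarse_grain(x, tau)
    s <- if (params$r_convention == "fixed_from_scale1") sd1 else sd(y)
    if (is.na(s) || s <= 0) {
      warning("mfe_curve degeneracy at scale ", tau, ": zero SD, NaN returned")
      next
    }
    out[[i]] <- fuzzy_entropy(y, params$m, params$n, params$r_coef * s,
                              params$membership)
  }
  out
}

#' Multiscale fuzzy entropy of an epoched recording
#'
#' Computes the per-epoch, per-channel MFE curve over all scale factors.
#'
#' @param epochs An `eeg_epochs` object from [epoch_recording()].
#' @param params An [mfe_params()].
#' @return An `mfe_matrix`: `values` is an array of dimension
#'   epoch x channel x scale; entropy values are non-negative up to
#'   numerical noise, `NaN` only for logged degeneracies.
#' @export
compute_mfe <- function(epochs, params = mfe_params()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$epochs)
  vals <- array(NA_real_, dim = c(d[1], d[2], length(params$scales)),
                dimnames = list(NULL, epochs$channel_names,
                                paste0("scale", params$scales)))
  for (e in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      vals[e, ch, ] <- mfe_curve(epochs$epochs[e, ch, ], params)
  structure(list(subject_id = epochs$subject_id, group = epochs$group,
                 dataset_id = epochs$dataset_id, values = vals,
                 params = params),
            class = "mfe_matrix")
}

#' @export
print.mfe_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mfe_matrix> %s (%s/%s): %d epochs x %d channels x %d scales\n",
              x$subject_id, x$group, x$dataset_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Long-scale MFE features of one subject
#'
#' One observation per epoch; one feature per channel, the mean MFE over
#' `params$feature_scales`. Observations containing `NaN` features are kept
#' but flagged in attribute `"flagged"`.
#'
#' @param mfe An `mfe_matrix` from [compute_mfe()].
#' @return Data frame with columns `subject_id`, `group`, `dataset_id`,
#'   `epoch` and one column per channel.
#' @export
extract_features <- function(mfe) {
  stopifnot(inherits(mfe, "mfe_matrix"))
  params <- mfe$params
  sc_idx <- match(params$feature_scales, params$scales)
  if (anyNA(sc_idx)) stop("parameter error: feature scales not present")
  feat <- apply(mfe$values[, , sc_idx, drop = FALSE], c(1, 2), mean)
  df <- data.frame(subject_id = mfe$subject_id, group = mfe$group,
                   dataset_id = mfe$dataset_id,
                   epoch = seq_len(nrow(feat)), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(feat))
  attr(df, "flagged") <- which(apply(feat, 1, anyNA))
  class(df) <- c("mfe_features", "data.frame")
  df
}

#' Bind per-subject feature tables into one observation table
#'
#' @param feature_list List of [extract_features()] outputs.
#' @return A single `mfe_features` data frame.
#' @export
combine_features <- function(feature_list) {
  df <- do.call(rbind, lapply(feature_list, function(x) {
    class(x) <- "data.frame"
    x
  }))
  rownames(df) <- NULL
  class(df) <- c("mfe_features", "data.frame")
  df
}

#' Names of the feature columns of an observation table
#'
#' @param ft An `mfe_features` data frame.
#' @return Character vector of per-channel feature column names.
#' @export
feature_cols <- function(ft) {
  setdiff(names(ft), c("subject_id", "group", "dataset_id", "epoch"))
}

#' Write an MFE matrix in long CSV format
#'
#' Columns: `subject_id`, `epoch`, `channel`, `scale`, `value`.
#'
#' @param mfe An `mfe_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_mfe_csv <- function(mfe, path) {
  d <- dim(mfe$values)
  long <- data.frame(
    subject_id = mfe$subject_id,
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(dimnames(mfe$values)[[2]], each = d[1]), times = d[3]),
    scale = rep(mfe$params$scales, each = d[1] * d[2]),
    value = as.vector(mfe$values))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
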