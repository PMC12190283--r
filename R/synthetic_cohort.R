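#' Configuration for the synthetic EEG cohort generator
#'
#' Defines a two-group (`HS` vs `AD`), two-site cohort of multichannel
#' recordings whose statistical structure mirrors what the MFE analysis
#' assumes: the groups differ in signal dynamics (and hence in long-scale
#' multiscale fuzzy entropy), while per-subject and per-site multiplicative
#' gains add a label-independent amplitude confound that emulates
#' heterogeneous acquisition hardware.
#'
#' Each channel is `dataset_gain * subject_gain * channel_gain *
#' (group process + white noise)`. The group process for `HS` is a fast
#' AR(1); for `AD` the same AR(1) plus a strongly autocorrelated slow
#' component (`slow_weight` times the base process SD) that carries extra
#' low-frequency power and survives coarse-graining, raising long-scale
#' entropy relative to `HS`.
#'
#' @param n_subjects_per_group Subjects per group (default 52).
#' @param n_channels Number of channels (default 19, the 10-20 montage).
#' @param fs Sampling rate in Hz (default 200).
#' @param duration Recording length in seconds (default 51).
#' @param group_dynamics Named list with one entry per group, each a list
#'   with elements `ar` (AR(1) coefficient of the fast process),
#'   `slow_weight` (SD of the slow component relative to the fast process
#'   SD) and `slow_ar` (AR(1) coefficient of the slow component).
#' @param channel_gain_profile Named list with one positive gain vector of
#'   length `n_channels` per group.
#' @param subject_gain_sigma Log-scale SD of the per-subject multiplicative
#'   gain, `gain ~ LogNormal(0, sigma)` (default 0.5).
#' @param dataset_gains Named vector of global per-site gains
#'   (default `c(A = 1, B = 3)`).
#' @param dataset_props Named vector of per-group subject proportions per
#'   site (default 35:17, i.e. `c(A = 35/52, B = 17/52)`).
#' @param noise_sd SD of additive white sensor noise (default 0.5).
#' @param common_weight Mixing weight of a shared across-channel component,
#'   in `[0, 1)`; gives physiological-looking inter-channel correlation
#'   (default 0.4).
#' @param amplitude_scale Overall output scale to microvolt-like units
#'   (default 10).
#' @param seed Integer seed; each subject gets an RNG stream derived from
#'   `(seed, subject index)` so cohorts are extensible without reshuffling.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects_per_group = 52L,
                         n_channels = 19L,
                         fs = 200,
                         duration = 51,
                         group_dynamics = list(
                           HS = list(ar = 0.88, slow_weight = 0, slow_ar = 0.95),
                           AD = list(ar = 0.88, slow_weight = 2.0, slow_ar = 0.95)),
                         channel_gain_profile = NULL,
                         subject_gain_sigma = 0.5,
                         dataset_gains = c(A = 1.0, B = 3.0),
                         dataset_props = c(A = 35 / 52, B = 17 / 52),
                         noise_sd = 0.5,
                         common_weight = 0.4,
                         amplitude_scale = 10,
                         seed = 1L) {
  groups <- names(group_dynamics)
  if (length(groups) != 2L || anyDuplicated(groups))
    stop("configuration error: exactly two distinct group labels required")
  if (is.null(channel_gain_profile))
    channel_gain_profile <- setNames(
      rep(list(rep(1, n_channels)), 2L), groups)
  cfg <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
              n_channels = as.integer(n_channels),
              fs = fs, duration = duration,
              group_dynamics = group_dynamics,
              channel_gain_profile = channel_gain_profile,
              subject_gain_sigma = subject_gain_sigma,
              dataset_gains = dataset_gains,
              dataset_props = dataset_props,
              noise_sd = noise_sd,
              common_weight = common_weight,
              amplitude_scale = amplitude_scale,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$fs <= 0 || cfg$duration <= 0)
    stop("configuration error: fs and duration must be positive")
  if (abs(cfg$duration * cfg$fs - round(cfg$duration * cfg$fs)) > 1e-9)
    stop("configuration error: duration * fs must be an integer sample count")
  if (any(cfg$dataset_gains <= 0))
    stop("configuration error: dataset gains must be positive")
  if (length(cfg$dataset_gains) < 2L)
    stop("configuration error: at least two dataset ids required")
  if (cfg$subject_gain_sigma < 0)
    stop("configuration error: subject_gain_sigma must be >= 0")
  for (g in names(cfg$channel_gain_profile)) {
    prof <- cfg$channel_gain_profile[[g]]
    if (length(prof) != cfg$n_channels || any(prof <= 0))
      stop("configuration error: channel gain profile must be positive and ",
           "of length n_channels")
  }
  invisible(cfg)
}

# Stationary AR(1) series with unit-variance innovations scaled to a target
# marginal SD; burn-in dropped so the start is (approximately) stationary.
ar1_series <- function(n, phi, target_sd, burn = 2000L) {
  innov_sd <- target_sd * sqrt(1 - phi^2)
  x <- stats::filter(rnorm(n + burn, sd = innov_sd), phi, method = "recursive")
  as.numeric(x)[(burn + 1L):(burn + n)]
}

# Group process: fast AR(1) plus an optional slow, strongly autocorrelated
# component. The mixture is rescaled to the same marginal SD regardless of
# slow_weight, so the groups differ in temporal structure (spectrum) but not
# in amplitude: amplitude stays a pure acquisition confound.
group_process <- function(n, dyn) {
  base_sd <- 1 / sqrt(1 - dyn$ar^2)
  x <- ar1_series(n, dyn$ar, base_sd)
  if (dyn$slow_weight > 0) {
    x <- x + ar1_series(n, dyn$slow_ar, dyn$slow_weight * base_sd)
    x <- x / sqrt(1 + dyn$slow_weight^2)
  }
  x
}

subject_seed <- function(seed, idx) {
  as.integer((as.double(seed) + 1000003 * idx) %% 2147483647)
}

#' Generate a synthetic EEG cohort
#'
#' Produces one seeded recording per subject according to a
#' [synth_config()]. Deterministic given the configuration seed: each
#' subject draws from an RNG stream derived from `(seed, subject index)`,
#' so growing the cohort does not reshuffle existing subjects. Subject and
#' dataset gains are assigned independently of the group label, making
#' amplitude a pure confound.
#'
#' @param config A `synth_config`.
#' @return List of [recording()] objects (first group block first).
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  n <- config$n_subjects_per_group
  groups <- names(config$group_dynamics)
  nsamp <- as.integer(round(config$duration * config$fs))
  ch_names <- if (config$n_channels == 19L) montage_1020() else
    sprintf("CH%02d", seq_len(config$n_channels))
  ds_ids <- names(config$dataset_gains)
  # deterministic per-group site assignment, identical pattern in both
  # groups so the gain structure is label-independent
  n_per_ds <- round(config$dataset_props[seq_along(ds_ids)] * n)
  n_per_ds[length(n_per_ds)] <- n - sum(n_per_ds[-length(n_per_ds)])
  ds_of_subject <- rep(ds_ids, times = n_per_ds)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  cohort <- vector("list", 2L * n)
  idx <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    dyn <- config$group_dynamics[[g]]
    ch_gain <- config$channel_gain_profile[[g]]
    for (si in seq_len(n)) {
      idx <- idx + 1L
      set.seed(subject_seed(config$seed, idx))
      ds <- ds_of_subject[[si]]
      sgain <- exp(rnorm(1, 0, config$subject_gain_sigma))
      common <- group_process(nsamp, dyn)
      w <- config$common_weight
      data <- matrix(0, config$n_channels, nsamp)
      for (ch in seq_len(config$n_channels)) {
        private <- group_process(nsamp, dyn)
        sig <- w * common + sqrt(1 - w^2) * private +
          rnorm(nsamp, sd = config$noise_sd)
        data[ch, ] <- config$amplitude_scale * config$dataset_gains[[ds]] *
          sgain * ch_gain[[ch]] * sig
      }
      cohort[[idx]] <- recording(data, config$fs, ch_names,
                                 subject_id = sprintf("S%03d", idx),
                                 group = g, dataset_id = ds)
    }
  }
  cohort
}

#' Subject metadata of a cohort
#'
#' @param cohort List of recordings.
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `dataset_id`.
#' @export
cohort_meta <- function(cohort) {
  data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
             group = vapply(cohort, `[[`, "", "group"),
             dataset_id = vapply(cohort, `[[`, "", "dataset_id"),
             stringsAsFactors = FALSE)
}

#' Write a cohort to disk as EDF files plus a manifest
#'
#' One EDF file per subject and a `manifest.csv` with columns
#' `subject_id`, `group`, `dataset_id`, `file`.
#'
#' @param cohort List of recordings.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(cohort, function(rec) {
    f <- file.path(dir, paste0(rec$subject_id, ".edf"))
    write_edf(rec, f)
    basename(f)
  }, "")
  manifest <- cbind(cohort_meta(cohort), file = files)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the EDF files.
#' @return List of recordings in manifest order.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_recording(file.path(dir, manifest$file[i]), format = "edf")
    rec$subject_id <- manifest$subject_id[i]
    rec$group <- manifest$group[i]
    rec$dataset_id <- manifest$dataset_id[i]
    rec
  })
}
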