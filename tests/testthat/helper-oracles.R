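# Independent brute-force fuzzy-entropy oracle: explicit double loop over
# ordered pairs, no vectorized reuse; mirrors only the definition.
fuzzen_oracle <- function(x, m, n, r) {
  N <- length(x)
  Nm <- N - m
  phi <- function(mm) {
    total <- 0
    for (i in 1:Nm) {
      si <- 0
      for (j in 1:Nm) {
        if (j == i) next
        vi <- x[i:(i + mm - 1)]
        vj <- x[j:(j + mm - 1)]
        d <- max(abs((vi - mean(vi)) - (vj - mean(vj))))
        si <- si + exp(-d^n / r)
      }
      total <- total + si / (Nm - 1)
    }
    total / Nm
  }
  log(phi(m)) - log(phi(m + 1))
}

# small, fast cohort configuration for structural tests
tiny_config <- function(...) {
  synth_config(n_subjects_per_group = 2L, n_channels = 3L, fs = 100,
               duration = 9, ...)
}

# exchangeable two-group configuration: identical dynamics, no gain
# heterogeneity -- the no-signal null
null_config <- function(n = 16L, seed = 1L, subject_gain_sigma = 0,
                        dataset_gains = c(A = 1, B = 1), ...) {
  dyn <- list(HS = list(ar = 0.88, slow_weight = 0, slow_ar = 0.95),
              AD = list(ar = 0.88, slow_weight = 0, slow_ar = 0.95))
  synth_config(n_subjects_per_group = n, group_dynamics = dyn,
               subject_gain_sigma = subject_gain_sigma,
               dataset_gains = dataset_gains, seed = seed, ...)
}

wn_recording <- function(nch = 2L, nsamp = 1200L, fs = 200, sd = 1,
                         seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  recording(matrix(rnorm(nch * nsamp, sd = sd), nch, nsamp), fs,
            sprintf("CH%02d", seq_len(nch)), ...)
}

# hand-built MFE matrix for feature-arithmetic tests
fake_mfe <- function(values, params = mfe_params(), subject_id = "S001",
                     group = "AD", dataset_id = "A") {
  structure(list(subject_id = subject_id, group = group,
                 dataset_id = dataset_id, values = values, params = params),
            class = "mfe_matrix")
}
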