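test_that("coarse-graining averages non-overlapping blocks", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  x <- rnorm(37)
  expect_identical(coarse_grain(x, 1), x)
  set.seed(23)
  y <- rnorm(600)
  cg <- coarse_grain(y, 20)
  expect_length(cg, 30L)
  for (j in seq_len(30)) {
    block <- 0
    for (k in 1:20) block <- block + y[(j - 1) * 20 + k]
    expect_equal(cg[[j]], block / 20, tolerance = 1e-12)
  }
  expect_equal(length(coarse_grain(rnorm(41), 20)), 2L)  # remainder dropped
  expect_error(coarse_grain(y, 0), "parameter error")
})

test_that("fuzzy entropy matches the brute-force double-loop oracle", {
  set.seed(29)
  for (i in 1:6) {
    x <- rnorm(sample(50:120, 1))
    r <- 0.2 * sd(x)
    expect_equal(fuzzy_entropy(x, 2, 2, r), fuzzen_oracle(x, 2, 2, r),
                 tolerance = 1e-10)
  }
  # non-default m and n
  x <- rnorm(80)
  expect_equal(fuzzy_entropy(x, 3, 1.5, 0.3), fuzzen_oracle(x, 3, 1.5, 0.3),
               tolerance = 1e-10)
})

test_that("fuzzy entropy limit and degeneracy behaviour", {
  set.seed(31)
  x <- rnorm(100)
  # r -> Inf: membership -> 1 everywhere, entropy -> 0
  expect_lt(abs(fuzzy_entropy(x, 2, 2, 1e12)), 1e-9)
  expect_error(fuzzy_entropy(x, 2, 2, 0), "degenerate-tolerance")
  expect_error(mfe_curve(rep(1, 600)), "degenerate-tolerance")
  # non-increasing in the tolerance r
  rs <- 0.2 * sd(x) * c(0.5, 1, 2, 5, 20)
  vals <- vapply(rs, function(r) fuzzy_entropy(x, 2, 2, r), 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("MFE is shift-invariant but amplitude-sensitive under the default membership", {
  set.seed(37)
  x <- rnorm(600)
  pr <- mfe_params(scales = c(1, 3, 5), feature_scales = 5)
  base <- mfe_curve(x, pr)
  expect_equal(mfe_curve(x + 100, pr), base, tolerance = 1e-10)
  expect_gt(max(abs(mfe_curve(2 * x, pr) - base)), 1e-3)
  # the alternative membership form exp(-(d/r)^n) with r ~ SD is
  # scale-invariant, collapsing all amplitude conditions
  pr2 <- mfe_params(scales = c(1, 3, 5), feature_scales = 5,
                    membership = "exp_d_over_r_n")
  expect_equal(mfe_curve(2 * x, pr2), mfe_curve(x, pr2), tolerance = 1e-10)
})

test_that("entropy is non-negative and scale 1 equals the raw-series entropy", {
  set.seed(41)
  for (i in 1:25) {
    x <- as.numeric(arima.sim(list(ar = runif(1, 0, 0.9)), 120))
    v <- fuzzy_entropy(x, 2, 2, 0.2 * sd(x))
    expect_gte(v, -1e-12)
  }
  x <- rnorm(400)
  pr <- mfe_params(scales = 1:3, feature_scales = 3)
  expect_equal(unname(mfe_curve(x, pr)[["scale1"]]),
               fuzzy_entropy(x, 2, 2, 0.2 * sd(x)), tolerance = 1e-12)
})

test_that("white-noise MFE regression fixtures and tolerance conventions", {
  set.seed(424)
  x <- rnorm(600)
  fixed <- mfe_curve(x, mfe_params(scales = c(1, 5, 10, 20),
                                   feature_scales = 20))
  per <- mfe_curve(x, mfe_params(scales = c(1, 5, 10, 20),
                                 feature_scales = 20,
                                 r_convention = "per_scale"))
  expect_equal(unname(fixed),
               c(1.3784397554, 0.6532984148, 0.5050059379, 0.3403937998),
               tolerance = 1e-8)
  expect_equal(unname(per),
               c(1.3784397554, 1.0187054590, 0.9683267188, 0.7633590580),
               tolerance = 1e-8)
  # white noise loses entropy monotonically across scales under per_scale
  expect_true(all(diff(per) < 0))
})

test_that("long-scale feature extraction averages the right scales", {
  pr <- mfe_params()
  vals <- array(0, dim = c(2, 3, 20),
                dimnames = list(NULL, c("C3", "C4", "CZ"),
                                paste0("scale", 1:20)))
  vals[1, 1, 17:20] <- c(1, 2, 3, 4)
  vals[2, , 17:20] <- 7
  ft <- extract_features(fake_mfe(vals, pr))
  expect_equal(ft$C3[1], 2.5)
  expect_equal(unlist(ft[2, c("C3", "C4", "CZ")]), c(C3 = 7, C4 = 7, CZ = 7))
  expect_identical(nrow(ft), 2L)
  # NaN in the feature band flags the observation
  vals[1, 2, 18] <- NaN
  ft2 <- extract_features(fake_mfe(vals, pr))
  expect_true(is.na(ft2$C4[1]))
  expect_identical(attr(ft2, "flagged"), 1L)
})

test_that("compute_mfe fills the epoch x channel x scale array", {
  rec <- wn_recording(nch = 2L, nsamp = 1200L, fs = 200, seed = 47)
  ep <- epoch_recording(rec, 3)
  pr <- mfe_params(scales = c(1, 17:20))
  mm <- compute_mfe(ep, pr)
  expect_identical(dim(mm$values), c(2L, 2L, 5L))
  expect_false(anyNA(mm$values))
  expect_equal(unname(mm$values[1, 2, "scale1"]),
               fuzzy_entropy(ep$epochs[1, 2, ], 2, 2,
                             0.2 * sd(ep$epochs[1, 2, ])),
               tolerance = 1e-12)
})
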