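make_smfe <- function(values, group, dataset = NULL) {
  n <- dim(values)[1]
  list(values = values, group = group,
       dataset_id = if (is.null(dataset)) rep("A", n) else dataset)
}

test_that("identical groups give p = 1 everywhere and an empty mask", {
  set.seed(61)
  half <- array(rnorm(4 * 3 * 5), dim = c(4, 3, 5),
                dimnames = list(NULL, c("C3", "C4", "CZ"),
                                paste0("scale", 1:5)))
  values <- array(0, dim = c(8, 3, 5), dimnames = dimnames(half))
  values[1:4, , ] <- half
  values[5:8, , ] <- half
  res <- ttest_grid_fdr(make_smfe(values, rep(c("HS", "AD"), each = 4)))
  expect_true(all(abs(res$p_raw - 1) < 1e-12))
  expect_false(any(res$mask))
})

test_that("BH adjustment over the grid matches the step-up definition", {
  set.seed(67)
  values <- array(rnorm(20 * 4 * 6), dim = c(20, 4, 6))
  values[11:20, , 1:2] <- values[11:20, , 1:2] + 1.2   # some real effects
  res <- ttest_grid_fdr(make_smfe(values, rep(c("HS", "AD"), each = 10)))
  p <- as.vector(res$p_raw)
  m <- length(p)
  # independent step-up oracle: adj_i = min_{j >= rank(i)} (m * p_(j) / j)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (j in rev(seq_len(m))) {
    running <- min(running, m * p[o[j]] / j)
    adj[o[j]] <- running
  }
  expect_equal(as.vector(res$p_adj), adj, tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  # toy quadruple from the step-up rule: all four rejected at q = 0.05
  toy <- c(0.01, 0.02, 0.03, 0.04)
  expect_true(all(rev(cummin(rev(length(toy) * toy / seq_along(toy)))) <
                    0.05))
})

test_that("Cohen's d matches hand-computed values", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(2, 4), c(0, 2)), sqrt(2), tolerance = 1e-12)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
})

test_that("mixed ANOVA: a duplicated null dataset factor is not significant", {
  set.seed(71)
  y <- matrix(rnorm(12 * 8), 12, 8) +
    outer(rep(c(0, 1), each = 6), seq(0, 1, length.out = 8))
  values <- array(0, dim = c(24, 1, 8))
  values[1:12, 1, ] <- y
  values[13:24, 1, ] <- y    # identical copy labelled as dataset B
  sm <- make_smfe(values, rep(rep(c("HS", "AD"), each = 6), 2),
                  dataset = rep(c("A", "B"), each = 12))
  out <- mixed_anova(sm)
  tab <- out$table
  expect_gt(tab$p[tab$effect == "Dataset"], 0.99)
  expect_lt(tab$p[tab$effect == "Scale"], 0.05)   # built-in scale trend
  expect_true(all(c("Scale", "Group", "Dataset", "Scale x Group") %in%
                    tab$effect))
})

test_that("mixed ANOVA group p-values are calibrated under permutation", {
  set.seed(73)
  n <- 20
  values <- array(rnorm(n * 1 * 8), dim = c(n, 1, 8))
  dataset <- rep(c("A", "B"), each = n / 2)
  hits <- 0
  n_perm <- 200
  for (i in seq_len(n_perm)) {
    grp <- sample(rep(c("HS", "AD"), each = n / 2))
    out <- mixed_anova(make_smfe(values, grp, dataset))
    p <- out$table$p[out$table$effect == "Group"]
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits / n_perm, 0.10)
})

test_that("paired accuracy comparison handles ties and degenerate cases", {
  mk <- function(acc) structure(list(per_subject = data.frame(
    subject_id = sprintf("S%02d", seq_along(acc)), accuracy = acc)),
    class = "eval_report")
  a <- mk(c(0.5, 0.6, 0.7, 0.8))
  expect_equal(accuracy_condition_test(a, a)$p, 0.5)
  up <- mk(c(0.5, 0.6, 0.7, 0.8) + 0.1)
  res <- accuracy_condition_test(a, up)
  expect_true(res$degenerate)
  expect_identical(res$p, 0)
  down <- mk(c(0.5, 0.6, 0.7, 0.8) - 0.1)
  expect_identical(accuracy_condition_test(a, down)$p, 1)
  set.seed(79)
  b <- mk(c(0.52, 0.63, 0.68, 0.81))
  expect_false(accuracy_condition_test(a, b)$degenerate)
  other <- mk(c(0.5, 0.6)); other$per_subject$subject_id <- c("X1", "X2")
  expect_error(accuracy_condition_test(a, other), "pairing error")
})

test_that("averaged correlation matrices match a direct computation", {
  set.seed(83)
  recs <- lapply(1:3, function(i)
    wn_recording(nch = 3L, nsamp = 400L, fs = 100, seed = 83 + i,
                 subject_id = sprintf("S%02d", i)))
  # duplicated channel correlates at exactly 1
  recs[[1]]$data[3, ] <- recs[[1]]$data[2, ]
  out <- correlation_preservation(recs, list("reference", "global_norm",
                                             "single_stand"))
  expect_lt(max(abs(out$global_norm - out$reference)), 1e-9)
  expect_lt(max(abs(out$single_stand - out$reference)), 1e-9)
  # brute-force averaged pairwise correlation oracle
  manual <- matrix(0, 3, 3)
  for (rec in recs) {
    m <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      xi <- rec$data[i, ]; xj <- rec$data[j, ]
      m[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
        sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    }
    manual <- manual + m / length(recs)
  }
  expect_equal(unname(out$reference), manual, tolerance = 1e-12)
  expect_equal(cor(recs[[1]]$data[2, ], recs[[1]]$data[3, ]), 1)
})

test_that("raw t-test grid is calibrated at the nominal level under the null", {
  set.seed(89)
  values <- array(rnorm(30 * 26 * 20), dim = c(30, 26, 20))
  res <- ttest_grid_fdr(make_smfe(values, rep(c("HS", "AD"), 15)))
  rate <- mean(res$p_raw < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
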