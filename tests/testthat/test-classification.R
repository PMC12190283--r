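# small synthetic feature tables: `sep` controls cluster separation
make_ft <- function(n_subj = 6L, n_epoch = 4L, n_feat = 2L, sep = 0,
                    seed = 1L) {
  set.seed(seed)
  groups <- rep(c("HS", "AD"), each = n_subj / 2)
  rows <- list()
  for (s in seq_len(n_subj)) {
    mu <- if (groups[[s]] == "AD") sep else 0
    f <- matrix(rnorm(n_epoch * n_feat, mean = mu), n_epoch, n_feat)
    colnames(f) <- sprintf("f%d", seq_len(n_feat))
    rows[[s]] <- cbind(
      data.frame(subject_id = sprintf("S%02d", s), group = groups[[s]],
                 dataset_id = rep(c("A", "B"), length.out = n_subj)[s],
                 epoch = seq_len(n_epoch), stringsAsFactors = FALSE),
      as.data.frame(f))
  }
  ft <- do.call(rbind, rows)
  class(ft) <- c("mfe_features", "data.frame")
  ft
}

test_that("MCC and accuracy arithmetic from confusion counts", {
  expect_identical(mcc_counts(240, 240, 0, 0), 1)
  expect_identical(mcc_counts(7, 7, 7, 7), 0)
  expect_equal(classification_accuracy(12, 0, 0, 4), 0.75)
  expect_identical(mcc_counts(0, 0, 240, 240), -1)
  # prediction inversion flips the MCC sign
  set.seed(53)
  for (i in 1:20) {
    cnt <- sample(1:50, 4)
    expect_equal(mcc_counts(cnt[4], cnt[3], cnt[2], cnt[1]),
                 -mcc_counts(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-12)
  }
  # degenerate marginal: defined as 0
  expect_identical(mcc_counts(5, 0, 0, 5), 0)
})

test_that("hyperparameter grids enumerate the declared values in order", {
  svm <- grid_default("svm")
  expect_identical(nrow(svm), 49L)
  expect_equal(svm$C[1:7], rep(0.1, 7))
  expect_equal(svm$gamma[1:7], c(0.01, 0.05, 0.1, 0.5, 0.7, 0.9, 1))
  rf <- grid_default("rf")
  expect_identical(nrow(rf), 81L)
  expect_equal(rf[1, ],
               data.frame(n_estimators = 50, max_depth = 10,
                          min_samples_split = 2, min_samples_leaf = 1),
               ignore_attr = TRUE)
  knn <- grid_default("knn")
  expect_identical(nrow(knn), 30L)
  expect_identical(knn$metric[1:3],
                   c("euclidean", "manhattan", "minkowski"))
})

test_that("split plans are disjoint, stratified and seeded", {
  meta <- data.frame(
    subject_id = sprintf("S%03d", 1:40),
    group = rep(c("HS", "AD"), each = 20),
    dataset_id = rep(rep(c("A", "B"), c(13, 7)), 2),
    stringsAsFactors = FALSE)
  sp <- split_plan(meta, test_frac = 0.3, seed = 4)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), meta$subject_id)
  tg <- table(meta$group[meta$subject_id %in% sp$test])
  expect_equal(unname(tg[["HS"]]), unname(tg[["AD"]]))
  expect_identical(split_plan(meta, test_frac = 0.3, seed = 4)$test, sp$test)
  expect_false(identical(split_plan(meta, test_frac = 0.3, seed = 5)$test,
                         sp$test))
  sp2 <- split_plan(meta, test_counts = c(A = 3, B = 2), seed = 1)
  expect_length(sp2$test, 10L)
})

test_that("grid search returns the single point and breaks ties by order", {
  ft <- make_ft(n_subj = 6L, sep = 10, seed = 7)
  g1 <- grid_reduced("knn")[1, , drop = FALSE]
  sel <- loso_select(ft, "knn", g1, seed = 1)
  expect_equal(sel$params, g1, ignore_attr = TRUE)
  expect_equal(sel$cv_accuracy, 1)
  # perfectly separable: every grid point reaches accuracy 1, first wins
  g <- grid_default("knn")[1:6, ]
  sel2 <- loso_select(ft, "knn", g, seed = 1)
  expect_true(all(sel2$grid_accuracy$accuracy == 1))
  expect_equal(sel2$params, g[1, , drop = FALSE], ignore_attr = TRUE)
})

test_that("LOSO KNN selection matches an independent naive re-evaluation", {
  ft <- make_ft(n_subj = 6L, n_epoch = 5L, sep = 1.2, seed = 11)
  grid <- grid_df_oracle <- expand.grid(
    n_neighbors = c(3, 5), weights = c("uniform", "distance"),
    metric = c("euclidean", "manhattan"), stringsAsFactors = FALSE)
  sel <- loso_select(ft, "knn", grid, seed = 1)

  # naive independent loop: z-score on the retained subjects, whole-matrix
  # distances, explicit vote counting
  X <- as.matrix(ft[, c("f1", "f2")])
  y <- ft$group
  subj <- ft$subject_id
  oracle_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    k <- grid$n_neighbors[g]
    hits <- 0
    for (s in unique(subj)) {
      tr <- subj != s
      mu <- colMeans(X[tr, ]); sv <- apply(X[tr, ], 2, sd)
      Z <- sweep(sweep(X, 2, mu), 2, sv, "/")
      for (i in which(!tr)) {
        p <- if (grid$metric[g] == "manhattan") 1 else 2
        d <- (rowSums(abs(sweep(Z[tr, , drop = FALSE], 2, Z[i, ]))^p))^(1 / p)
        nn <- order(d)[seq_len(k)]
        w <- if (grid$weights[g] == "distance") 1 / d[nn] else rep(1, k)
        vote <- tapply(w, y[tr][nn], sum)
        hits <- hits + (names(vote)[which.max(vote)] == y[i])
      }
    }
    oracle_acc[g] <- hits / length(subj)
  }
  expect_equal(sel$grid_accuracy$accuracy, oracle_acc, tolerance = 1e-12)
  expect_equal(unlist(sel$params),
               unlist(grid[which.max(oracle_acc), ]))
})

test_that("evaluation reports per-subject accuracy, uncertainty and MCC", {
  train <- make_ft(n_subj = 8L, n_epoch = 6L, sep = 3, seed = 13)
  test <- make_ft(n_subj = 6L, n_epoch = 6L, sep = 3, seed = 14)
  test$subject_id <- sub("S", "T", test$subject_id)
  rep <- fit_evaluate(train, test, "knn", grid_reduced("knn")[1, ],
                      seed = 1)
  expect_identical(nrow(rep$per_subject), 6L)
  expect_true(all(rep$per_subject$accuracy >= 0 &
                    rep$per_subject$accuracy <= 1))
  expect_gte(rep$mcc, -1); expect_lte(rep$mcc, 1)
  expect_identical(unname(sum(rep$confusion)), rep$n_test_obs)
  expect_equal(rep$uncertainty,
               2 * sd(rep$per_subject$accuracy) / sqrt(6), tolerance = 1e-12)
  expect_gt(rep$mean_accuracy, 0.9)  # well-separated clusters
  # leakage guard
  expect_error(fit_evaluate(train, train, "knn", grid_reduced("knn")[1, ]),
               "leakage error")
})

test_that("all three classifier backends train and predict on separable data", {
  train <- make_ft(n_subj = 8L, n_epoch = 6L, sep = 4, seed = 17)
  test <- make_ft(n_subj = 4L, n_epoch = 6L, sep = 4, seed = 18)
  test$subject_id <- sub("S", "T", test$subject_id)
  for (fam in c("svm", "rf", "knn")) {
    rep <- fit_evaluate(train, test, fam, grid_reduced(fam)[1, ], seed = 1)
    expect_gt(rep$mean_accuracy, 0.9)
    expect_gt(rep$mcc, 0.8)
  }
})
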