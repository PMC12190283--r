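#' Hyperparameter grids for the three classifier families
#'
#' `grid_default()` returns the full search grid for a family: SVM (RBF
#' kernel; `C` in 0.1-100, `gamma` in 0.01-1), random forest
#' (`n_estimators`, `max_depth` with `NA` = unlimited, `min_samples_split`,
#' `min_samples_leaf`) and KNN (`n_neighbors`, `weights`, `metric`).
#' Combinations are enumerated in declaration order with the
#' later-listed hyperparameter varying fastest; grid-search ties are broken
#' in favour of the earliest combination.
#'
#' @param family `"svm"`, `"rf"` or `"knn"`.
#' @return Data frame of hyperparameter combinations.
#' @export
grid_default <- function(family = c("svm", "rf", "knn")) {
  family <- match.arg(family)
  values <- switch(family,
    svm = list(C = c(0.1, 1, 10, 50, 70, 90, 100),
               gamma = c(0.01, 0.05, 0.1, 0.5, 0.7, 0.9, 1),
               kernel = "rbf"),
    rf = list(n_estimators = c(50, 100, 200),
              max_depth = c(10, 20, NA),
              min_samples_split = c(2, 5, 10),
              min_samples_leaf = c(1, 2, 4)),
    knn = list(n_neighbors = c(3, 5, 7, 9, 11),
               weights = c("uniform", "distance"),
               metric = c("euclidean", "manhattan", "minkowski")))
  grid_df(values)
}

#' @rdname grid_default
#' @details `grid_reduced()` is a small sub-grid of the full one, intended
#'   for simulation studies and tests where the full search is not the
#'   object of interest.
#' @export
grid_reduced <- function(family = c("svm", "rf", "knn")) {
  family <- match.arg(family)
  values <- switch(family,
    svm = list(C = c(1, 10), gamma = c(0.01, 0.1), kernel = "rbf"),
    rf = list(n_estimators = 100, max_depth = c(10, NA),
              min_samples_split = 2, min_samples_leaf = 1),
    knn = list(n_neighbors = c(5, 9), weights = "distance",
               metric = "euclidean"))
  grid_df(values)
}

# enumerate combinations with the first-listed hyperparameter varying
# slowest (odometer order over the declared value lists)
grid_df <- function(values) {
  g <- expand.grid(rev(values), stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Stratified train/test split of subjects
#'
#' Subjects are split so that (i) no subject's epochs straddle the split and
#' (ii) both sets contain the same number of subjects from each group,
#' stratified by acquisition dataset. Within each (group, dataset) cell the
#' same per-dataset test count is drawn for both groups, seeded.
#'
#' @param meta Data frame with columns `subject_id`, `group`, `dataset_id`
#'   (one row per subject), e.g. from [cohort_meta()].
#' @param test_frac Fraction of each dataset's per-group subjects assigned
#'   to the test set (default 30/104, the study-scale split).
#' @param test_counts Optional named vector: per-dataset test count per
#'   group (overrides `test_frac`), e.g. `c(A = 9, B = 6)`.
#' @param seed Integer seed for the random subject draw.
#' @return A `split_plan` with `train` and `test` subject-id vectors.
#' @export
split_plan <- function(meta, test_frac = 30 / 104, test_counts = NULL,
                       seed = 1L) {
  stopifnot(all(c("subject_id", "group", "dataset_id") %in% names(meta)))
  groups <- sort(unique(meta$group))
  datasets <- sort(unique(meta$dataset_id))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  test_ids <- character(0)
  for (d in datasets) {
    cells <- lapply(groups, function(g)
      meta$subject_id[meta$group == g & meta$dataset_id == d])
    k <- if (!is.null(test_counts)) test_counts[[d]] else
      round(test_frac * min(lengths(cells)))
    if (any(lengths(cells) < k))
      stop("split error: dataset ", d, " has fewer subjects than test count")
    for (cell in cells)
      test_ids <- c(test_ids, sort(cell)[sample.int(length(cell), k)])
  }
  train_ids <- setdiff(meta$subject_id, test_ids)
  structure(list(train = train_ids, test = test_ids, seed = seed,
                 strata = table(group = meta$group,
                                dataset = meta$dataset_id,
                                split = ifelse(meta$subject_id %in% test_ids,
                                               "test", "train"))),
            class = "split_plan")
}

ft_matrix <- function(ft) {
  x <- as.matrix(ft[, feature_cols(ft), drop = FALSE])
  storage.mode(x) <- "double"
  x
}

ft_labels <- function(ft, positive = "AD") {
  levs <- c(setdiff(unique(ft$group), positive), positive)
  factor(ft$group, levels = levs)
}

drop_flagged <- function(ft) {
  x <- ft_matrix(ft)
  bad <- apply(x, 1, anyNA)
  if (any(bad)) {
    message("dropping ", sum(bad), " observations with NaN features")
    ft <- ft[!bad, , drop = FALSE]
  }
  ft
}

zscore_fit <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s <= 0] <- 1
  list(mean = mu, sd = s)
}

zscore_apply <- function(x, zs) {
  sweep(sweep(x, 2, zs$mean), 2, zs$sd, "/")
}

fit_model <- function(family, params, x, y, seed = 1L) {
  switch(family,
    svm = e1071::svm(x = x, y = y, type = "C-classification",
                     kernel = "radial", cost = params$C,
                     gamma = params$gamma, scale = FALSE),
    rf = ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = params$n_estimators,
      max.depth = if (is.na(params$max_depth)) NULL else params$max_depth,
      min.node.size = params$min_samples_split,
      min.bucket = params$min_samples_leaf,
      seed = seed, num.threads = 1),
    knn = list(x = x, y = y, k = params$n_neighbors,
               weights = params$weights, metric = params$metric),
    stop("configuration error: unknown classifier family ", family))
}

predict_model <- function(family, model, x) {
  switch(family,
    svm = predict(model, x),
    rf = predict(model, data = as.data.frame(x),
                 num.threads = 1)$predictions,
    knn = knn_predict(model$x, model$y, x, model$k, model$weights,
                      model$metric))
}

# weighted k-nearest-neighbour classifier; euclidean/minkowski use p = 2,
# manhattan p = 1; "distance" weights are 1/d with exact matches dominating
knn_predict <- function(train_x, train_y, test_x, k, weights, metric) {
  p <- if (metric == "manhattan") 1 else 2
  D <- matrix(0, nrow(test_x), nrow(train_x))
  for (j in seq_len(ncol(train_x)))
    D <- D + abs(outer(test_x[, j], train_x[, j], "-"))^p
  D <- D^(1 / p)
  levs <- levels(train_y)
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nn <- order(D[i, ], seq_along(train_y))[seq_len(k)]
    w <- if (weights == "distance") 1 / pmax(D[i, nn], 1e-12) else rep(1, k)
    votes <- tapply(w, factor(train_y[nn], levels = levs), sum, default = 0)
    pred[i] <- levs[which.max(votes)]
  }
  factor(pred, levels = levs)
}

#' Leave-one-subject-out grid-search model selection
#'
#' For every hyperparameter combination, each training subject is held out
#' in turn: the model is fitted on the remaining subjects' observations
#' (with per-feature z-scoring fitted on those subjects only, so no
#' information leaks from the held-out subject) and validated on the
#' held-out subject's observations. The combination with the highest mean
#' validation accuracy is selected; ties go to the earliest combination in
#' grid order.
#'
#' @param train_ft Feature table (observations of the training subjects).
#' @param family `"svm"`, `"rf"` or `"knn"`.
#' @param grid Hyperparameter grid, e.g. [grid_default()].
#' @param seed Integer seed (forwarded to stochastic learners).
#' @param optimize `"observation"` (default): accuracy over all held-out
#'   observations; `"subject"`: mean of per-subject accuracies.
#' @return A `loso_selection` with the chosen `params` and the per-point
#'   accuracies.
#' @export
loso_select <- function(train_ft, family, grid = grid_default(family),
                        seed = 1L, optimize = c("observation", "subject")) {
  optimize <- match.arg(optimize)
  train_ft <- drop_flagged(train_ft)
  x <- ft_matrix(train_ft)
  y <- ft_labels(train_ft)
  subj <- train_ft$subject_id
  subjects <- unique(subj)
  if (length(subjects) < 2L)
    stop("parameter error: LOSO needs at least 2 training subjects")
  folds <- lapply(subjects, function(s) subj == s)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- grid[g, , drop = FALSE]
    correct <- total <- 0
    per_subj <- numeric(length(folds))
    for (f in seq_along(folds)) {
      held <- folds[[f]]
      zs <- zscore_fit(x[!held, , drop = FALSE])
      model <- fit_model(family, params,
                         zscore_apply(x[!held, , drop = FALSE], zs),
                         y[!held], seed = seed)
      pred <- predict_model(family, model,
                            zscore_apply(x[held, , drop = FALSE], zs))
      hits <- pred == y[held]
      correct <- correct + sum(hits)
      total <- total + length(hits)
      per_subj[[f]] <- mean(hits)
    }
    acc[[g]] <- if (optimize == "observation") correct / total else
      mean(per_subj)
  }
  best <- which.max(acc)
  structure(list(family = family, params = grid[best, , drop = FALSE],
                 cv_accuracy = acc[[best]],
                 grid_accuracy = cbind(grid, accuracy = acc)),
            class = "loso_selection")
}

#' Retrain on the full training set and evaluate on held-out subjects
#'
#' Features are z-scored with moments from the training set only. Reports
#' per-subject accuracy, their mean with expanded uncertainty
#' `k * sd / sqrt(K)` (coverage factor `k = 2`, approximately a 95%
#' interval over `K` test subjects), the pooled confusion counts over all
#' test observations, and the Matthews correlation coefficient.
#'
#' @param train_ft,test_ft Feature tables with disjoint subjects.
#' @param family Classifier family.
#' @param params One-row data frame of hyperparameters (e.g.
#'   `loso_select(...)$params`).
#' @param seed Integer seed for stochastic learners.
#' @param positive Positive class label (default `"AD"`).
#' @return An `eval_report`.
#' @export
fit_evaluate <- function(train_ft, test_ft, family, params, seed = 1L,
                         positive = "AD") {
  if (length(intersect(unique(train_ft$subject_id),
                       unique(test_ft$subject_id))) > 0)
    stop("leakage error: train and test subjects overlap")
  train_ft <- drop_flagged(train_ft)
  test_ft <- drop_flagged(test_ft)
  x_tr <- ft_matrix(train_ft)
  y_tr <- ft_labels(train_ft, positive)
  x_te <- ft_matrix(test_ft)
  y_te <- factor(test_ft$group, levels = levels(y_tr))
  zs <- zscore_fit(x_tr)
  model <- fit_model(family, params, zscore_apply(x_tr, zs), y_tr,
                     seed = seed)
  pred <- predict_model(family, model, zscore_apply(x_te, zs))

  subjects <- unique(test_ft$subject_id)
  acc <- vapply(subjects, function(s) {
    i <- test_ft$subject_id == s
    mean(pred[i] == y_te[i])
  }, 0)
  tp <- sum(pred == positive & y_te == positive)
  tn <- sum(pred != positive & y_te != positive)
  fp <- sum(pred == positive & y_te != positive)
  fn <- sum(pred != positive & y_te == positive)
  structure(list(
    family = family, params = params, condition = NA_character_,
    per_subject = data.frame(
      subject_id = subjects,
      group = test_ft$group[match(subjects, test_ft$subject_id)],
      accuracy = unname(acc), stringsAsFactors = FALSE),
    mean_accuracy = mean(acc),
    uncertainty = 2 * sd(acc) / sqrt(length(acc)),
    k = 2,
    mcc = mcc_counts(tp, tn, fp, fn),
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
    n_test_obs = length(pred)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s%s: accuracy %.1f%% +/- %.1f%% (k=%d), MCC %.3f\n",
              x$family,
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              100 * x$mean_accuracy, 100 * x$uncertainty, x$k, x$mcc))
  cat(sprintf("  confusion TP=%d TN=%d FP=%d FN=%d over %d observations\n",
              x$confusion[["TP"]], x$confusion[["TN"]], x$confusion[["FP"]],
              x$confusion[["FN"]], x$n_test_obs))
  invisible(x)
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`;
#' defined as 0 when any marginal is empty.
#'
#' @param tp,tn,fp,fn Confusion-matrix counts.
#' @return MCC value.
#' @export
mcc_counts <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Classification accuracy from confusion counts
#'
#' @param tp,tn,fp,fn Confusion-matrix counts.
#' @return `(TP + TN) / (TP + TN + FP + FN)`.
#' @export
classification_accuracy <- function(tp, tn, fp, fn) {
  (tp + tn) / (tp + tn + fp + fn)
}
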