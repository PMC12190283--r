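#' Per-subject MFE summary array
#'
#' Averages each subject's MFE over epochs, yielding one value per
#' subject, channel and scale — the unit of analysis for the group tests
#' (avoids pseudo-replication of epochs).
#'
#' @param mfe_list List of `mfe_matrix` objects, one per subject.
#' @return List with `values` (array subject x channel x scale), `group`
#'   and `dataset_id` vectors.
#' @export
subject_mfe <- function(mfe_list) {
  arrs <- lapply(mfe_list, function(m) apply(m$values, c(2, 3), mean))
  values <- aperm(simplify2array(arrs), c(3, 1, 2))
  dimnames(values)[[1]] <- vapply(mfe_list, `[[`, "", "subject_id")
  list(values = values,
       group = vapply(mfe_list, `[[`, "", "group"),
       dataset_id = vapply(mfe_list, `[[`, "", "dataset_id"))
}

#' Welch t-test grid over scales and channels with FDR correction
#'
#' Two-tailed Welch tests comparing the groups' per-subject MFE within each
#' (scale, channel) cell; Benjamini-Hochberg adjustment is applied across
#' the full grid and the significance mask is taken at the adjusted level.
#'
#' @param smfe A [subject_mfe()] summary.
#' @param alpha Significance level for the mask (default 0.05).
#' @return An `mfe_ttest_grid` with raw and adjusted p-value matrices
#'   (scale x channel), the significance `mask`, a matching Cohen's `d`
#'   grid, and indices of cells flagged as undefined (zero variance in both
#'   groups).
#' @export
ttest_grid_fdr <- function(smfe, alpha = 0.05) {
  groups <- unique(smfe$group)
  if (length(groups) != 2L) stop("parameter error: exactly two groups required")
  a <- smfe$values[smfe$group == groups[[1]], , , drop = FALSE]
  b <- smfe$values[smfe$group == groups[[2]], , , drop = FALSE]
  if (dim(a)[1] < 2L || dim(b)[1] < 2L)
    stop("parameter error: at least 2 subjects per group required")
  n_ch <- dim(smfe$values)[2]
  n_sc <- dim(smfe$values)[3]
  p <- d <- matrix(NA_real_, n_sc, n_ch,
                   dimnames = list(dimnames(smfe$values)[[3]],
                                   dimnames(smfe$values)[[2]]))
  for (sc in seq_len(n_sc))
    for (ch in seq_len(n_ch)) {
      va <- a[, ch, sc]
      vb <- b[, ch, sc]
      p[sc, ch] <- tryCatch(t.test(va, vb)$p.value, error = function(e) NA_real_)
      d[sc, ch] <- cohens_d(va, vb)
    }
  p_adj <- p
  ok <- !is.na(p)
  p_adj[ok] <- p.adjust(p[ok], method = "BH")
  structure(list(groups = groups, p_raw = p, p_adj = p_adj,
                 mask = !is.na(p_adj) & p_adj < alpha, cohens_d = d,
                 alpha = alpha, flagged = which(!ok, arr.ind = TRUE)),
            class = "mfe_ttest_grid")
}

#' Cohen's d effect size
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled SD using `n - 1`
#' weights. Undefined (NA) when the pooled SD is zero.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return Effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("parameter error: need >= 2 values per group")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Mixed-design ANOVA of channel-averaged MFE
#'
#' Within-subject factor: scale (one level per scale factor); between
#' factors: group and dataset. Channel-averaged per-subject MFE values are
#' analysed with type-III sums of squares; within-factor p-values carry a
#' Greenhouse-Geisser sphericity correction where the error structure
#' permits estimating it (it always does at the intended cohort sizes; with
#' fewer subjects than within levels, uncorrected p-values are returned and
#' `gg_applied` is `FALSE`).
#'
#' @param smfe A [subject_mfe()] summary (values are averaged over the
#'   channel dimension internally).
#' @return An `mfe_anova`: data frame of effects (`Scale`, `Group`,
#'   `Dataset`, `Scale x Group`, plus remaining interactions) with F and
#'   p-values.
#' @export
mixed_anova <- function(smfe) {
  y <- apply(smfe$values, c(1, 3), mean)   # subject x scale
  n_sc <- ncol(y)
  bt <- data.frame(group = factor(smfe$group),
                   dataset = factor(smfe$dataset_id))
  if (any(table(bt$group, bt$dataset) == 0))
    stop("parameter error: empty group x dataset cell")
  mod <- lm(y ~ group * dataset, data = bt,
            contrasts = list(group = contr.sum, dataset = contr.sum))
  av <- car::Anova(mod, idata = data.frame(scale = factor(seq_len(n_sc))),
                   idesign = ~scale, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  adj <- s$pval.adjustments
  gg <- function(term) {
    if (!is.null(adj) && term %in% rownames(adj) &&
        is.finite(adj[term, "Pr(>F[GG])"]))
      adj[term, "Pr(>F[GG])"] else NA_real_
  }
  terms <- c(Scale = "scale", Group = "group", Dataset = "dataset",
             `Scale x Group` = "group:scale",
             `Group x Dataset` = "group:dataset",
             `Scale x Dataset` = "dataset:scale",
             `Scale x Group x Dataset` = "group:dataset:scale")
  terms <- terms[terms %in% rownames(ut)]
  within <- grepl("scale", terms)
  p_unc <- ut[terms, "Pr(>F)"]
  p_gg <- vapply(terms, gg, 0)
  gg_applied <- within & is.finite(p_gg)
  tab <- data.frame(effect = names(terms),
                    F = ut[terms, "F value"],
                    num_df = ut[terms, "num Df"],
                    den_df = ut[terms, "den Df"],
                    p_uncorrected = p_unc,
                    p = ifelse(gg_applied, p_gg, p_unc),
                    gg_applied = gg_applied,
                    row.names = NULL)
  structure(list(table = tab, gg_applied = all(gg_applied[within])),
            class = "mfe_anova")
}

#' @export
print.mfe_anova <- function(x, ...) {
  cat("<mfe_anova> mixed-design ANOVA (type III",
      if (x$gg_applied) ", GG-corrected within effects" else "", ")\n",
      sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Paired one-tailed comparison of per-subject accuracies
#'
#' Tests whether a transform condition improves per-subject classification
#' accuracy over the reference condition, using a paired one-tailed t-test
#' (alternative: condition greater than reference) on the same test
#' subjects. If the paired differences have zero variance the p-value is
#' degenerate and reported as 0, 0.5 or 1 according to the sign of the
#' mean difference, with `degenerate = TRUE`.
#'
#' @param report_ref,report_cond `eval_report`s for the reference and the
#'   transform condition, from the same split.
#' @return List with `p`, `mean_difference`, `t` and `degenerate`.
#' @export
accuracy_condition_test <- function(report_ref, report_cond) {
  ref <- report_ref$per_subject
  cond <- report_cond$per_subject
  if (!setequal(ref$subject_id, cond$subject_id))
    stop("pairing error: reports cover different test subjects")
  diffs <- cond$accuracy[match(ref$subject_id, cond$subject_id)] -
    ref$accuracy
  if (sd(diffs) == 0) {
    p <- if (mean(diffs) > 0) 0 else if (mean(diffs) < 0) 1 else 0.5
    return(list(p = p, mean_difference = mean(diffs), t = NA_real_,
                degenerate = TRUE))
  }
  tt <- t.test(diffs, alternative = "greater")
  list(p = tt$p.value, mean_difference = mean(diffs),
       t = unname(tt$statistic), degenerate = FALSE)
}

#' Averaged inter-channel correlation matrices per condition
#'
#' For each amplitude condition, computes every subject's channel-by-channel
#' Pearson correlation matrix over the full transformed recording and
#' averages them across subjects. Because all four transforms are
#' per-channel affine maps with positive slope, these matrices should match
#' the reference to numerical precision.
#'
#' @param recordings List of post-filter recordings (one per subject).
#' @param conditions List of [transform_spec()]s (or condition-name
#'   strings) to evaluate.
#' @return Named list of averaged correlation matrices.
#' @export
correlation_preservation <- function(recordings,
                                     conditions = list("reference",
                                                       "global_norm")) {
  conditions <- lapply(conditions, function(cnd)
    if (inherits(cnd, "transform_spec")) cnd else transform_spec(cnd))
  out <- list()
  for (spec in conditions) {
    mats <- lapply(recordings, function(rec) {
      tr <- apply_condition(rec, spec)
      if (any(apply(tr$data, 1, sd) == 0))
        warning("constant channel in ", rec$subject_id,
                ": undefined correlation entries")
      suppressWarnings(cor(t(tr$data)))
    })
    out[[spec$condition]] <- Reduce(`+`, mats) / length(mats)
  }
  out
}
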