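#' Random-forest configuration
#'
#' Mirrors a default-settings protocol: 1000 trees (enough for the
#' out-of-bag accuracy to have converged at these sample sizes), 10-fold
#' stratified cross-validation, all other hyperparameters at the
#' randomForest library defaults, no tuning.
#'
#' @param n_trees number of trees, >= 1 (default 1000).
#' @param cv_folds number of CV folds, >= 2 (default 10).
#' @param seed integer seed controlling fold assignment and forest growth.
#' @return a list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000, cv_folds = 10, seed = 1L) {
  if (n_trees < 1) abort("`n_trees` must be >= 1.", class = "swayrisk_parameter_error")
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.", class = "swayrisk_parameter_error")
  structure(list(n_trees = as.integer(n_trees), cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Diagnostic metrics from a pooled confusion matrix
#'
#' Accuracy `(TP + TN) / (TP + FN + TN + FP)`, sensitivity `TP / (TP + FN)`
#' and specificity `TN / (TN + FP)`, evaluated exactly on the counts. A zero
#' denominator yields `NA` for the affected rate.
#'
#' @param tp,fn,tn,fp non-negative integer counts; either pass the four
#'   counts or a single named vector/list as `tp`.
#' @return one-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' diagnostic_metrics(tp = 8, fn = 2, tn = 9, fp = 1)
diagnostic_metrics <- function(tp, fn = NULL, tn = NULL, fp = NULL) {
  if (is.null(fn) && (is.list(tp) || length(tp) == 4)) {
    cm <- tp
    tp <- cm[["tp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]; fp <- cm[["fp"]]
  }
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("Confusion counts must be non-negative with positive total.",
          class = "swayrisk_input_error")
  }
  tibble(
    accuracy = (tp + tn) / (tp + fn + tn + fp),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

# Stratified fold ids: within each class, shuffle members and deal them
# round-robin into folds, so every fold holds ~n/k of each class.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      abort(paste0("Class '", cl, "' has ", length(idx),
                   " members, fewer than cv_folds = ", k,
                   "; reduce the number of folds."),
            class = "swayrisk_stratification_error")
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Median imputation fit on training rows only (no label leakage): returns
# the feature matrix with NAs in both splits replaced by training medians.
impute_median <- function(x_train, x_test) {
  med <- vapply(x_train, function(v) median(v, na.rm = TRUE), numeric(1))
  med[!is.finite(med)] <- 0
  fill <- function(df) {
    for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- med[j]
    df
  }
  list(train = fill(x_train), test = fill(x_test))
}

#' Cross-validated random-forest comparison of two groups
#'
#' Trains and evaluates a random forest discriminating `group_a` from
#' `group_b` through stratified k-fold cross-validation. Out-of-fold
#' predictions are pooled into a single confusion matrix from which
#' accuracy, sensitivity and specificity are computed (micro-averaging,
#' which is stable at the small per-group sample sizes typical of clinical
#' cohorts). Missing feature values are median-imputed with medians fit on
#' each training fold only. Fully reproducible given `config$seed`.
#'
#' @param data data frame with a `risk_group` column and the feature
#'   columns.
#' @param group_a,group_b the two group labels to compare.
#' @param features character vector of feature column names.
#' @param positive which group counts as the positive class for
#'   sensitivity; defaults to the higher-risk group of the pair (group
#'   order `HC < MS_Low < MS_Mod < MS_High`).
#' @param config a [forest_config()].
#' @return object of class `sway_comparison`: list with `spec` (labels,
#'   features, positive class), `confusion` (tp/fn/tn/fp), `metrics`
#'   (tibble), `predictions` (per-sample out-of-fold tibble), `n_a`, `n_b`,
#'   `seed`.
#' @export
run_comparison <- function(data, group_a, group_b, features,
                           positive = NULL, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  if (group_a == group_b) {
    abort("`group_a` and `group_b` must differ.", class = "swayrisk_parameter_error")
  }
  miss <- setdiff(features, names(data))
  if (length(miss)) {
    abort(paste0("Feature column(s) not in data: ", paste(miss, collapse = ", ")),
          class = "swayrisk_configuration_error")
  }
  if (is.null(positive)) {
    ord <- risk_group_levels()
    positive <- if (match(group_a, ord, nomatch = 0) >
                    match(group_b, ord, nomatch = 0)) group_a else group_b
  }
  if (!positive %in% c(group_a, group_b)) {
    abort("`positive` must be one of the compared groups.",
          class = "swayrisk_parameter_error")
  }
  negative <- setdiff(c(group_a, group_b), positive)
  sub <- data[data$risk_group %in% c(group_a, group_b), , drop = FALSE]
  y <- factor(as.character(sub$risk_group), levels = c(negative, positive))
  x <- as.data.frame(sub[, features, drop = FALSE])

  set.seed(config$seed)
  fold <- stratified_folds(y, config$cv_folds)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (k in seq_len(config$cv_folds)) {
    tr <- fold != k
    imp <- impute_median(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    fit <- randomForest::randomForest(x = imp$train, y = y[tr],
                                      ntree = config$n_trees)
    pred[!tr] <- predict(fit, imp$test)
  }
  tp <- sum(pred == positive & y == positive)
  fn <- sum(pred == negative & y == positive)
  tn <- sum(pred == negative & y == negative)
  fp <- sum(pred == positive & y == negative)
  structure(
    list(
      spec = list(group_a = group_a, group_b = group_b,
                  positive = positive, features = features),
      confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
      metrics = diagnostic_metrics(tp, fn, tn, fp),
      predictions = tibble(participant_id = sub$participant_id %||% NA_character_,
                           truth = y, prediction = pred, fold = fold),
      n_a = sum(y == group_a), n_b = sum(y == group_b),
      seed = config$seed
    ),
    class = "sway_comparison"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sway_comparison <- function(x, ...) {
  m <- x$metrics
  cat("<sway_comparison> ", x$spec$group_a, " vs ", x$spec$group_b,
      " (positive: ", x$spec$positive, ")\n", sep = "")
  cat(sprintf("  ACC %.1f%%  SEN %.1f%%  SPC %.1f%%  (n = %d + %d)\n",
              100 * m$accuracy, 100 * m$sensitivity, 100 * m$specificity,
              x$n_a, x$n_b))
  invisible(x)
}

#' @rdname run_comparison
#' @param x a `sway_comparison`.
#' @param ... unused.
#' @export
tidy.sway_comparison <- function(x, ...) {
  tibble(
    comparison = paste0(x$spec$group_a, "_vs_", x$spec$group_b),
    metric = c("accuracy", "sensitivity", "specificity"),
    estimate = c(x$metrics$accuracy, x$metrics$sensitivity,
                 x$metrics$specificity)
  )
}

#' @rdname run_comparison
#' @export
glance.sway_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tibble(comparison = paste0(x$spec$group_a, "_vs_", x$spec$group_b),
           positive = x$spec$positive),
    x$metrics,
    tibble(tp = x$confusion[["tp"]], fn = x$confusion[["fn"]],
           tn = x$confusion[["tn"]], fp = x$confusion[["fp"]],
           n_a = x$n_a, n_b = x$n_b, seed = x$seed)
  )
}

#' Mean Decrease Impurity feature importance for one comparison
#'
#' Fits one random forest on the full two-group dataset (CV is only used
#' for the diagnostic metrics; importance is reported per classifier, not
#' per fold) and extracts impurity-based importance (Gini decrease summed
#' over all splits on a feature, weighted by the samples each split
#' partitions), normalised to sum to 1. Constant features get importance 0
#' and stay in the report.
#'
#' @inheritParams run_comparison
#' @param top_k how many features to flag as top predictors (default 5).
#' @return object of class `sway_importance`: tibble with `feature`, `mdi`
#'   (raw impurity decrease), `share` (normalised, sums to 1), `rank`,
#'   `top` (logical, rank <= top_k); attributes record the comparison.
#' @export
feature_importance <- function(data, group_a, group_b, features,
                               config = forest_config(), top_k = 5) {
  sub <- data[data$risk_group %in% c(group_a, group_b), , drop = FALSE]
  y <- factor(as.character(sub$risk_group), levels = c(group_a, group_b))
  x <- as.data.frame(sub[, features, drop = FALSE])
  imp_all <- impute_median(x, x)$train
  set.seed(config$seed)
  fit <- randomForest::randomForest(x = imp_all, y = y, ntree = config$n_trees,
                                    importance = FALSE)
  mdi <- randomForest::importance(fit, type = 2)[, 1]
  total <- sum(mdi)
  share <- if (total > 0) mdi / total else rep(0, length(mdi))
  out <- tibble(feature = names(mdi), mdi = unname(mdi),
                share = unname(share))
  out <- dplyr::arrange(out, dplyr::desc(.data$share))
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top_k
  attr(out, "comparison") <- paste0(group_a, "_vs_", group_b)
  class(out) <- c("sway_importance", class(out))
  out
}

#' @export
print.sway_importance <- function(x, ...) {
  cat("<sway_importance> ", attr(x, "comparison"), "\n", sep = "")
  NextMethod()
}

#' Run every pairwise group comparison for one or both feature sets
#'
#' Evaluates all pairwise comparisons among the risk groups present in the
#' data (six for the standard four-group cohort), separately on the sway
#' metric panel and on the clinical balance measures (BBS and balance
#' confidence), producing the full diagnostic report: pooled-CV accuracy,
#' sensitivity and specificity per comparison plus a Mean Decrease Impurity
#' importance report per classifier.
#'
#' @param data data frame with `risk_group`, the 19 sway metric columns
#'   and/or `bbs` + `balance_confidence` (join the feature table and the
#'   prepared participant table by `participant_id` first).
#' @param feature_sets which panels to run: subset of `c("sway", "clinical")`.
#' @param config a [forest_config()]; each comparison derives its own fold
#'   seed from it deterministically.
#' @param groups group labels to compare (default: the standard four, in
#'   risk order, restricted to those present).
#' @return object of class `sway_report`: list with `results` (tibble, one
#'   row per comparison x feature set with metrics in percent) and
#'   `importance` (named list of `sway_importance` tibbles).
#' @export
run_all_comparisons <- function(data, feature_sets = c("sway", "clinical"),
                                config = forest_config(), groups = NULL) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  panels <- list(sway = sway_metric_names(),
                 clinical = c("bbs", "balance_confidence"))
  if (is.null(groups)) {
    groups <- intersect(risk_group_levels(), unique(as.character(data$risk_group)))
  }
  if (length(groups) < 2) {
    abort("Need at least 2 groups to compare.", class = "swayrisk_input_error")
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  importance <- list()
  i <- 0L
  for (fs_name in feature_sets) {
    feats <- panels[[fs_name]]
    miss <- setdiff(feats, names(data))
    if (length(miss)) {
      abort(paste0("Feature set '", fs_name, "' needs missing column(s): ",
                   paste(miss, collapse = ", ")),
            class = "swayrisk_configuration_error")
    }
    for (pr in pairs) {
      i <- i + 1L
      cfg_i <- forest_config(config$n_trees, config$cv_folds,
                             (config$seed + 17L * i) %% .Machine$integer.max)
      cmp <- run_comparison(data, pr[1], pr[2], feats, config = cfg_i)
      imp <- feature_importance(data, pr[1], pr[2], feats, config = cfg_i)
      key <- paste0(fs_name, ":", pr[1], "_vs_", pr[2])
      importance[[key]] <- imp
      rows[[key]] <- dplyr::bind_cols(
        tibble(feature_set = fs_name),
        glance(cmp)
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  results$accuracy_pct <- round(100 * results$accuracy, 1)
  results$sensitivity_pct <- round(100 * results$sensitivity, 1)
  results$specificity_pct <- round(100 * results$specificity, 1)
  structure(list(results = results, importance = importance,
                 config = config, groups = groups),
            class = "sway_report")
}

#' @export
print.sway_report <- function(x, ...) {
  cat("<sway_report> ", nrow(x$results), " comparisons (",
      paste(unique(x$results$feature_set), collapse = ", "), ")\n", sep = "")
  print(x$results[, c("feature_set", "comparison", "accuracy_pct",
                      "sensitivity_pct", "specificity_pct")])
  invisible(x)
}

#' @rdname run_all_comparisons
#' @param x a `sway_report`.
#' @param ... unused.
#' @export
tidy.sway_report <- function(x, ...) {
  as_tibble(x$results)
}

#' Reshape a report into the triangular accuracy matrix layout
#'
#' One row per reference group, one column block per comparison group,
#' values in percent — the layout diagnostic tables in this field are
#' printed in.
#'
#' @param report a `sway_report`.
#' @param feature_set which panel to tabulate.
#' @param metric one of `"accuracy"`, `"sensitivity"`, `"specificity"`.
#' @return tibble, groups x groups, upper triangle filled (percent).
#' @export
report_matrix <- function(report, feature_set = "sway", metric = "accuracy") {
  res <- report$results[report$results$feature_set == feature_set, ]
  col <- paste0(metric, "_pct")
  groups <- report$groups
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(nrow(res))) {
    parts <- strsplit(res$comparison[i], "_vs_")[[1]]
    m[parts[1], parts[2]] <- res[[col]][i]
  }
  as_tibble(m, rownames = "group")
}
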