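test_that("diagnostic metrics reproduce hand-computed values exactly", {
  m <- diagnostic_metrics(tp = 8, fn = 2, tn = 9, fp = 1)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.85)
  perfect <- diagnostic_metrics(tp = 10, fn = 0, tn = 12, fp = 0)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1, specificity = 1))
  undef <- diagnostic_metrics(tp = 0, fn = 0, tn = 5, fp = 2)
  expect_true(is.na(undef$sensitivity))
  expect_error(diagnostic_metrics(tp = -1, fn = 0, tn = 0, fp = 1),
               class = "swayrisk_input_error")
})

test_that("well-separated classes are classified almost perfectly", {
  d <- make_planted_features(n_per_class = 30, delta = 10, seed = 41)
  res <- run_comparison(d, "HC", "MS_High", setdiff(names(d), c("participant_id", "risk_group")),
                        config = forest_config(n_trees = 100, seed = 1))
  expect_gte(res$metrics$accuracy, 0.98)
  expect_equal(res$spec$positive, "MS_High")
  expect_equal(sum(res$confusion), 60)
  expect_equal(res$confusion[["tp"]] + res$confusion[["fn"]], 30)
})

test_that("permuted labels give chance-level pooled accuracy", {
  accs <- vapply(1:20, function(s) {
    d <- make_planted_features(n_per_class = 25, delta = 0, seed = 100 + s)
    res <- run_comparison(d, "HC", "MS_High",
                          setdiff(names(d), c("participant_id", "risk_group")),
                          config = forest_config(n_trees = 100, cv_folds = 5,
                                                 seed = s))
    res$metrics$accuracy
  }, numeric(1))
  # mean over 20 null cohorts of n=50: binomial 95% band around 0.5
  se <- sqrt(0.25 / (50 * 20))
  expect_lt(abs(mean(accs) - 0.5), 1.96 * se + 0.05)
  expect_true(all(accs > 0.2 & accs < 0.8))
})

test_that("results are reproducible and order-invariant given a seed", {
  d <- make_planted_features(n_per_class = 20, delta = 1.5, seed = 7)
  feats <- setdiff(names(d), c("participant_id", "risk_group"))
  cfg <- forest_config(n_trees = 100, cv_folds = 5, seed = 3)
  r1 <- run_comparison(d, "HC", "MS_High", feats, config = cfg)
  r2 <- run_comparison(d, "HC", "MS_High", feats, config = cfg)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(glance(r1), glance(r2))
})

test_that("duplicating the informative feature does not change accuracy much", {
  d <- make_planted_features(n_per_class = 25, delta = 2, seed = 9)
  feats <- setdiff(names(d), c("participant_id", "risk_group"))
  cfg <- forest_config(n_trees = 200, cv_folds = 5, seed = 5)
  base <- run_comparison(d, "HC", "MS_High", feats, config = cfg)
  d2 <- d
  d2$signal_copy <- d2$signal
  dup <- run_comparison(d2, "HC", "MS_High", c(feats, "signal_copy"),
                        config = cfg)
  expect_lt(abs(dup$metrics$accuracy - base$metrics$accuracy), 0.1)
})

test_that("missing features are imputed fold-wise without aborting", {
  d <- make_planted_features(n_per_class = 20, delta = 3, seed = 11)
  d$signal[c(1, 25)] <- NA
  d$noise1[3] <- NA
  res <- run_comparison(d, "HC", "MS_High",
                        setdiff(names(d), c("participant_id", "risk_group")),
                        config = forest_config(n_trees = 100, cv_folds = 5,
                                               seed = 2))
  expect_gte(res$metrics$accuracy, 0.9)
})

test_that("stratification error names the small class", {
  d <- make_planted_features(n_per_class = 5, seed = 13)
  expect_error(
    run_comparison(d, "HC", "MS_High", "signal",
                   config = forest_config(n_trees = 10, cv_folds = 10)),
    class = "swayrisk_stratification_error")
})

test_that("MDI importance finds a planted signal and is normalised", {
  hits <- vapply(1:10, function(s) {
    d <- make_planted_features(n_per_class = 30, delta = 3, seed = 200 + s)
    imp <- feature_importance(d, "HC", "MS_High",
                              setdiff(names(d), c("participant_id", "risk_group")),
                              config = forest_config(n_trees = 200, seed = s))
    expect_equal(sum(imp$share), 1, tolerance = 1e-9)
    expect_true(all(imp$share >= 0))
    imp$share[imp$feature == "signal"]
  }, numeric(1))
  expect_true(all(hits > 0.5))
})

test_that("null features give a flat importance profile", {
  maxima <- vapply(1:5, function(s) {
    d <- make_planted_features(n_per_class = 30, delta = 0, seed = 300 + s)
    imp <- feature_importance(d, "HC", "MS_High",
                              setdiff(names(d), c("participant_id", "risk_group")),
                              config = forest_config(n_trees = 200, seed = s))
    max(imp$share) / mean(imp$share)
  }, numeric(1))
  expect_lt(mean(maxima), 2)
})

test_that("duplicated informative features share their importance", {
  d <- make_planted_features(n_per_class = 30, delta = 3, seed = 17)
  feats <- setdiff(names(d), c("participant_id", "risk_group"))
  cfg <- forest_config(n_trees = 500, seed = 4)
  single <- feature_importance(d, "HC", "MS_High", feats, config = cfg)
  d2 <- d
  d2$signal_copy <- d2$signal
  dup <- feature_importance(d2, "HC", "MS_High", c(feats, "signal_copy"),
                            config = cfg)
  combined <- sum(dup$share[dup$feature %in% c("signal", "signal_copy")])
  # the copies split importance between them; their combined share stays of
  # the same order as the single feature's (mtry resampling gives a
  # duplicated signal somewhat more exposure, so exact equality is not
  # expected)
  ratio <- combined / single$share[single$feature == "signal"]
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.6)
})

test_that("constant features get zero importance but stay in the report", {
  d <- make_planted_features(n_per_class = 15, delta = 2, seed = 19)
  d$flat <- 1
  imp <- feature_importance(d, "HC", "MS_High",
                            setdiff(names(d), c("participant_id", "risk_group")),
                            config = forest_config(n_trees = 100, seed = 1))
  expect_true("flat" %in% imp$feature)
  expect_equal(imp$share[imp$feature == "flat"], 0, tolerance = 1e-9)
})

test_that("run_all_comparisons covers every pair and both feature sets", {
  set.seed(50)
  groups <- rep(c("HC", "MS_Low", "MS_Mod", "MS_High"), each = 12)
  shift <- (match(groups, c("HC", "MS_Low", "MS_Mod", "MS_High")) - 1)
  d <- tibble::tibble(
    participant_id = sprintf("q%02d", seq_along(groups)),
    risk_group = factor(groups, levels = c("HC", "MS_Low", "MS_Mod", "MS_High")),
    bbs = 55 - 4 * shift + rnorm(length(groups), 0, 2),
    balance_confidence = 90 - 10 * shift + rnorm(length(groups), 0, 5)
  )
  for (f in sway_metric_names()) d[[f]] <- rnorm(length(groups)) + shift
  rep1 <- run_all_comparisons(d, config = forest_config(n_trees = 50,
                                                        cv_folds = 4, seed = 8))
  expect_equal(nrow(rep1$results), 12)  # 6 pairs x 2 feature sets
  expect_length(rep1$importance, 12)
  expect_true(all(rep1$results$tp + rep1$results$fn +
                    rep1$results$tn + rep1$results$fp == 24))
  rep2 <- run_all_comparisons(d, config = forest_config(n_trees = 50,
                                                        cv_folds = 4, seed = 8))
  expect_identical(rep1$results, rep2$results)
  expect_error(run_all_comparisons(d[, 1:3]),
               class = "swayrisk_configuration_error")
  # matrix layout carries percentages
  m <- report_matrix(rep1, "sway", "accuracy")
  expect_equal(dim(m), c(4, 5))
  expect_equal(m$MS_Low[m$group == "HC"],
               rep1$results$accuracy_pct[rep1$results$feature_set == "sway" &
                 rep1$results$comparison == "HC_vs_MS_Low"])
})

test_that("tidiers return well-formed tibbles", {
  d <- make_planted_features(n_per_class = 15, delta = 2, seed = 23)
  res <- run_comparison(d, "HC", "MS_High",
                        setdiff(names(d), c("participant_id", "risk_group")),
                        config = forest_config(n_trees = 50, cv_folds = 5, seed = 1))
  td <- tidy(res)
  expect_equal(td$metric, c("accuracy", "sensitivity", "specificity"))
  g <- glance(res)
  expect_equal(g$tp + g$fn + g$tn + g$fp, 30)
  expect_equal(g$accuracy, (g$tp + g$tn) / 30)
})
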