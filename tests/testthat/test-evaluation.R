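test_that("ECE matches closed-form and simulation oracles", {
  set.seed(101)
  n <- 5000
  sd <- runif(n, 0.2, 1)
  mean <- rnorm(n)
  preds <- predictive_distribution(mean, sd)

  # perfectly calibrated by construction
  truth <- rnorm(n, mean, sd)
  expect_lt(expected_calibration_error(preds, truth), 0.03)

  # zero residuals with positive sd: coverage 1 at every level -> mean(1 - p)
  levels <- seq(0.05, 0.95, by = 0.05)
  expect_equal(expected_calibration_error(preds, mean), mean(1 - levels))
  expect_equal(mean(1 - levels), 0.5)

  # sd understated 5x: strong miscalibration
  under <- predictive_distribution(mean, sd / 5)
  expect_gt(expected_calibration_error(under, truth), 0.2)
  # analytic coverage mismatch oracle for the same setting
  z <- qnorm((1 + levels) / 2)
  expect_gt(mean(abs((2 * pnorm(z / 5) - 1) - levels)), 0.2)

  expect_warning(expected_calibration_error(preds[1:5, ], truth[1:5]), "noisy")
  expect_error(expected_calibration_error(preds, truth[-1]), "length")
})

test_that("ENCE matches its closed-form cases and a calibrated simulation", {
  set.seed(202)
  n <- 200
  sd <- runif(n, 0.2, 1)
  mean <- rnorm(n)
  preds <- predictive_distribution(mean, sd)

  # residuals exactly +/- pred_std: RMSE_b = RMV_b in every bin
  truth_pm <- mean + sd * rep_len(c(1, -1), n)
  expect_equal(expected_normalized_calibration_error(preds, truth_pm), 0)

  # residuals exactly 2x pred_std: |2s - s| / s = 1 in every bin
  expect_equal(
    expected_normalized_calibration_error(preds, mean + 2 * sd), 1)

  # calibrated simulation, 10 bins
  set.seed(203)
  n <- 5000
  sd <- runif(n, 0.2, 1); mean <- rnorm(n)
  big <- predictive_distribution(mean, sd)
  expect_lt(expected_normalized_calibration_error(big, rnorm(n, mean, sd), 10),
            0.1)

  expect_error(expected_normalized_calibration_error(preds[1:5, ], mean[1:5], 10),
               "n_bins")
})

test_that("metrics are invariant to prediction order", {
  set.seed(17)
  n <- 100
  preds <- predictive_distribution(rnorm(n), runif(n, 0.1, 1))
  truth <- rnorm(n, preds$pred_mean, preds$pred_std)
  perm <- sample(n)
  shuffled <- predictive_distribution(preds$pred_mean[perm], preds$pred_std[perm])
  expect_equal(expected_calibration_error(preds, truth),
               expected_calibration_error(shuffled, truth[perm]))
  expect_equal(expected_normalized_calibration_error(preds, truth, 10),
               expected_normalized_calibration_error(shuffled, truth[perm], 10))
})

test_that("distance calibration correlates uncertainty with chemical distance", {
  vocab <- synthetic_vocabulary()
  train <- vocab[seq(1, 120, by = 2)]
  queries <- vocab[seq(2, 400, by = 2)]
  d <- tanimoto_knn_distance(queries, train, k = 5)

  # pred_std a strictly increasing function of distance -> rho = 1
  preds <- predictive_distribution(rep(1, length(d)), 0.1 + d^3)
  dc <- distance_calibration(preds, queries, train)
  expect_equal(dc$spearman, 1)
  expect_false(dc$degenerate)

  # pred_std independent of distance -> near-zero correlation
  set.seed(1)
  indep <- predictive_distribution(rep(1, length(d)),
                                   runif(length(d), 0.3, 0.9))
  dc0 <- distance_calibration(indep, queries, train)
  expect_lt(abs(dc0$spearman), 0.15)

  # constant sd: flagged degenerate, never silently zero
  flat <- predictive_distribution(rep(1, length(d)), rep(0.5, length(d)))
  dcf <- distance_calibration(flat, queries, train)
  expect_true(dcf$degenerate)
  expect_true(is.na(dcf$pearson) && is.na(dcf$spearman))
})

test_that("regression metrics behave at the extremes", {
  truth <- c(1, 2, 3, 4)
  expect_equal(regression_metrics(truth, truth), list(r2 = 1, rmse = 0))
  expect_lte(regression_metrics(truth, rep(mean(truth), 4))$r2, 0)
})

test_that("fold assignment is deterministic and order-independent", {
  ids <- sprintf("c%03d", 1:57)
  f1 <- assign_folds(ids, 5, seed = 9)
  f2 <- assign_folds(ids, 5, seed = 9)
  expect_identical(f1, f2)
  expect_true(all(table(f1) %in% c(11, 12)))
  perm <- sample(57)
  f3 <- assign_folds(ids[perm], 5, seed = 9)
  expect_identical(f3, f1[perm])
  expect_false(identical(assign_folds(ids, 5, seed = 10), f1))
})

test_that("nested CV selects, refits and never leaks test information", {
  sim <- shared_sim()
  cur <- shared_curated()
  cv <- cv_config(outer_folds = 3, inner_folds = 2, seed = 5)
  cands <- list(cv_candidate(feature_set_spec("descriptors_2d"), "matern25"),
                cv_candidate(feature_set_spec("maccs"), "rbf"))
  rep1 <- nested_cv(sim$records, cur$mu_mean, cur$mu_std, cv = cv,
                    candidates = cands, gp_restarts = 2)

  ids <- vapply(sim$records, `[[`, character(1), "compound_id")
  expect_setequal(rep1$predictions$compound_id, ids)  # each compound once
  expect_equal(anyDuplicated(rep1$predictions$compound_id), 0L)
  expect_true(all(rep1$winners %in% vapply(cands, `[[`, character(1), "label")))
  expect_equal(nrow(rep1$per_fold), 3)
  expect_true(is.finite(rep1$pooled$rmse) && rep1$pooled$rmse >= 0)

  # leakage guard: permuting targets *within* outer fold 1 must leave the
  # predictions for fold-1 compounds bit-identical (its model never saw them)
  folds <- rep1$folds[ids]
  mu2 <- cur$mu_mean
  in1 <- which(folds == 1)
  mu2[in1] <- mu2[rev(in1)]
  rep2 <- nested_cv(sim$records, mu2, cur$mu_std, cv = cv,
                    candidates = cands, gp_restarts = 2)
  p1 <- rep1$predictions[rep1$predictions$fold == 1, ]
  p2 <- rep2$predictions[rep2$predictions$fold == 1, ]
  expect_identical(p1[order(p1$compound_id), c("pred_mean", "pred_std")],
                   p2[order(p2$compound_id), c("pred_mean", "pred_std")])
})

test_that("nested CV GPR agrees with an independent ridge oracle", {
  sim <- generate_compounds(synthetic_spec(n_compounds = 200,
                                           replicate_range = c(5, 15),
                                           noise_sd = 0.3, seed = 777))
  cur <- curate_records(sim$records)
  cv <- cv_config(outer_folds = 3, inner_folds = 2, seed = 2)
  rep <- nested_cv(sim$records, cur$mu_mean, cur$mu_std, cv = cv,
                   candidates = list(
                     cv_candidate(feature_set_spec("descriptors_2d"), "matern25")),
                   gp_restarts = 2)

  # ridge on the same folds and (scaled, selected) descriptor features
  ids <- vapply(sim$records, `[[`, character(1), "compound_id")
  folds <- rep$folds[ids]
  sse <- 0; sst <- 0
  for (f in 1:3) {
    tr <- which(folds != f); te <- which(folds == f)
    fm <- fit_scale(featurize(sim$records[tr], feature_set_spec("descriptors_2d")))
    sel <- select_features(fm)
    fq <- apply_scale(featurize(sim$records[te], feature_set_spec("descriptors_2d")),
                      fm$scaler_state)
    pred <- oracle_ridge(sel$values,
                         cur$mu_mean[tr],
                         fq$values[, colnames(sel$values), drop = FALSE],
                         lambda = 1)
    sse <- sse + sum((cur$mu_mean[te] - pred)^2)
    sst <- sst + sum((cur$mu_mean[te] - mean(cur$mu_mean[tr]))^2)
  }
  ridge_r2 <- 1 - sse / sst
  expect_lt(abs(rep$pooled$r2 - ridge_r2), 0.1)
})
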