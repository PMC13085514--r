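# Model evaluation: nested cross-validation, accuracy metrics, and the three
# uncertainty-calibration diagnostics (ECE, ENCE, distance-based calibration).

#' Cross-validation configuration
#'
#' Folds partition *compounds* (each compound, with all its observations, is
#' in exactly one outer fold). Fold assignment is a deterministic function of
#' the compound ids and the seed, independent of input order.
#'
#' @param outer_folds,inner_folds Number of folds (>= 2; defaults 5 and 5).
#' @param seed Integer seed.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 5, inner_folds = 5, seed = 1) {
  stopifnot(outer_folds >= 2, inner_folds >= 2)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Deterministic fold assignment
#'
#' @param ids Character vector of compound ids (unique).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`, aligned with `ids`;
#'   identical for any permutation of the same id set.
#' @export
assign_folds <- function(ids, k, seed) {
  stopifnot(!anyDuplicated(ids), k >= 2, length(ids) >= k)
  ord <- order(ids)
  folds_sorted <- local({
    set.seed(seed)
    sample(rep_len(seq_len(k), length(ids)))
  })
  folds <- integer(length(ids))
  folds[ord] <- folds_sorted
  folds
}

#' Regression accuracy metrics
#'
#' @param truth,pred Aligned numeric vectors.
#' @return List with `r2` (coefficient of determination; `<= 1`, negative for
#'   predictors worse than the mean) and `rmse`.
#' @export
regression_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((truth - pred)^2)))
}

.check_preds <- function(preds, truth) {
  stopifnot(is.data.frame(preds), all(c("pred_mean", "pred_std") %in% names(preds)))
  if (nrow(preds) != length(truth)) {
    stop("predictions and truth have different lengths", call. = FALSE)
  }
}

#' Expected Calibration Error (ECE)
#'
#' Checks how closely the empirical coverage of central prediction intervals
#' matches the nominal coverage: over nominal levels `p` (default 0.05, 0.10,
#' ..., 0.95), the empirical coverage is the fraction of truths inside
#' `pred_mean +/- z_{(1+p)/2} * pred_std`, and ECE is the mean absolute gap to
#' `p`. 0 is perfectly calibrated; a forecaster whose residuals are all zero
#' but reports nonzero uncertainty scores 0.5 on this grid.
#'
#' @param preds A [predictive_distribution()] (columns `pred_mean`, `pred_std`).
#' @param truth Observed values.
#' @param levels Nominal central-coverage levels.
#' @return ECE in `[0, 1]`.
#' @export
expected_calibration_error <- function(preds, truth,
                                       levels = seq(0.05, 0.95, by = 0.05)) {
  .check_preds(preds, truth)
  if (length(truth) < 20) warning("ECE on fewer than 20 points is noisy")
  z <- stats::qnorm((1 + levels) / 2)
  absres <- abs(truth - preds$pred_mean)
  cover <- vapply(z, function(zz) mean(absres <= zz * preds$pred_std), numeric(1))
  mean(abs(cover - levels))
}

#' Expected Normalized Calibration Error (ENCE)
#'
#' Evaluates whether residual magnitude scales with the predicted
#' uncertainty: predictions are sorted by `pred_std` into `n_bins` equal-count
#' bins; per bin the root-mean-variance `RMV = sqrt(mean(pred_std^2))` is
#' compared with the empirical `RMSE`, and ENCE is the mean of
#' `|RMV - RMSE| / RMV`. 0 means uncertainties match errors bin by bin;
#' residuals uniformly twice the stated uncertainty give 1.
#'
#' @inheritParams expected_calibration_error
#' @param n_bins Number of equal-count bins (default 10).
#' @return ENCE (>= 0).
#' @export
expected_normalized_calibration_error <- function(preds, truth, n_bins = 10) {
  .check_preds(preds, truth)
  n <- length(truth)
  if (n < n_bins) stop("need at least n_bins points", call. = FALSE)
  ord <- order(preds$pred_std)
  bin <- ceiling(seq_len(n) * n_bins / n)
  res <- (truth - preds$pred_mean)[ord]
  sd2 <- (preds$pred_std^2)[ord]
  per_bin <- vapply(seq_len(n_bins), function(b) {
    rmv <- sqrt(mean(sd2[bin == b]))
    if (rmv == 0) stop("degenerate bin with zero root-mean-variance", call. = FALSE)
    rmse <- sqrt(mean(res[bin == b]^2))
    abs(rmv - rmse) / rmv
  }, numeric(1))
  mean(per_bin)
}

#' Distance-based calibration
#'
#' Correlates each query's mean Tanimoto distance to its `k` nearest training
#' compounds ([tanimoto_knn_distance()]) with the predicted uncertainty.
#' Positive correlation means the model is (correctly) less confident far from
#' its training domain.
#'
#' @inheritParams expected_calibration_error
#' @param query_smiles,train_smiles SMILES of query and training compounds.
#' @param k Neighbours for the distance (default 5).
#' @return List with `pearson`, `spearman` and `degenerate` (`TRUE`, with
#'   `NA` correlations, when distances or uncertainties are constant --
#'   flagged, never silently zero).
#' @export
distance_calibration <- function(preds, query_smiles, train_smiles, k = 5) {
  stopifnot(is.data.frame(preds), nrow(preds) >= 3,
            length(query_smiles) == nrow(preds))
  d <- tanimoto_knn_distance(query_smiles, train_smiles, k = k)
  if (stats::sd(d) == 0 || stats::sd(preds$pred_std) == 0) {
    return(list(pearson = NA_real_, spearman = NA_real_, degenerate = TRUE))
  }
  list(pearson = stats::cor(d, preds$pred_std, method = "pearson"),
       spearman = stats::cor(d, preds$pred_std, method = "spearman"),
       degenerate = FALSE)
}

#' Model/feature candidate for cross-validation
#'
#' @param features A [feature_set_spec()].
#' @param kernel GP kernel name (ignored for the RF model).
#' @param label Optional display label.
#' @return A list usable in `nested_cv()`'s candidate list.
#' @export
cv_candidate <- function(features, kernel = "matern25", label = NULL) {
  if (is.null(label)) {
    label <- paste0(paste(features$names, collapse = "+"), "/", kernel)
  }
  list(features = features, kernel = kernel, label = label)
}

# Fit the full pipeline (featurize -> scale -> select -> model) on training
# records only; returns a self-contained predictor state.
.fit_pipeline <- function(train_records, y, alpha, candidate, model, seed,
                          gp_restarts = 5) {
  fm <- fit_scale(featurize(train_records, candidate$features))
  sel <- select_features(fm)
  ts <- training_set(sel, y, alpha)
  fitted <- if (model == "gpr") {
    fit_gpr(ts, kernel = candidate$kernel, seed = seed, restarts = gp_restarts)
  } else {
    fit_rf(ts, seed = seed)
  }
  list(candidate = candidate, model_type = model,
       scaler_state = fm$scaler_state,
       selected = colnames(sel$values),
       selection_report = attr(sel, "selection"),
       fit = fitted)
}

.predict_pipeline <- function(state, query_records) {
  fm <- featurize(query_records, state$candidate$features)
  fm <- apply_scale(fm, state$scaler_state)
  X <- fm$values[, state$selected, drop = FALSE]
  if (state$model_type == "gpr") predict_gpr(state$fit, X) else predict_rf(state$fit, X)
}

#' Nested cross-validation
#'
#' Outer folds estimate generalization; within each outer-training partition,
#' inner cross-validation selects the best candidate (feature set x kernel) by
#' mean inner RMSE, the winner is refit on the full outer-training set, and
#' all metrics are computed on the pooled outer-test predictions. Scaling and
#' feature selection are re-fit inside every training partition, so no test
#' information leaks into the pipeline. With a single candidate the inner loop
#' is skipped. Candidates that fail to fit on a fold are recorded as failures,
#' not propagated as errors.
#'
#' @param records List of `compound_record` (one per compound).
#' @param mu_mean Target vector (Bayesian mean log10 half-life), aligned.
#' @param mu_std Target uncertainty vector (log10 days), aligned; `NULL` for
#'   homoscedastic fitting. Enters the GP as `alpha = mu_std^2`.
#' @param cv A [cv_config()].
#' @param candidates List of [cv_candidate()]s.
#' @param model `"gpr"` or `"rf"`.
#' @param gp_restarts Restarts of the GP hyperparameter search per fit.
#' @param ence_bins Bins for the pooled ENCE.
#' @return An `evaluation_report`: list with `pooled` metrics (`r2`, `rmse`,
#'   `ece`, `ence`, `dist_pearson`, `dist_spearman`), `per_fold` breakdown,
#'   `predictions` (pooled outer-test predictions), `winners`, `failures`,
#'   `folds`, and a `config` echo.
#' @export
nested_cv <- function(records, mu_mean, mu_std = NULL, cv = cv_config(),
                      candidates = list(cv_candidate(feature_set_spec("maccs"))),
                      model = c("gpr", "rf"), gp_restarts = 5, ence_bins = 10) {
  model <- match.arg(model)
  stopifnot(length(records) == length(mu_mean))
  ids <- vapply(records, function(r) r$compound_id, character(1))
  alpha <- if (is.null(mu_std)) rep(0, length(mu_mean)) else mu_std^2
  folds <- assign_folds(ids, cv$outer_folds, cv$seed)

  failures <- list(); winners <- character(cv$outer_folds)
  per_fold <- list(); pooled_rows <- list()

  for (f in seq_len(cv$outer_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    # ----- inner model selection -----
    if (length(candidates) > 1) {
      inner_folds <- assign_folds(ids[tr], cv$inner_folds, cv$seed + f)
      inner_rmse <- vapply(seq_along(candidates), function(ci) {
        rmses <- vapply(seq_len(cv$inner_folds), function(g) {
          itr <- tr[inner_folds != g]; ite <- tr[inner_folds == g]
          st <- tryCatch(
            .fit_pipeline(records[itr], mu_mean[itr], alpha[itr],
                          candidates[[ci]], model, cv$seed, gp_restarts),
            error = function(e) e)
          if (inherits(st, "error")) return(NA_real_)
          pr <- .predict_pipeline(st, records[ite])
          regression_metrics(mu_mean[ite], pr$pred_mean)$rmse
        }, numeric(1))
        mean(rmses)
      }, numeric(1))
      if (all(is.na(inner_rmse))) {
        failures[[length(failures) + 1L]] <-
          list(fold = f, reason = "all candidates failed in inner CV")
        next
      }
      win <- which.min(inner_rmse)
    } else win <- 1L
    winners[f] <- candidates[[win]]$label
    # ----- refit winner on the outer-training set -----
    st <- tryCatch(
      .fit_pipeline(records[tr], mu_mean[tr], alpha[tr], candidates[[win]],
                    model, cv$seed, gp_restarts),
      error = function(e) e)
    if (inherits(st, "error")) {
      failures[[length(failures) + 1L]] <- list(fold = f, candidate = win,
                                                reason = conditionMessage(st))
      next
    }
    pr <- .predict_pipeline(st, records[te])
    pooled_rows[[f]] <- data.frame(compound_id = ids[te], fold = f,
                                   truth = mu_mean[te],
                                   pred_mean = pr$pred_mean,
                                   pred_std = pr$pred_std,
                                   train_n = length(tr),
                                   stringsAsFactors = FALSE)
    m <- regression_metrics(mu_mean[te], pr$pred_mean)
    per_fold[[f]] <- data.frame(
      fold = f, n = length(te), candidate = candidates[[win]]$label,
      r2 = m$r2, rmse = m$rmse,
      ece = suppressWarnings(expected_calibration_error(pr, mu_mean[te])),
      ence = if (length(te) >= ence_bins)
        expected_normalized_calibration_error(pr, mu_mean[te], ence_bins)
      else NA_real_,
      stringsAsFactors = FALSE)
  }

  predictions <- do.call(rbind, pooled_rows)
  if (is.null(predictions) || nrow(predictions) == 0) {
    stop("nested CV produced no successful folds", call. = FALSE)
  }
  preds <- predictive_distribution(predictions$pred_mean, predictions$pred_std)
  m <- regression_metrics(predictions$truth, predictions$pred_mean)
  # distance calibration: per fold against that fold's training compounds
  smiles <- vapply(records, function(r) r$smiles, character(1))
  dists <- unlist(lapply(seq_len(cv$outer_folds), function(f) {
    te <- which(folds == f)
    if (!f %in% predictions$fold) return(numeric(0))
    tanimoto_knn_distance(smiles[te], smiles[folds != f],
                          k = min(5, sum(folds != f)))
  }))
  dist_cal <- if (stats::sd(dists) == 0 || stats::sd(predictions$pred_std) == 0) {
    list(pearson = NA_real_, spearman = NA_real_, degenerate = TRUE)
  } else {
    list(pearson = stats::cor(dists, predictions$pred_std),
         spearman = stats::cor(dists, predictions$pred_std, method = "spearman"),
         degenerate = FALSE)
  }
  structure(list(
    pooled = list(r2 = m$r2, rmse = m$rmse,
                  ece = suppressWarnings(
                    expected_calibration_error(preds, predictions$truth)),
                  ence = expected_normalized_calibration_error(
                    preds, predictions$truth, min(ence_bins, nrow(predictions))),
                  dist_pearson = dist_cal$pearson,
                  dist_spearman = dist_cal$spearman),
    per_fold = do.call(rbind, per_fold),
    predictions = predictions,
    winners = winners,
    failures = failures,
    folds = stats::setNames(folds, ids),
    config = list(cv = unclass(cv), model = model,
                  candidates = vapply(candidates, `[[`, character(1), "label"))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report %s: pooled R2 = %.3f, RMSE = %.3f, ECE = %.3f, ENCE = %.3f>\n",
              x$config$model, x$pooled$r2, x$pooled$rmse, x$pooled$ece, x$pooled$ence))
  invisible(x)
}
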