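# Random-forest baseline: ensemble mean as the prediction, empirical spread
# across trees as the uncertainty proxy.

#' Fit the random-forest baseline
#'
#' A seeded regression forest (bootstrap resampling, per-node `mtry` feature
#' subsampling, variance-reduction splits, unlimited depth by default).
#' Unlike the GP, the forest does not consume the per-sample target noise;
#' it serves as a point-prediction baseline whose tree spread provides an
#' empirical (not necessarily Gaussian) uncertainty estimate.
#'
#' @param train A [training_set()].
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per node (default `ceiling(p / 3)`).
#' @param min_node Minimum samples per leaf (default 5).
#' @param max_depth Maximum depth; `0` (default) means unlimited.
#' @param bootstrap Resample training rows per tree (default `TRUE`).
#' @param seed Integer seed; same seed and data give bit-identical forests.
#' @return An object of class `rf_model`.
#' @export
fit_rf <- function(train, n_trees = 500, mtry = NULL, min_node = 5,
                   max_depth = 0, bootstrap = TRUE, seed = 1) {
  stopifnot(inherits(train, "training_set"), n_trees >= 1)
  p <- ncol(train$X)
  if (is.null(mtry)) mtry <- max(1L, ceiling(p / 3))
  forest <- rf_fit_cpp(train$X, train$y, as.integer(n_trees), as.integer(mtry),
                       as.integer(min_node), as.integer(max_depth),
                       isTRUE(bootstrap), as.double(seed))
  structure(list(forest = forest, n_trees = n_trees, mtry = mtry,
                 min_node = min_node, max_depth = max_depth, seed = seed,
                 p = p, schema_version = 1L),
            class = "rf_model")
}

#' Predict from the random-forest baseline
#'
#' @param model An `rf_model`.
#' @param X_query Query matrix (or `feature_matrix`), same pipeline state as
#'   training.
#' @param sd_floor Lower bound on the reported spread (default `1e-3`); keeps
#'   `pred_std > 0` even when all trees agree (e.g. a single-tree forest).
#' @return A [predictive_distribution()]: per-query ensemble mean and
#'   population SD across trees.
#' @export
predict_rf <- function(model, X_query, sd_floor = 1e-3) {
  stopifnot(inherits(model, "rf_model"))
  if (inherits(X_query, "feature_matrix")) X_query <- X_query$values
  if (is.null(dim(X_query))) X_query <- matrix(X_query, nrow = 1)
  if (ncol(X_query) != model$p) {
    stop("query has ", ncol(X_query), " features, model expects ", model$p,
         call. = FALSE)
  }
  per_tree <- rf_predict_cpp(model$forest, X_query)
  m <- rowMeans(per_tree)
  sd_pop <- sqrt(rowMeans((per_tree - m)^2))
  predictive_distribution(m, pmax(sd_pop, sd_floor))
}
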