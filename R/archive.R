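# Model persistence: one JSON archive holding the entire prediction pipeline
# state (scaler, selection, model hyperparameters, training data) plus a
# schema version; loading refuses mismatched schemas.

ARCHIVE_SCHEMA <- 1L

#' Save a fitted prediction pipeline
#'
#' @param state A pipeline state as produced by [train_pipeline()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_model <- function(state, path) {
  stopifnot(is.list(state), !is.null(state$model_type))
  payload <- list(
    schema_version = ARCHIVE_SCHEMA,
    package_version = as.character(utils::packageVersion("dt50prob")),
    model_type = state$model_type,
    features = list(names = state$candidate$features$names,
                    external_path = state$candidate$features$external_path),
    kernel = state$candidate$kernel,
    scaler_state = state$scaler_state,
    selected = state$selected,
    selection_report = state$selection_report)
  if (state$model_type == "gpr") {
    f <- state$fit
    payload$gp <- list(kernel = f$kernel, outputscale = f$outputscale,
                       lengthscale = f$lengthscale, noise_var = f$noise_var,
                       ybar = f$ybar, alpha = f$alpha,
                       X = f$X, train_y = f$y)
  } else {
    f <- state$fit
    payload$rf <- list(n_trees = f$n_trees, mtry = f$mtry,
                       min_node = f$min_node, max_depth = f$max_depth,
                       seed = f$seed, p = f$p, forest = f$forest)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor",
                       dataframe = "columns")
  invisible(path)
}

#' Load a fitted prediction pipeline
#'
#' @param path Archive written by [save_model()].
#' @return A pipeline state usable with [predict_pipeline()].
#' @export
load_model <- function(path) {
  # simplifyDataFrame would collapse the tree list into a data.frame of
  # columns; keep record lists as lists and coerce explicitly below
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(as.integer(payload$schema_version), ARCHIVE_SCHEMA)) {
    stop("model archive schema version ", payload$schema_version,
         " does not match supported version ", ARCHIVE_SCHEMA, call. = FALSE)
  }
  features <- feature_set_spec(payload$features$names,
                               external_path = payload$features$external_path)
  candidate <- cv_candidate(features, kernel = payload$kernel)
  scaler <- as.data.frame(payload$scaler_state, stringsAsFactors = FALSE)
  if (!is.null(payload$selection_report)) {
    payload$selection_report <- as.data.frame(payload$selection_report,
                                              stringsAsFactors = FALSE)
  }
  fit <- if (payload$model_type == "gpr") {
    g <- payload$gp
    X <- as.matrix(g$X)
    colnames(X) <- payload$selected
    .gp_rebuild(X, as.numeric(g$train_y), as.numeric(g$alpha), g$kernel,
                g$outputscale, g$lengthscale, g$noise_var, g$ybar)
  } else {
    r <- payload$rf
    forest <- lapply(r$forest, function(tr) {
      list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
           left = as.integer(tr$left), right = as.integer(tr$right),
           value = as.numeric(tr$value))
    })
    structure(list(forest = forest, n_trees = r$n_trees, mtry = r$mtry,
                   min_node = r$min_node, max_depth = r$max_depth,
                   seed = r$seed, p = r$p, schema_version = 1L),
              class = "rf_model")
  }
  list(candidate = candidate, model_type = payload$model_type,
       scaler_state = scaler, selected = payload$selected,
       selection_report = payload$selection_report, fit = fit)
}

.gp_rebuild <- function(X, y, alpha, kernel, outputscale, lengthscale,
                        noise_var, ybar) {
  n <- length(y)
  r <- sqrt(.sq_dist(X, X))
  C <- outputscale * .kernel_g(r / lengthscale, kernel) +
    diag(noise_var + alpha, n)
  ch <- .chol_with_jitter(C)
  yc <- y - ybar
  w <- backsolve(ch$L, forwardsolve(t(ch$L), yc))
  structure(list(kernel = kernel, outputscale = outputscale,
                 lengthscale = lengthscale, noise_var = noise_var,
                 jitter = ch$jitter, X = X, alpha = alpha, ybar = ybar,
                 L = ch$L, w = w, restarts = NA_integer_, seed = NA_integer_,
                 schema_version = 1L),
            class = "gp_model")
}

#' Train the full prediction pipeline
#'
#' Featurizes the training compounds, fits the min-max scaler and the
#' variance/correlation feature selection on them, and fits the requested
#' probabilistic model on the selected features with heteroscedastic target
#' noise `alpha = mu_std^2`.
#'
#' @param records List of `compound_record` (SMILES already standardized).
#' @param mu_mean Target vector, aligned with `records`.
#' @param mu_std Target uncertainty (log10 days) aligned; `NULL` for
#'   homoscedastic fitting.
#' @param features A [feature_set_spec()].
#' @param kernel GP kernel (`"matern25"`, `"matern15"`, `"rbf"`).
#' @param model `"gpr"` or `"rf"`.
#' @param seed Integer seed.
#' @param gp_restarts Hyperparameter-search restarts.
#' @return A pipeline state (list) for [predict_pipeline()] / [save_model()].
#' @export
train_pipeline <- function(records, mu_mean, mu_std = NULL,
                           features = feature_set_spec("maccs"),
                           kernel = "matern25", model = c("gpr", "rf"),
                           seed = 1, gp_restarts = 5) {
  model <- match.arg(model)
  alpha <- if (is.null(mu_std)) rep(0, length(mu_mean)) else mu_std^2
  .fit_pipeline(records, mu_mean, alpha, cv_candidate(features, kernel),
                model, seed, gp_restarts)
}

#' Predict with a trained pipeline
#'
#' @param state A pipeline state from [train_pipeline()] or [load_model()].
#' @param records List of `compound_record` or character vector of
#'   standardized SMILES.
#' @return A [predictive_distribution()].
#' @export
predict_pipeline <- function(state, records) {
  if (is.character(records)) {
    records <- lapply(records, function(s) compound_record(s, s))
  }
  .predict_pipeline(state, records)
}
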