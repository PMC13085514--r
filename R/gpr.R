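# Gaussian-process regression with heteroscedastic per-sample target noise.
#
# Covariance of the training targets:
#   C = s2 * g(r/ell) + noise_var * I + diag(alpha) + jitter * I
# where g is the base kernel (RBF or Matern 1.5/2.5), s2 the constant
# prefactor (output scale), ell an isotropic length-scale, noise_var a fitted
# white-noise term, and alpha the *fixed* per-compound target variances
# (mu_std^2 from the Bayesian curation step) that downweight uncertain
# training half-lives. Hyperparameters (s2, ell, noise_var) are fitted by
# maximizing the log marginal likelihood with analytic gradients and multiple
# seeded restarts. Targets are centered by the training mean (not rescaled),
# so predictions stay in log10-day units. Predictive variance includes the
# fitted white-noise floor but not alpha (which is a property of the training
# data, not of a new query).

KERNELS <- c("matern25", "matern15", "rbf")

#' Training set for the probabilistic regressors
#'
#' @param X A `feature_matrix` (scaled, selected) or a plain numeric matrix.
#' @param y Target vector: Bayesian mean log10 half-lives (`mu_mean`).
#' @param noise Per-sample target variance `alpha = mu_std^2` (>= 0);
#'   default 0 (homoscedastic).
#' @return An object of class `training_set`.
#' @export
training_set <- function(X, y, noise = NULL) {
  ids <- NULL
  if (inherits(X, "feature_matrix")) { ids <- X$compound_ids; X <- X$values }
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (is.null(noise)) noise <- rep(0, length(y))
  stopifnot(length(noise) == length(y), all(noise >= 0))
  structure(list(X = X, y = as.numeric(y), noise = as.numeric(noise), ids = ids),
            class = "training_set")
}

#' Predictive distribution container
#'
#' @param pred_mean Predicted mean log10 half-life.
#' @param pred_std Predictive standard deviation (> 0), log10 days.
#' @return A `data.frame` of class `predictive_distribution`.
#' @export
predictive_distribution <- function(pred_mean, pred_std) {
  stopifnot(length(pred_mean) == length(pred_std), all(pred_std > 0))
  structure(data.frame(pred_mean = pred_mean, pred_std = pred_std),
            class = c("predictive_distribution", "data.frame"))
}

.sq_dist <- function(A, B) {
  # squared Euclidean distances, rows of A x rows of B
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# base kernel g(u) and d g / d log(ell) = -u g'(u), on scaled distance u = r/ell
.kernel_g <- function(u, kernel) {
  switch(kernel,
    rbf = exp(-u^2 / 2),
    matern15 = { a <- sqrt(3); (1 + a * u) * exp(-a * u) },
    matern25 = { a <- sqrt(5); (1 + a * u + a^2 * u^2 / 3) * exp(-a * u) })
}

.kernel_dg_dlogell <- function(u, kernel) {
  switch(kernel,
    rbf = u^2 * exp(-u^2 / 2),
    matern15 = { a <- sqrt(3); a^2 * u^2 * exp(-a * u) },
    matern25 = { a <- sqrt(5); (a^2 * u^2 / 3) * (1 + a * u) * exp(-a * u) })
}

.chol_with_jitter <- function(C, jitter0 = 1e-8) {
  jitter <- jitter0
  for (i in 1:8) {
    L <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jitter))
    jitter <- jitter * 10
  }
  stop("kernel matrix is not positive definite even with jitter up to ",
       format(jitter / 10), "; check for duplicated rows with conflicting ",
       "targets and zero noise", call. = FALSE)
}

# negative log marginal likelihood and gradient wrt theta = log(s2, ell, nv)
.gp_nlml <- function(theta, r, yc, alpha, kernel, want_grad = FALSE) {
  s2 <- exp(theta[1]); ell <- exp(theta[2]); nv <- exp(theta[3])
  n <- length(yc)
  u <- r / ell
  G <- .kernel_g(u, kernel)
  C <- s2 * G + diag(nv + alpha, n)
  ch <- tryCatch(.chol_with_jitter(C), error = function(e) NULL)
  if (is.null(ch)) {
    return(list(value = 1e10, grad = rep(0, 3)))
  }
  L <- ch$L
  w <- backsolve(L, forwardsolve(t(L), yc))
  nlml <- 0.5 * sum(yc * w) + sum(log(diag(L))) + n / 2 * log(2 * pi)
  out <- list(value = nlml)
  if (want_grad) {
    Cinv <- chol2inv(L)
    M <- tcrossprod(w) - Cinv  # dL/dtheta = 0.5 tr(M dC/dtheta); nlml = -L
    dK_ds2 <- s2 * G
    dK_dell <- s2 * .kernel_dg_dlogell(u, kernel)
    out$grad <- -0.5 * c(sum(M * dK_ds2),
                         sum(M * dK_dell),
                         nv * sum(diag(M)))
  }
  out
}

#' Fit a Gaussian-process regressor
#'
#' @param train A [training_set()].
#' @param kernel One of `"matern25"` (default), `"matern15"`, `"rbf"`; each
#'   with a constant prefactor and an additive fitted white-noise term on top
#'   of the fixed per-sample noise `alpha`.
#' @param restarts Number of seeded random restarts of the marginal-likelihood
#'   optimization (default 5).
#' @param seed Integer seed for the restart draws.
#' @param optimize If `FALSE`, skip hyperparameter fitting and use `init`
#'   as-is (useful for closed-form checks).
#' @param init Optional named list `outputscale`, `lengthscale`, `noise_var`
#'   overriding the data-driven initialization.
#' @param center Center targets by the training mean (default `TRUE`).
#' @return An object of class `gp_model`.
#' @export
fit_gpr <- function(train, kernel = c("matern25", "matern15", "rbf"),
                    restarts = 5, seed = 1, optimize = TRUE, init = NULL,
                    center = TRUE) {
  stopifnot(inherits(train, "training_set"))
  kernel <- match.arg(kernel)
  X <- train$X; y <- train$y; alpha <- train$noise
  n <- length(y)
  ybar <- if (center) mean(y) else 0
  yc <- y - ybar
  r <- sqrt(.sq_dist(X, X))

  vary <- stats::var(yc)
  if (!is.finite(vary) || vary <= 0) vary <- 1
  d0 <- stats::median(r[upper.tri(r)])
  if (!is.finite(d0) || d0 <= 0) d0 <- 1
  init_def <- list(outputscale = vary, lengthscale = d0, noise_var = 0.05 * vary)
  if (!is.null(init)) init_def <- utils::modifyList(init_def, init)

  theta0 <- log(pmax(unname(unlist(
    init_def[c("outputscale", "lengthscale", "noise_var")])), 1e-12))
  if (!optimize) {
    theta <- theta0
  } else {
    lower <- c(log(vary) - 12, log(d0) - 7, log(vary) - 18)
    upper <- c(log(vary) + 8, log(d0) + 7, log(vary) + 4)
    starts <- list(theta0)
    if (restarts > 1) {
      rng <- local({ set.seed(seed); lapply(seq_len(restarts - 1), function(i)
        theta0 + stats::runif(3, -2, 2)) })
      starts <- c(starts, rng)
    }
    fits <- lapply(starts, function(t0) {
      stats::optim(pmin(pmax(t0, lower), upper),
                   fn = function(th) .gp_nlml(th, r, yc, alpha, kernel)$value,
                   gr = function(th) .gp_nlml(th, r, yc, alpha, kernel,
                                              want_grad = TRUE)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200))
    })
    best <- which.min(vapply(fits, function(f) f$value, numeric(1)))
    theta <- fits[[best]]$par
  }
  s2 <- exp(theta[1]); ell <- exp(theta[2]); nv <- exp(theta[3])
  if (!optimize && !is.null(init) && identical(init$noise_var, 0)) nv <- 0
  C <- s2 * .kernel_g(r / ell, kernel) + diag(nv + alpha, n)
  ch <- .chol_with_jitter(C)
  w <- backsolve(ch$L, forwardsolve(t(ch$L), yc))
  structure(list(kernel = kernel, outputscale = s2, lengthscale = ell,
                 noise_var = nv, jitter = ch$jitter, X = X, y = y,
                 alpha = alpha, ybar = ybar, L = ch$L, w = w,
                 restarts = restarts, seed = seed, schema_version = 1L),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model %s: outputscale %.3g, lengthscale %.3g, noise_var %.3g, n = %d>\n",
              x$kernel, x$outputscale, x$lengthscale, x$noise_var, nrow(x$X)))
  invisible(x)
}

#' Predict from a fitted GP
#'
#' Predictive mean `ybar + k*' C^{-1} y_c` and variance
#' `s2 + noise_var - k*' C^{-1} k*` (the fitted white-noise floor is part of
#' the reported uncertainty; the per-training-sample `alpha` is not). The
#' variance never exceeds the prior variance `s2 + noise_var`.
#'
#' @param model A `gp_model`.
#' @param X_query Numeric matrix (or `feature_matrix`) of query features,
#'   scaled/selected with the training pipeline state.
#' @return A [predictive_distribution()].
#' @export
predict_gpr <- function(model, X_query) {
  stopifnot(inherits(model, "gp_model"))
  if (inherits(X_query, "feature_matrix")) X_query <- X_query$values
  if (is.null(dim(X_query))) X_query <- matrix(X_query, nrow = 1)
  if (ncol(X_query) != ncol(model$X)) {
    stop("query has ", ncol(X_query), " features, model expects ", ncol(model$X),
         call. = FALSE)
  }
  r <- sqrt(.sq_dist(X_query, model$X))
  Ks <- model$outputscale * .kernel_g(r / model$lengthscale, model$kernel)
  mean <- model$ybar + as.numeric(Ks %*% model$w)
  V <- forwardsolve(t(model$L), t(Ks))
  var <- model$outputscale + model$noise_var + model$jitter - colSums(V^2)
  predictive_distribution(mean, sqrt(pmax(var, 1e-12)))
}
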