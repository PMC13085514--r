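# Shared fixtures and independent oracles. Everything is generated in code at
# test time; nothing is read from disk.

write_obs_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# A tiny cached synthetic world reused by several test files (built once per
# test run; the chem backend memoises featurization).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_compounds(synthetic_spec(
        n_compounds = 40, replicate_range = c(3, 12), seed = 424242))
    }
    cache
  }
})

shared_curated <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- curate_records(shared_sim()$records)
    cache
  }
})

# Published pathway table used as ground truth for the probability checks:
# columns are mean, sd (2 dp as printed) and printed integer percents
# p(nP), p(P), p(vP). One-point slack is allowed only because the printed
# inputs are rounded to 2 dp.
PATHWAY_TABLE <- rbind(
  c(1.37, 0.06, 100, 0, 0),
  c(1.19, 0.14, 100, 0, 0),
  c(1.54, 0.52, 85, 15, 8),
  c(2.75, 0.14, 0, 100, 100),
  c(0.62, 0.45, 100, 0, 0),
  c(2.47, 0.58, 25, 75, 65),
  c(1.67, 0.60, 75, 25, 17),
  c(1.57, 0.64, 79, 21, 14),
  c(2.07, 0.66, 50, 50, 39),
  c(1.05, 0.65, 94, 6, 3),
  c(1.56, 0.63, 80, 20, 13))

# ---- independent oracles -------------------------------------------------

# Conjugate normal-normal posterior for the mean with KNOWN sigma:
# posterior variance 1/(1/s0^2 + n/sigma^2), mean weighted accordingly.
oracle_conjugate <- function(y, m0, s0, sigma) {
  v <- 1 / (1 / s0^2 + length(y) / sigma^2)
  list(mean = v * (m0 / s0^2 + sum(y) / sigma^2), sd = sqrt(v))
}

# Brute-force 2-D posterior integration, written independently of the package
# (plain double loop over a fine grid, trapezoid weights, direct likelihood
# evaluation observation by observation).
oracle_grid_posterior <- function(obs, m0, s0, sigma0, tau0,
                                  n_mu = 801, n_sigma = 601) {
  mu <- seq(m0 - 7 * s0, m0 + 7 * s0, length.out = n_mu)
  sig <- seq(1e-4, sigma0 + 7 * tau0, length.out = n_sigma)
  lp <- matrix(0, n_mu, n_sigma)
  for (j in seq_len(n_sigma)) {
    l <- dnorm(mu, m0, s0, log = TRUE) + dnorm(sig[j], sigma0, tau0, log = TRUE)
    for (k in seq_len(nrow(obs))) {
      l <- l + switch(obs$censor[k],
        exact = dnorm(obs$log_value[k], mu, sig[j], log = TRUE),
        left = pnorm(obs$log_value[k], mu, sig[j], log.p = TRUE),
        right = pnorm(obs$log_value[k], mu, sig[j], lower.tail = FALSE,
                      log.p = TRUE))
    }
    lp[, j] <- l
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mu_mean <- sum(rowSums(w) * mu)
  list(mu_mean = mu_mean,
       mu_std = sqrt(sum(rowSums(w) * (mu - mu_mean)^2)),
       sigma_mean = sum(colSums(w) * sig),
       # posterior predictive exceedance P(y_new >= thr)
       predictive_exceedance = function(thr) {
         sum(w * outer(mu, sig, function(m, s) pnorm((thr - m) / s,
                                                     lower.tail = FALSE)))
       })
}

# Dense linear-algebra GP oracle (solve(), no Cholesky reuse).
oracle_gp <- function(X, y, alpha, Xq, kernel, s2, ell, nv) {
  base <- function(r) {
    u <- r / ell
    switch(kernel,
      rbf = exp(-u^2 / 2),
      matern15 = (1 + sqrt(3) * u) * exp(-sqrt(3) * u),
      matern25 = (1 + sqrt(5) * u + 5 * u^2 / 3) * exp(-sqrt(5) * u))
  }
  rXX <- as.matrix(stats::dist(X))
  C <- s2 * base(rXX) + diag(nv + alpha, nrow(X))
  rq <- sqrt(outer(rowSums(Xq^2), rowSums(X^2), "+") - 2 * Xq %*% t(X))
  rq[!is.finite(rq) | rq < 0] <- 0
  Ks <- s2 * base(rq)
  mean <- as.numeric(Ks %*% solve(C, y))
  var <- s2 + nv - diag(Ks %*% solve(C, t(Ks)))
  list(mean = mean, sd = sqrt(pmax(var, 0)))
}

# Closed-form ridge regression oracle.
oracle_ridge <- function(Xtr, ytr, Xte, lambda = 1) {
  Xtr <- cbind(1, Xtr); Xte <- cbind(1, Xte)
  pen <- diag(c(0, rep(lambda, ncol(Xtr) - 1)))
  beta <- solve(crossprod(Xtr) + pen, crossprod(Xtr, ytr))
  as.numeric(Xte %*% beta)
}
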