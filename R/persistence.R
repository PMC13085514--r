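# REACH persistence probabilities from Gaussian log10 half-life distributions.
#
# For a threshold T in days, the probability that a compound's mean half-life
# exceeds T is
#     p(log DT50 >= log T) = 1 - Phi((log10 T - mu) / sd)
# with Phi the standard normal CDF. p(P) uses T = 120 d, p(vP) uses T = 180 d,
# and p(nP) = 1 - p(P).

#' Regulatory persistence thresholds
#'
#' Defaults are the REACH soil criteria: persistent at a half-life of 120 days
#' or more, very persistent at 180 days or more. Other jurisdictions can be
#' accommodated by overriding the values.
#'
#' @param T_P Persistence threshold in days.
#' @param T_vP Very-persistent threshold in days (> `T_P`).
#' @return An object of class `regulatory_thresholds`.
#' @export
regulatory_thresholds <- function(T_P = 120, T_vP = 180) {
  stopifnot(T_P > 0, T_vP > T_P)
  structure(list(T_P = T_P, T_vP = T_vP), class = "regulatory_thresholds")
}

#' Probability that the half-life exceeds a threshold
#'
#' @param mu Mean log10 half-life (log10 days); vectorized.
#' @param sd Standard deviation of the log10 half-life (> 0); vectorized.
#' @param T_days Threshold in days (> 0).
#' @return `1 - pnorm((log10(T_days) - mu) / sd)`, in `[0, 1]`.
#' @export
exceedance_probability <- function(mu, sd, T_days) {
  stopifnot(is.numeric(mu), is.numeric(sd), length(T_days) == 1, T_days > 0)
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("sd must be positive; for a degenerate (sd = 0) distribution use ",
         "classify_with_ci()", call. = FALSE)
  }
  stats::pnorm((log10(T_days) - mu) / sd, lower.tail = FALSE)
}

#' Round a probability to an integer percent, half up
#'
#' Regulatory tables print integer percentages with conventional half-up
#' rounding (0.495 -> 50), not banker's rounding.
#'
#' @param p Probability in `[0, 1]`.
#' @return Integer percent.
#' @export
percent_half_up <- function(p) {
  as.integer(floor(p * 100 + 0.5))
}

.confidence_category <- function(sd) {
  ifelse(sd < 0.5, "good", ifelse(sd < 0.7, "acceptable", "low"))
}

#' Persistence assessment of a half-life distribution
#'
#' Converts a Gaussian log10 half-life distribution into REACH class
#' probabilities and a prediction-confidence category. The confidence bands
#' follow the suggested uncertainty guidance: `sd < 0.5` log10 days ("good",
#' about a 3-fold change in half-life), `0.5 <= sd < 0.7` ("acceptable",
#' about 5-fold), and `sd >= 0.7` ("low").
#'
#' @param dist A `halflife_distribution`, a `predictive_distribution`, or a
#'   numeric `c(mean, sd)`.
#' @param thresholds A [regulatory_thresholds()].
#' @param source Label recorded in the output: `"bayesian"` for distributions
#'   inferred from data, `"predicted"` for model output. Inferred from the
#'   class of `dist` when `NULL`.
#' @return An object of class `persistence_assessment`: list with `p_nP`,
#'   `p_P`, `p_vP`, `confidence`, `source` (and integer-percent fields
#'   `pct_nP`, `pct_P`, `pct_vP`).
#' @export
assess <- function(dist, thresholds = regulatory_thresholds(), source = NULL) {
  ms <- .dist_mean_sd(dist)
  if (is.null(source)) {
    source <- if (inherits(dist, "predictive_distribution")) "predicted" else "bayesian"
  }
  p_P <- exceedance_probability(ms$mean, ms$sd, thresholds$T_P)
  p_vP <- exceedance_probability(ms$mean, ms$sd, thresholds$T_vP)
  structure(list(p_nP = 1 - p_P, p_P = p_P, p_vP = p_vP,
                 pct_nP = percent_half_up(1 - p_P),
                 pct_P = percent_half_up(p_P),
                 pct_vP = percent_half_up(p_vP),
                 confidence = .confidence_category(ms$sd),
                 source = source,
                 mu = ms$mean, sd = ms$sd),
            class = "persistence_assessment")
}

#' @export
print.persistence_assessment <- function(x, ...) {
  cat(sprintf(
    "<persistence_assessment mu = %.2f, sd = %.2f | p(nP,P,vP) = %d, %d, %d%% | %s, %s>\n",
    x$mu, x$sd, x$pct_nP, x$pct_P, x$pct_vP, x$confidence, x$source))
  invisible(x)
}

#' Vectorized persistence assessment table
#'
#' @param compound_id Identifier vector.
#' @param mu,sd Mean and SD of log10 half-life, per compound.
#' @inheritParams assess
#' @return A `data.frame` with columns `compound_id`, `mu`, `sd`, `p_nP`,
#'   `p_P`, `p_vP`, `confidence`, `source`.
#' @export
assess_table <- function(compound_id, mu, sd,
                         thresholds = regulatory_thresholds(),
                         source = "predicted") {
  stopifnot(length(mu) == length(sd), length(compound_id) == length(mu))
  p_P <- exceedance_probability(mu, sd, thresholds$T_P)
  p_vP <- exceedance_probability(mu, sd, thresholds$T_vP)
  data.frame(compound_id = compound_id, mu = mu, sd = sd,
             p_nP = 1 - p_P, p_P = p_P, p_vP = p_vP,
             confidence = .confidence_category(sd),
             source = source, stringsAsFactors = FALSE)
}
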