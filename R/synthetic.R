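# Seeded synthetic-data generators. They emulate the statistical structure of
# a soil-simulation-study export -- per-compound replicate counts from 1 to 59,
# log10-normal half-lives around 1.2 log10 days, occasional right-censored
# values -- over a built-in combinatorial vocabulary of small organic
# molecules, so the whole pipeline is testable without any download. They make
# no attempt to mimic real pesticide chemistry.

.synth_env <- new.env(parent = emptyenv())

.SYNTH_TEMPLATES <- c("%sc1ccc(%s)cc1", "%sc1cccc(%s)c1", "%sc1ccc(%s)nc1",
                      "%sc1ccc(%s)s1", "%sc1ccc(%s)o1", "%sC1CCC(%s)CC1")
.SYNTH_GROUPS <- c("C", "CC", "CCC", "CCCC", "C(C)C", "O", "OC", "OCC", "CO",
                   "CCO", "N", "NC", "F", "Cl", "Br", "S", "SC", "N#C", "C#N",
                   "OC(=O)", "C(=O)O", "C(=O)OC", "NC(=O)", "C(=O)N",
                   "C(F)(F)F", "[N+](=O)[O-]", "OCC(=O)O")

#' Built-in synthetic SMILES vocabulary
#'
#' Disubstituted benzene / pyridine / thiophene / furan / cyclohexane
#' scaffolds crossed with a fixed substituent list; combinations that RDKit
#' cannot parse are discarded, survivors are canonicalized, deduplicated,
#' filtered through the applicability-domain gate and sorted. Deterministic;
#' well over 500 distinct structures.
#'
#' @return Character vector of canonical SMILES.
#' @export
synthetic_vocabulary <- function() {
  if (!is.null(.synth_env$vocab)) return(.synth_env$vocab)
  raw <- unlist(lapply(.SYNTH_TEMPLATES, function(tpl) {
    outer(.SYNTH_GROUPS, .SYNTH_GROUPS,
          function(a, b) sprintf(tpl, a, b))
  }))
  res <- chem_batch("standardize", raw)
  canon <- unlist(lapply(res, function(r) if (isTRUE(r$ok)) r$canonical else NULL))
  canon <- sort(unique(canon))
  ad <- check_applicability_domain(canon)
  vocab <- canon[ad$in_domain]
  .synth_env$vocab <- vocab
  vocab
}

#' Synthetic-world specification
#'
#' Defaults state the emulated world once: replicate counts uniform on 1..59
#' (the observed range in soil data packages), replicate scatter
#' `sigma* ~ Uniform(0.15, 0.6)` log10 days, a 5% rate of right-censored
#' reports, and a structure signal that is affine in five standardized 2-D
#' descriptors around the 1.2 log10-day center of soil half-life data, with
#' compound-level noise `noise_sd`.
#'
#' @param n_compounds Number of compounds to generate.
#' @param replicate_range Integer `(min, max)` replicate counts.
#' @param true_sigma_range Range of the true replicate SD, log10 days.
#' @param censor_fraction Probability that an observation is reported as a
#'   censored bound at its own value, in `[0, 1)`.
#' @param signal_model `"linear_in_descriptors"` (structure-driven) or
#'   `"lookup"` (pure random compound means; no structure signal).
#' @param noise_sd SD of compound-level noise around the structural signal,
#'   log10 days.
#' @param seed Integer seed; everything downstream is a deterministic
#'   function of the spec.
#' @param censor_side `"right"` (default; the dominant regulatory case
#'   "beyond the last sampling time point") or `"left"`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 100, replicate_range = c(1, 59),
                           true_sigma_range = c(0.15, 0.6),
                           censor_fraction = 0.05,
                           signal_model = c("linear_in_descriptors", "lookup"),
                           noise_sd = 0.3, seed = 1, censor_side = "right") {
  signal_model <- match.arg(signal_model)
  stopifnot(n_compounds >= 1,
            length(replicate_range) == 2, replicate_range[1] >= 1,
            replicate_range[2] >= replicate_range[1],
            true_sigma_range[1] > 0, true_sigma_range[2] >= true_sigma_range[1],
            censor_fraction >= 0, censor_fraction < 1, noise_sd >= 0,
            censor_side %in% c("right", "left"))
  structure(list(n_compounds = as.integer(n_compounds),
                 replicate_range = as.integer(replicate_range),
                 true_sigma_range = true_sigma_range,
                 censor_fraction = censor_fraction,
                 signal_model = signal_model, noise_sd = noise_sd,
                 seed = as.integer(seed), censor_side = censor_side),
            class = "synthetic_spec")
}

.SIGNAL_DESCRIPTORS <- c("MolWt", "MolLogP", "TPSA", "NumRotatableBonds", "RingCount")
.SIGNAL_WEIGHTS <- c(0.30, 0.35, 0.25, 0.20, 0.15)
.SIGNAL_INTERCEPT <- 1.2

#' Generate synthetic compounds and observations
#'
#' Draws distinct structures from [synthetic_vocabulary()], assigns each a
#' true mean log10 half-life `mu*` (affine in five standardized descriptors
#' plus Normal(0, `noise_sd`) compound noise, or purely random under
#' `"lookup"`), a true replicate SD `sigma*`, and `n_i` replicate observations
#' `y_ij ~ Normal(mu*, sigma*^2)`. With probability `censor_fraction` an
#' observation is converted to a censored bound at its own value. The ground
#' truth is returned separately and is never consumed by the pipeline.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (list of `compound_record`) and `truth`
#'   (`data.frame`: `compound_id`, `smiles`, `mu_star`, `sigma_star`, `n`).
#' @export
generate_compounds <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vocab <- synthetic_vocabulary()
  if (spec$n_compounds > length(vocab)) {
    stop("vocabulary exhausted: ", length(vocab), " structures available, ",
         spec$n_compounds, " requested", call. = FALSE)
  }
  set.seed(spec$seed)
  smiles <- sample(vocab, spec$n_compounds)
  ids <- sprintf("SYNC%04d", seq_len(spec$n_compounds))

  if (spec$signal_model == "linear_in_descriptors") {
    res <- chem_batch("descriptors", smiles, list(names = .SIGNAL_DESCRIPTORS))
    D <- t(vapply(res, function(r)
      vapply(.SIGNAL_DESCRIPTORS, function(k) as.numeric(r$descriptors[[k]]),
             numeric(1)),
      numeric(length(.SIGNAL_DESCRIPTORS))))
    Z <- scale(D)
    Z[!is.finite(Z)] <- 0  # constant descriptor across the draw
    signal <- as.numeric(Z %*% .SIGNAL_WEIGHTS)
  } else {
    signal <- rep(0, spec$n_compounds)
  }
  mu_star <- .SIGNAL_INTERCEPT + signal +
    stats::rnorm(spec$n_compounds, 0, spec$noise_sd)
  sigma_star <- stats::runif(spec$n_compounds, spec$true_sigma_range[1],
                             spec$true_sigma_range[2])
  n_i <- sample(seq(spec$replicate_range[1], spec$replicate_range[2]),
                spec$n_compounds, replace = TRUE)

  records <- vector("list", spec$n_compounds)
  for (i in seq_len(spec$n_compounds)) {
    y <- stats::rnorm(n_i[i], mu_star[i], sigma_star[i])
    censor <- rep("exact", n_i[i])
    if (spec$censor_fraction > 0) {
      hit <- stats::runif(n_i[i]) < spec$censor_fraction
      censor[hit] <- spec$censor_side
    }
    records[[i]] <- compound_record(ids[i], smiles[i],
                                    observation(10^y, censor))
  }
  truth <- data.frame(compound_id = ids, smiles = smiles, mu_star = mu_star,
                      sigma_star = sigma_star, n = n_i, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}
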