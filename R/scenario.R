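# Scenario configuration: covariate specifications, the linear probability
# outcome model, and complete simulation worlds.

#' Covariate specification
#'
#' Describes one baseline covariate, independently distributed of all
#' others, with population-specific parameters: a Bernoulli prevalence for
#' binary covariates, or a normal mean (with common standard deviation) for
#' continuous ones.
#'
#' @param label short unique label, e.g. `"Z111"`.
#' @param kind `"binary"` or `"continuous-normal"`.
#' @param trial_param prevalence (binary) or mean (continuous) in the trial
#'   population.
#' @param target_param same quantity in the target population.
#' @param scale_param standard deviation, continuous covariates only.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(label, kind = c("binary", "continuous-normal"),
                           trial_param, target_param, scale_param = 1) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.numeric(trial_param), length(trial_param) == 1L,
            is.numeric(target_param), length(target_param) == 1L)
  if (kind == "binary") {
    if (trial_param < 0 || trial_param > 1 || target_param < 0 || target_param > 1)
      stop("binary covariate parameters must be probabilities in [0, 1]")
  } else {
    if (!is.numeric(scale_param) || scale_param <= 0)
      stop("continuous covariate scale_param must be > 0")
  }
  structure(
    list(label = label, kind = kind,
         trial_param = as.numeric(trial_param),
         target_param = as.numeric(target_param),
         scale_param = as.numeric(scale_param)),
    class = "covariate_spec")
}

#' Outcome model specification
#'
#' A linear probability model for a binary outcome:
#' `Pr(Y = 1 | X, Z) = intercept + treatment_coef * X + sum_j main_coefs[j] * Z_j
#'  + sum_j interaction_coefs[j] * X * Z_j`.
#' Every coefficient is on the probability scale; interaction coefficients
#' encode effect measure modification on the risk-difference scale.
#'
#' @param intercept baseline risk.
#' @param treatment_coef coefficient on treatment `X`.
#' @param main_coefs named numeric vector, covariate label -> main-effect
#'   coefficient.  May be empty.
#' @param interaction_coefs named numeric vector, covariate label ->
#'   coefficient on the `X * Z` product.  May be empty.
#' @return an object of class `outcome_model_spec`.
#' @export
outcome_model_spec <- function(intercept, treatment_coef,
                               main_coefs = numeric(0),
                               interaction_coefs = numeric(0)) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(treatment_coef), length(treatment_coef) == 1L,
            is.numeric(main_coefs), is.numeric(interaction_coefs))
  if (length(main_coefs) && is.null(names(main_coefs)))
    stop("main_coefs must be named by covariate label")
  if (length(interaction_coefs) && is.null(names(interaction_coefs)))
    stop("interaction_coefs must be named by covariate label")
  structure(
    list(intercept = as.numeric(intercept),
         treatment_coef = as.numeric(treatment_coef),
         main_coefs = main_coefs,
         interaction_coefs = interaction_coefs,
         outcome_kind = "bernoulli-linear-probability"),
    class = "outcome_model_spec")
}

#' Dependent covariate specification
#'
#' A binary covariate whose prevalence depends linearly on other declared
#' covariates and on the population indicator:
#' `Pr(W = 1 | Z, P) = base + sum_j on[j] * Z_j + p_coef * P`, clipped to
#' `[0, 1]`.  Used only by scenarios that deliberately break the mutual
#' independence of the baseline covariates (the extra-covariate risk-ratio
#' variant).
#'
#' @param label covariate label.
#' @param base intercept of the prevalence model.
#' @param on named numeric vector of coefficients on parent covariates.
#' @param p_coef coefficient on the population indicator `P`.
#' @return object of class `dependent_covariate_spec`.
#' @export
dependent_covariate_spec <- function(label, base, on, p_coef) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(base), is.numeric(on), !is.null(names(on)),
            is.numeric(p_coef))
  structure(list(label = label, base = as.numeric(base), on = on,
                 p_coef = as.numeric(p_coef)),
            class = "dependent_covariate_spec")
}

# Exact range of the outcome linear predictor when treatment and all
# covariates are binary.  Interactions couple X with Z, so the extremes are
# taken within each treatment arm and then across arms.
.binary_lp_range <- function(outcome, labels) {
  b <- outcome$main_coefs[labels]
  b[is.na(b)] <- 0
  g <- outcome$interaction_coefs[labels]
  g[is.na(g)] <- 0
  lo0 <- outcome$intercept + sum(pmin(0, b))
  hi0 <- outcome$intercept + sum(pmax(0, b))
  lo1 <- outcome$intercept + outcome$treatment_coef + sum(pmin(0, b + g))
  hi1 <- outcome$intercept + outcome$treatment_coef + sum(pmax(0, b + g))
  c(min(lo0, lo1), max(hi0, hi1))
}

#' Scenario configuration
#'
#' A complete simulation world: population sizes, covariate specifications,
#' outcome model, treatment mechanism, effect scale, and replicate count.
#' Construction validates that, when treatment and every covariate are
#' binary, the outcome linear predictor stays inside `[0, 1]` for every
#' covariate/treatment cell; scenarios whose predictor can escape (any
#' continuous treatment or covariate) must declare `allow_clipping = TRUE`,
#' in which case out-of-range probabilities are clipped and counted at
#' generation time.
#'
#' @param name scenario name.
#' @param n_trial,n_target population sizes (>= 2).
#' @param covariates list of [covariate_spec()] objects, unique labels.
#' @param outcome an [outcome_model_spec()].
#' @param treatment_kind `"binary-randomized"` or `"continuous-normal"`.
#' @param randomization_prob treatment probability for binary treatment.
#' @param effect_scale `"RD"` or `"logRR"`.
#' @param n_replicates default replicate count for full-scale runs.
#' @param prob_clip epsilon used to clip fitted sampling probabilities into
#'   `(prob_clip, 1 - prob_clip)`.
#' @param allow_clipping permit (and count) clipping of outcome
#'   probabilities to `[0, 1]`.
#' @param dependent_covariates optional list of
#'   [dependent_covariate_spec()] objects, generated after the independent
#'   covariates.
#' @param approximate flag carried into reports for scenarios whose
#'   parameter values are package defaults rather than published constants.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(name, n_trial, n_target, covariates, outcome,
                            treatment_kind = c("binary-randomized",
                                               "continuous-normal"),
                            randomization_prob = 0.5,
                            effect_scale = c("RD", "logRR"),
                            n_replicates = 10000,
                            prob_clip = 1e-6,
                            allow_clipping = FALSE,
                            dependent_covariates = list(),
                            approximate = FALSE) {
  treatment_kind <- match.arg(treatment_kind)
  effect_scale <- match.arg(effect_scale)
  stopifnot(is.character(name), length(name) == 1L,
            n_trial >= 2, n_target >= 2,
            n_replicates >= 1, prob_clip > 0, prob_clip < 0.5,
            is.list(covariates), length(covariates) >= 1L,
            inherits(outcome, "outcome_model_spec"))
  if (randomization_prob <= 0 || randomization_prob >= 1)
    stop("randomization_prob must lie strictly inside (0, 1)")
  if (!all(vapply(covariates, inherits, logical(1), "covariate_spec")))
    stop("covariates must be a list of covariate_spec objects")
  labels <- vapply(covariates, `[[`, character(1), "label")
  dep_labels <- vapply(dependent_covariates, `[[`, character(1), "label")
  all_labels <- c(labels, dep_labels)
  if (anyDuplicated(all_labels))
    stop("covariate labels must be unique within a scenario")
  coef_labels <- unique(c(names(outcome$main_coefs),
                          names(outcome$interaction_coefs)))
  unknown <- setdiff(coef_labels, all_labels)
  if (length(unknown))
    stop("outcome model references undeclared covariate(s): ",
         paste(unknown, collapse = ", "))
  for (d in dependent_covariates) {
    if (!all(names(d$on) %in% labels))
      stop("dependent covariate '", d$label,
           "' references undeclared parent covariate(s)")
  }
  all_binary <- treatment_kind == "binary-randomized" &&
    all(vapply(covariates, function(s) s$kind == "binary", logical(1)))
  if (all_binary && !allow_clipping) {
    rng <- .binary_lp_range(outcome, all_labels)
    if (rng[1] < 0 || rng[2] > 1)
      stop(sprintf(paste0("outcome linear predictor escapes [0, 1] ",
                          "(range %.3f to %.3f); declare allow_clipping ",
                          "to permit clipping"), rng[1], rng[2]))
  }
  if (!all_binary && !allow_clipping)
    stop("scenarios with continuous treatment or covariates must declare ",
         "allow_clipping = TRUE")
  structure(
    list(name = name,
         n_trial = as.integer(n_trial), n_target = as.integer(n_target),
         covariates = covariates, outcome = outcome,
         treatment_kind = treatment_kind,
         randomization_prob = as.numeric(randomization_prob),
         effect_scale = effect_scale,
         n_replicates = as.integer(n_replicates),
         prob_clip = as.numeric(prob_clip),
         allow_clipping = isTRUE(allow_clipping),
         dependent_covariates = dependent_covariates,
         approximate = isTRUE(approximate)),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config '%s'>\n", x$name))
  cat(sprintf("  trial n = %d, target n = %d, scale = %s, replicates = %d\n",
              x$n_trial, x$n_target, x$effect_scale, x$n_replicates))
  for (s in x$covariates)
    cat(sprintf("  %s [%s]: trial %.3g, target %.3g\n",
                s$label, s$kind, s$trial_param, s$target_param))
  for (d in x$dependent_covariates)
    cat(sprintf("  %s [dependent binary]: base %.3g, p_coef %.3g\n",
                d$label, d$base, d$p_coef))
  invisible(x)
}

.base_covariates <- function() {
  list(
    covariate_spec("Z000", "binary", 0.5, 0.5),
    covariate_spec("Z010", "binary", 0.5, 0.5),
    covariate_spec("Z011", "binary", 0.5, 0.5),
    covariate_spec("Z100", "binary", 0.2, 0.8),
    covariate_spec("Z110", "binary", 0.2, 0.8),
    covariate_spec("Z111", "binary", 0.2, 0.8))
}

.base_outcome <- function() {
  outcome_model_spec(
    intercept = 0.1, treatment_coef = 0.1,
    main_coefs = c(Z010 = 0.1, Z011 = 0.1, Z110 = 0.1, Z111 = 0.1),
    interaction_coefs = c(Z011 = 0.1, Z111 = 0.1))
}

#' Base simulation scenario
#'
#' The reference world: a 10 000-person 1:1 randomized trial and a
#' 10 000-person external target population; six independent binary
#' covariates `Z000 ... Z111` with trial/target prevalences
#' 0.5/0.5 (first three) and 0.2/0.8 (last three); outcome probability
#' `0.1 + 0.1 X + 0.1 Z010 + 0.1 Z011 + 0.1 Z110 + 0.1 Z111
#'  + 0.1 X Z011 + 0.1 X Z111`; risk-difference scale.
#'
#' Under this model the true marginal RD is 0.230 in the target population
#' and 0.170 in the trial.
#'
#' @return a [scenario_config()].
#' @export
build_base_scenario <- function() {
  scenario_config(
    name = "base", n_trial = 10000, n_target = 10000,
    covariates = .base_covariates(), outcome = .base_outcome(),
    treatment_kind = "binary-randomized", randomization_prob = 0.5,
    effect_scale = "RD", n_replicates = 10000)
}

#' Sensitivity scenarios
#'
#' Seven named variants of the base world, each differing in the documented
#' fields only:
#' * `small_trial` — 1000-person trial, 10 000-person target.
#' * `large_target` — 10 000-person trial, 100 000-person target.
#' * `reduced_gap` — trial/target prevalences of `Z100`, `Z110`, `Z111`
#'   moved toward each other (default 0.35/0.65; a package default, flagged
#'   approximate).
#' * `rr_base` — effect scale switched to the log risk ratio.
#' * `rr_extra_covariate` — log risk ratio with an extra binary outcome
#'   predictor `W`, `Pr(W = 1) = 0.2 + 0.3 Z111 + 0.2 P`, outcome
#'   coefficient 0.1; the minimally sufficient set becomes `{Z111, W}`
#'   (defaults flagged approximate).
#' * `continuous_x` — treatment is standard normal instead of binary.
#' * `continuous_z` — `Z100`, `Z110`, `Z111` are normal with unit variance,
#'   trial mean 0 and target mean 1 (defaults flagged approximate).
#'
#' @param reduced_gap_params length-2 numeric, trial and target prevalence
#'   for the differential covariates in the `reduced_gap` variant.
#' @param continuous_z_means length-2 numeric, trial and target means for
#'   the `continuous_z` variant.
#' @return named list of [scenario_config()] objects.
#' @export
build_sensitivity_scenarios <- function(reduced_gap_params = c(0.35, 0.65),
                                        continuous_z_means = c(0, 1)) {
  base <- build_base_scenario()
  out <- list()

  out$small_trial <- base
  out$small_trial$name <- "small_trial"
  out$small_trial$n_trial <- 1000L

  out$large_target <- base
  out$large_target$name <- "large_target"
  out$large_target$n_target <- 100000L

  rg_cov <- .base_covariates()
  for (i in 4:6) {
    rg_cov[[i]]$trial_param <- reduced_gap_params[1]
    rg_cov[[i]]$target_param <- reduced_gap_params[2]
  }
  out$reduced_gap <- scenario_config(
    name = "reduced_gap", n_trial = 10000, n_target = 10000,
    covariates = rg_cov, outcome = .base_outcome(),
    approximate = TRUE)

  out$rr_base <- base
  out$rr_base$name <- "rr_base"
  out$rr_base$effect_scale <- "logRR"

  w_outcome <- .base_outcome()
  w_outcome$main_coefs <- c(w_outcome$main_coefs, W = 0.1)
  out$rr_extra_covariate <- scenario_config(
    name = "rr_extra_covariate", n_trial = 10000, n_target = 10000,
    covariates = .base_covariates(), outcome = w_outcome,
    effect_scale = "logRR",
    dependent_covariates = list(
      dependent_covariate_spec("W", base = 0.2, on = c(Z111 = 0.3),
                               p_coef = 0.2)),
    approximate = TRUE)

  out$continuous_x <- scenario_config(
    name = "continuous_x", n_trial = 10000, n_target = 10000,
    covariates = .base_covariates(), outcome = .base_outcome(),
    treatment_kind = "continuous-normal", allow_clipping = TRUE)

  cz_cov <- .base_covariates()
  for (i in 4:6) {
    cz_cov[[i]]$kind <- "continuous-normal"
    cz_cov[[i]]$trial_param <- continuous_z_means[1]
    cz_cov[[i]]$target_param <- continuous_z_means[2]
    cz_cov[[i]]$scale_param <- 1
  }
  out$continuous_z <- scenario_config(
    name = "continuous_z", n_trial = 10000, n_target = 10000,
    covariates = cz_cov, outcome = .base_outcome(),
    allow_clipping = TRUE, approximate = TRUE)

  out
}
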