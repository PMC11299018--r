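# JSON (de)serialization of scenario configurations and adjustment sets.
# The on-disk schema mirrors the constructors field for field, so a
# round-trip reconstructs an equal object.

.covariate_to_list <- function(s) {
  list(label = s$label, kind = s$kind, trial_param = s$trial_param,
       target_param = s$target_param, scale_param = s$scale_param)
}

.dependent_to_list <- function(d) {
  list(label = d$label, base = d$base, on = as.list(d$on),
       p_coef = d$p_coef)
}

#' Serialize a scenario configuration to JSON
#'
#' @param config a [scenario_config()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
scenario_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  x <- list(
    name = config$name,
    n_trial = config$n_trial, n_target = config$n_target,
    covariates = lapply(config$covariates, .covariate_to_list),
    outcome = list(
      intercept = config$outcome$intercept,
      treatment_coef = config$outcome$treatment_coef,
      main_coefs = as.list(config$outcome$main_coefs),
      interaction_coefs = as.list(config$outcome$interaction_coefs)),
    treatment_kind = config$treatment_kind,
    randomization_prob = config$randomization_prob,
    effect_scale = config$effect_scale,
    n_replicates = config$n_replicates,
    prob_clip = config$prob_clip,
    allow_clipping = config$allow_clipping,
    dependent_covariates = lapply(config$dependent_covariates,
                                  .dependent_to_list),
    approximate = config$approximate)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Read a scenario configuration from JSON
#'
#' @param path file path or a JSON string.
#' @return a [scenario_config()].
#' @export
scenario_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  covs <- lapply(x$covariates, function(s)
    covariate_spec(s$label, s$kind, s$trial_param, s$target_param,
                   s$scale_param))
  outcome <- outcome_model_spec(
    intercept = x$outcome$intercept,
    treatment_coef = x$outcome$treatment_coef,
    main_coefs = unlist(x$outcome$main_coefs) %||% numeric(0),
    interaction_coefs = unlist(x$outcome$interaction_coefs) %||% numeric(0))
  deps <- lapply(x$dependent_covariates, function(d)
    dependent_covariate_spec(d$label, d$base, unlist(d$on), d$p_coef))
  scenario_config(
    name = x$name, n_trial = x$n_trial, n_target = x$n_target,
    covariates = covs, outcome = outcome,
    treatment_kind = x$treatment_kind,
    randomization_prob = x$randomization_prob,
    effect_scale = x$effect_scale,
    n_replicates = x$n_replicates,
    prob_clip = x$prob_clip,
    allow_clipping = x$allow_clipping,
    dependent_covariates = deps,
    approximate = x$approximate)
}

#' Serialize adjustment sets to JSON
#'
#' @param sets list of [adjustment_set()] objects.
#' @param path optional file path.
#' @return JSON string, invisibly when written to a file.
#' @export
adjustment_sets_to_json <- function(sets, path = NULL) {
  x <- lapply(sets, function(s)
    list(name = s$name, members = as.list(s$members), referent = s$referent))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Read adjustment sets from JSON
#'
#' @param path file path or JSON string.
#' @return list of [adjustment_set()] objects.
#' @export
adjustment_sets_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(x, function(s)
    adjustment_set(s$name, as.character(unlist(s$members)), s$referent))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
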