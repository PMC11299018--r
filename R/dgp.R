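# Data-generating process: simulate trial (P = 0) and target (P = 1)
# populations and compute closed-form true effects.
#
# The target population is completely external to the trial, so only its
# covariates are ever used: target tables carry no treatment or outcome.

.gen_covariates <- function(config, n, which_pop) {
  cols <- vector("list", length(config$covariates))
  names(cols) <- vapply(config$covariates, `[[`, character(1), "label")
  for (i in seq_along(config$covariates)) {
    s <- config$covariates[[i]]
    p <- if (which_pop == "trial") s$trial_param else s$target_param
    cols[[i]] <- if (s$kind == "binary") rbinom(n, 1L, p)
                 else rnorm(n, mean = p, sd = s$scale_param)
  }
  pind <- if (which_pop == "trial") 0L else 1L
  for (d in config$dependent_covariates) {
    pw <- rep(d$base + d$p_coef * pind, n)
    for (parent in names(d$on)) pw <- pw + d$on[[parent]] * cols[[parent]]
    pw <- pmin(1, pmax(0, pw))
    cols[[d$label]] <- rbinom(n, 1L, pw)
  }
  cols
}

.linear_predictor <- function(outcome, x, cols) {
  lp <- rep(outcome$intercept, length(x)) + outcome$treatment_coef * x
  for (lab in names(outcome$main_coefs))
    lp <- lp + outcome$main_coefs[[lab]] * cols[[lab]]
  for (lab in names(outcome$interaction_coefs))
    lp <- lp + outcome$interaction_coefs[[lab]] * (x * cols[[lab]])
  lp
}

#' Generate one trial/target population pair
#'
#' Covariates are drawn independently per [covariate_spec()] using the
#' population-specific parameter (dependent covariates afterwards, from
#' their parents).  In the trial, treatment is Bernoulli with the
#' randomization probability (or standard normal for continuous-treatment
#' scenarios) and the outcome is Bernoulli with probability given by the
#' linear predictor.  When the predictor can escape `[0, 1]` (continuous
#' treatment or covariates) it is clipped and the number of clipped rows is
#' recorded in the `n_clipped` attribute of the trial table; all-binary
#' scenarios are validated at construction so no clipping can occur.
#'
#' The same `seed` always reproduces the same pair bit for bit.  Trial and
#' target use separate substreams derived from `seed`, so the target draw
#' does not depend on how many trial columns were generated.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed for this replicate.
#' @return list with elements `trial` and `target`, each a `data.frame`
#'   with column `P`, one column per covariate, and (trial only) `X` and
#'   `Y`.  The trial table carries an `n_clipped` attribute.
#' @export
generate_populations <- function(config, seed) {
  stopifnot(inherits(config, "scenario_config"))
  sub <- derive_seeds(seed, 2L)

  set.seed(sub[1])
  n0 <- config$n_trial
  cols <- .gen_covariates(config, n0, "trial")
  x <- if (config$treatment_kind == "binary-randomized")
    rbinom(n0, 1L, config$randomization_prob) else rnorm(n0)
  lp <- .linear_predictor(config$outcome, x, cols)
  n_clipped <- sum(lp < 0 | lp > 1)
  if (n_clipped > 0) {
    if (!config$allow_clipping)
      stop("outcome probabilities escaped [0, 1] without a clipping policy")
    lp <- pmin(1, pmax(0, lp))
  }
  y <- rbinom(n0, 1L, lp)
  trial <- data.frame(P = 0L, cols, X = x, Y = y)
  attr(trial, "population") <- "trial"
  attr(trial, "n_clipped") <- n_clipped

  set.seed(sub[2])
  target <- data.frame(P = 1L,
                       .gen_covariates(config, config$n_target, "target"))
  attr(target, "population") <- "target"

  list(trial = trial, target = target)
}

#' Write a generated population to CSV
#'
#' Columns: `P`, one per covariate, then `X` and `Y` for trial tables.
#'
#' @param population a table from [generate_populations()].
#' @param path output file.
#' @export
write_population_csv <- function(population, path) {
  write.csv(population, path, row.names = FALSE, quote = FALSE)
}

# Population-specific covariate means implied by the configuration
# (ignoring prevalence clipping for dependent covariates, which the
# default parameterizations never trigger).
.covariate_means <- function(config, population) {
  mu <- numeric(0)
  for (s in config$covariates) {
    mu[[s$label]] <- if (population == "trial") s$trial_param
                     else s$target_param
  }
  pind <- if (population == "trial") 0 else 1
  for (d in config$dependent_covariates) {
    m <- d$base + d$p_coef * pind
    for (parent in names(d$on)) m <- m + d$on[[parent]] * mu[[parent]]
    mu[[d$label]] <- min(1, max(0, m))
  }
  mu
}

#' Closed-form true effect of treatment in a chosen population
#'
#' With independent covariates and a linear probability outcome model the
#' marginal risk difference in population `pop` is
#' `RD = beta_X + sum_j gamma_j E_pop[Z_j]`, where `gamma_j` are the
#' treatment-covariate interaction coefficients.  On the log risk ratio
#' scale, `risk0 = intercept + sum_j beta_j E_pop[Z_j]`,
#' `risk1 = risk0 + RD`, and the value is `log(risk1 / risk0)`.
#'
#' For continuous treatment the RD is read as the effect per unit of `X`;
#' the closed form is identical.  In clipped scenarios the formula ignores
#' clipping and is therefore an approximation wherever clipping actually
#' occurs.
#'
#' @param config a [scenario_config()].
#' @param population `"trial"` or `"target"`.
#' @param scale `"RD"` or `"logRR"`; defaults to the scenario's scale.
#' @return object of class `true_effect` with fields `scale`, `population`
#'   and `value`.
#' @export
true_effect <- function(config, population = c("target", "trial"),
                        scale = NULL) {
  population <- match.arg(population)
  scale <- if (is.null(scale)) config$effect_scale
           else match.arg(scale, c("RD", "logRR"))
  mu <- .covariate_means(config, population)
  gamma <- config$outcome$interaction_coefs
  rd <- config$outcome$treatment_coef +
    sum(vapply(names(gamma), function(l) gamma[[l]] * mu[[l]], numeric(1)))
  value <- if (scale == "RD") {
    rd
  } else {
    beta <- config$outcome$main_coefs
    risk0 <- config$outcome$intercept +
      sum(vapply(names(beta), function(l) beta[[l]] * mu[[l]], numeric(1)))
    risk1 <- risk0 + rd
    if (risk0 <= 0 || risk1 <= 0)
      stop("logRR undefined: a potential-outcome risk is <= 0")
    log(risk1 / risk0)
  }
  structure(list(scale = scale, population = population, value = value),
            class = "true_effect")
}

#' @export
print.true_effect <- function(x, ...) {
  cat(sprintf("true %s in %s population: %.4f\n", x$scale, x$population,
              x$value))
  invisible(x)
}
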