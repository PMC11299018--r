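test_that("sampling model reproduces stratum proportions on the worked example", {
  fit <- fit_sampling_probabilities(tiny_trial(), tiny_target(), tiny_adj())
  expect_s3_class(fit, "sampling_fit")
  # saturated one-binary-covariate OLS: Pr(P=1|Z=1) = 8/12, Pr(P=1|Z=0) = 2/6
  z <- tiny_trial()$Z
  expect_equal(unname(fit$probabilities[z == 1]), rep(2 / 3, 4))
  expect_equal(unname(fit$probabilities[z == 0]), rep(1 / 3, 4))
  expect_length(fit$coefficients, 2L)
  expect_identical(fit$n_clipped, 0L)

  w <- inverse_odds_weights(fit)
  expect_equal(unname(w$weights[z == 1]), rep(2, 4))
  expect_equal(unname(w$weights[z == 0]), rep(0.5, 4))
})

test_that("intercept-only sampling fits return the pooled proportion", {
  trial <- data.frame(P = 0L, Z = rbinom(40, 1, 0.5),
                      X = rep(0:1, 20), Y = rbinom(40, 1, 0.3))
  target_eq <- data.frame(P = 1L, Z = rbinom(40, 1, 0.5))
  fit <- fit_sampling_probabilities(trial, target_eq, character(0))
  expect_equal(unname(fit$probabilities), rep(0.5, 40))

  target_10x <- data.frame(P = 1L, Z = rbinom(400, 1, 0.5))
  fit2 <- fit_sampling_probabilities(trial, target_10x, character(0))
  expect_equal(unname(fit2$probabilities), rep(10 / 11, 40))
})

test_that("odds arithmetic and clipping boundary are honoured", {
  mkfit <- function(p) structure(list(probabilities = p, coefficients = 0,
                                      n_clipped = 0L), class = "sampling_fit")
  expect_equal(inverse_odds_weights(mkfit(0.5))$weights, 1)
  expect_equal(inverse_odds_weights(mkfit(2 / 3))$weights, 2)
  eps <- 1e-6
  w <- inverse_odds_weights(mkfit(1 - eps))$weights
  expect_true(is.finite(w))
  expect_equal(w, (1 - eps) / eps)

  # clipping engages when one population lacks a covariate level
  trial <- data.frame(P = 0L, Z = rep(c(0L, 1L), 10),
                      X = rep(0:1, 10), Y = rbinom(20, 1, 0.5))
  target <- data.frame(P = 1L, Z = rep(1L, 20))
  fit <- fit_sampling_probabilities(trial, target, "Z")
  expect_gt(fit$n_clipped, 0L)
  expect_true(all(fit$probabilities > 0 & fit$probabilities < 1))
})

test_that("Hajek normalization sums to one within each treatment arm", {
  set.seed(1)
  x <- rbinom(50, 1, 0.5)
  w <- rexp(50) + 0.01
  nw <- hajek_normalize(w, x)
  expect_equal(sum(nw[x == 1]), 1)
  expect_equal(sum(nw[x == 0]), 1)
  expect_true(all(nw > 0))
})

test_that("both estimators recover 0.4 on the worked example; crude is 0.25", {
  trial <- tiny_trial(); target <- tiny_target(); adj <- tiny_adj()
  expect_equal(iow_estimate(trial, target, adj), 0.4)
  expect_equal(outcome_model_estimate(trial, target, adj), 0.4)
  expect_equal(crude_estimate(trial), 0.25)
  expect_equal(direct_standardization_rd(trial, target), 0.4)
})

test_that("empty adjustment set reduces every estimator to the crude contrast", {
  trial <- tiny_trial(); target <- tiny_target()
  empty <- adjustment_set("empty", character(0), "self")
  expect_identical(iow_estimate(trial, target, empty), crude_estimate(trial))
  expect_identical(outcome_model_estimate(trial, target, empty),
                   crude_estimate(trial))

  set.seed(33)
  big <- data.frame(P = 0L, Z = rbinom(200, 1, 0.4), X = rbinom(200, 1, 0.5),
                    Y = rbinom(200, 1, 0.5))
  tgt <- data.frame(P = 1L, Z = rbinom(100, 1, 0.7))
  expect_equal(iow_estimate(big, tgt, empty), crude_estimate(big))
  expect_equal(outcome_model_estimate(big, tgt, empty), crude_estimate(big))
})

test_that("estimators equal direct stratum standardization on balanced instances", {
  for (seed in c(4, 8, 15, 16, 23, 42)) {
    inst <- balanced_instance(seed)
    # both covariate strata and both arms must be populated for the oracle
    tab <- table(inst$trial$Z, inst$trial$X)
    if (any(tab == 0) || length(unique(inst$target$Z)) < 2) next
    oracle <- direct_standardization_rd(inst$trial, inst$target)
    adj <- adjustment_set("Z", "Z", "alone")
    expect_equal(iow_estimate(inst$trial, inst$target, adj), oracle,
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(outcome_model_estimate(inst$trial, inst$target, adj),
                 oracle, tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("estimates are invariant to row permutation of either table", {
  set.seed(99)
  cfg <- build_base_scenario()
  cfg$n_trial <- 400L; cfg$n_target <- 300L
  pops <- generate_populations(cfg, 1L)
  adj <- adjustment_set("a", c("Z100", "Z111"), "plus_z111")
  ref_iow <- iow_estimate(pops$trial, pops$target, adj)
  ref_om <- outcome_model_estimate(pops$trial, pops$target, adj)
  for (i in 1:3) {
    tr <- pops$trial[sample(nrow(pops$trial)), ]
    tg <- pops$target[sample(nrow(pops$target)), ]
    expect_equal(iow_estimate(tr, tg, adj), ref_iow)
    expect_equal(outcome_model_estimate(tr, tg, adj), ref_om)
  }
})

test_that("constant design columns are dropped with a classed warning", {
  trial <- data.frame(P = 0L, Z = rep(1L, 20), W = rep(c(0L, 1L), 10),
                      X = rep(0:1, 10), Y = rbinom(20, 1, 0.5))
  target <- data.frame(P = 1L, Z = rep(1L, 10), W = rbinom(10, 1, 0.5))
  expect_warning(
    fit <- fit_sampling_probabilities(trial, target, c("Z", "W")),
    class = "transportsim_dropped_column")
  # dropping the constant column must equal never having included it
  fit_ref <- fit_sampling_probabilities(trial, target, "W")
  expect_equal(fit$probabilities, fit_ref$probabilities)
})

test_that("logRR domain failures raise a classed condition", {
  # untreated arm with all-zero outcomes => mu0 = 0
  trial <- data.frame(P = 0L, Z = rep(c(0L, 1L), 10), X = rep(0:1, 10),
                      Y = ifelse(rep(0:1, 10) == 1, 1L, 0L))
  target <- data.frame(P = 1L, Z = rbinom(10, 1, 0.5))
  expect_error(crude_estimate(trial, "logRR"),
               class = "transportsim_estimate_failure")
  expect_error(iow_estimate(trial, target, "Z", "logRR"),
               class = "transportsim_estimate_failure")
  # empty arm is a hard error, not a coded failure
  all1 <- data.frame(P = 0L, Z = 0L, X = rep(1L, 10), Y = rbinom(10, 1, 0.5))
  expect_error(crude_estimate(all1), "empty treatment arm")
})

test_that("continuous-treatment estimators behave as weighted regressions", {
  set.seed(12)
  x <- rnorm(100)
  trial <- data.frame(P = 0L, Z = rbinom(100, 1, 0.5), X = x,
                      Y = 0.2 + 0.3 * x)
  target <- data.frame(P = 1L, Z = rbinom(50, 1, 0.5))
  # exact linear outcome => exact slope recovery, any weights
  expect_equal(iow_estimate_continuous(trial, target, "Z"), 0.3)
  expect_equal(iow_estimate_continuous(trial, target, character(0)), 0.3)

  # outcome-model analogue: Y = a + bX + cZ + dXZ recovered exactly,
  # transported slope = b + d * mean(target Z)
  trial2 <- trial
  trial2$Y <- 0.1 + 0.2 * x + 0.15 * trial$Z + 0.25 * x * trial$Z
  slope <- 0.2 + 0.25 * mean(target$Z)
  expect_equal(outcome_model_estimate_continuous(trial2, target, "Z"), slope)

  const <- data.frame(P = 0L, Z = 0L, X = rep(1, 10), Y = rep(0.5, 10))
  expect_error(iow_estimate_continuous(const, target, character(0)),
               "degenerate")
})
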