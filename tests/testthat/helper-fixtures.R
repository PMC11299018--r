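# Hand-checkable worked example: one binary covariate Z, trial of 8 with
# balanced 1:1 treatment inside each Z stratum, target of 10 with
# Pr(Z = 1) = 0.8.  Known answers: sampling probabilities 2/3 (Z=1) and
# 1/3 (Z=0), inverse odds weights 2 and 0.5, transported RD 0.4 for both
# estimators, crude RD 0.25.
tiny_trial <- function() {
  data.frame(P = 0L,
             Z = c(1, 1, 1, 1, 0, 0, 0, 0),
             X = c(1, 1, 0, 0, 1, 1, 0, 0),
             Y = c(1, 1, 0, 1, 0, 0, 0, 0))
}

tiny_target <- function() {
  data.frame(P = 1L, Z = c(rep(1L, 8), rep(0L, 2)))
}

tiny_adj <- function() adjustment_set("Z alone", "Z", "alone")

# Random single-binary-covariate instance with exactly balanced treatment
# arms within each covariate stratum (treatment proportion equal across
# strata), for which both estimators must agree exactly with direct
# stratum standardization.
balanced_instance <- function(seed) {
  set.seed(seed)
  n_z1 <- 2L * sample(3:10, 1)
  n_z0 <- 2L * sample(3:10, 1)
  z <- c(rep(1L, n_z1), rep(0L, n_z0))
  x <- c(rep(c(0L, 1L), n_z1 / 2), rep(c(0L, 1L), n_z0 / 2))
  y <- rbinom(length(z), 1L, 0.3 + 0.3 * z + 0.2 * x * z)
  trial <- data.frame(P = 0L, Z = z, X = x, Y = y)
  m <- sample(5:30, 1)
  target <- data.frame(P = 1L, Z = rbinom(m, 1L, 0.7))
  list(trial = trial, target = target)
}

# Direct standardization oracle: stratum-specific arm-mean contrasts
# weighted by the target covariate distribution.  Independent of the
# estimator code paths (plain counting).
direct_standardization_rd <- function(trial, target) {
  mu <- c(0, 0)
  for (arm in 0:1) {
    acc <- 0
    for (z in unique(target$Z)) {
      rows <- trial$Y[trial$Z == z & trial$X == arm]
      acc <- acc + mean(rows) * mean(target$Z == z)
    }
    mu[arm + 1] <- acc
  }
  mu[2] - mu[1]
}
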