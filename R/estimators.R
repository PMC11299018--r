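# Transport estimators: inverse odds weighting (IOW) and
# treatment-stratified outcome-model standardization, plus the crude
# trial contrast.
#
# Both the sampling model and the outcome models are linear probability
# models fit by ordinary least squares, with main effects of the
# adjustment-set members only.  Treatment-by-covariate interactions enter
# the outcome approach implicitly through stratification on treatment.

# Signalled for replicate-level domain failures (e.g. a nonpositive risk
# on the log risk ratio scale).  The simulation engine records these as
# failed replicates instead of propagating them.
estimate_failure <- function(msg) {
  stop(errorCondition(msg, class = c("transportsim_estimate_failure",
                                     "error", "condition")))
}

.members_of <- function(adj) {
  if (inherits(adj, "adjustment_set")) adj$members else as.character(adj)
}

# Design matrix of an intercept plus the named columns, dropping columns
# that are constant in `data_cols` (singular design) with a classed
# warning.  Returns the matrix and the labels actually kept.
.design <- function(data_cols, members) {
  n <- length(data_cols[[1]]) %||% 0L
  keep <- character(0)
  for (m in members) {
    col <- data_cols[[m]]
    if (is.null(col)) stop("adjustment set member '", m, "' not found")
    if (min(col) == max(col)) {
      warning(warningCondition(
        paste0("dropping constant column '", m, "' from a singular design"),
        class = "transportsim_dropped_column"))
    } else keep <- c(keep, m)
  }
  X <- matrix(1, n, 1L + length(keep))
  for (j in seq_along(keep)) X[, j + 1L] <- data_cols[[keep[j]]]
  colnames(X) <- c("(Intercept)", keep)
  X
}

# OLS coefficients with aliased (NA) coefficients zeroed, equivalent to
# dropping the redundant column.
.ols_coef <- function(X, y, w = NULL) {
  fit <- if (is.null(w)) lm.fit(X, y) else lm.wfit(X, y, w)
  co <- fit$coefficients
  if (anyNA(co)) {
    warning(warningCondition(
      "aliased coefficient(s) set to zero in a rank-deficient fit",
      class = "transportsim_dropped_column"))
    co[is.na(co)] <- 0
  }
  co
}

#' Fit the linear probability sampling model
#'
#' Stacks the trial (`P = 0`) and target (`P = 1`) rows and regresses the
#' population indicator on an intercept plus main effects of the
#' adjustment-set members by ordinary least squares.  Fitted values for
#' the trial rows are clipped into `(eps, 1 - eps)` so the implied odds
#' are always finite; the clip count is returned.
#'
#' @param trial,target population tables from [generate_populations()].
#' @param adj an [adjustment_set()] or character vector of member labels.
#' @param eps clipping bound for fitted probabilities.
#' @return object of class `sampling_fit`: `probabilities` (per trial
#'   row), `coefficients`, `n_clipped`.
#' @export
fit_sampling_probabilities <- function(trial, target, adj, eps = 1e-6) {
  members <- .members_of(adj)
  n0 <- nrow(trial)
  cols <- lapply(members, function(m) {
    if (is.null(trial[[m]]) || is.null(target[[m]]))
      stop("adjustment set member '", m, "' not present in both populations")
    c(trial[[m]], target[[m]])
  })
  names(cols) <- members
  cols[[".p"]] <- c(rep.int(0L, n0), rep.int(1L, nrow(target)))
  X <- .design(cols, members)
  co <- .ols_coef(X, cols[[".p"]])
  p <- drop(X[seq_len(n0), , drop = FALSE] %*% co)
  n_clipped <- sum(p <= eps | p >= 1 - eps)
  p <- pmin(1 - eps, pmax(eps, p))
  structure(list(probabilities = p, coefficients = co,
                 n_clipped = n_clipped),
            class = "sampling_fit")
}

#' Inverse odds weights from a sampling fit
#'
#' `w_i = p_i / (1 - p_i)`: the fitted odds of target membership given the
#' adjustment covariates, one weight per trial row.  Weights are finite
#' and positive because the fit clips its probabilities.
#'
#' @param fit a `sampling_fit` from [fit_sampling_probabilities()].
#' @return object of class `weight_vector` with fields `weights` and
#'   `normalization` (`"hajek-within-arm"`).
#' @export
inverse_odds_weights <- function(fit) {
  stopifnot(inherits(fit, "sampling_fit"))
  structure(list(weights = fit$probabilities / (1 - fit$probabilities),
                 normalization = "hajek-within-arm"),
            class = "weight_vector")
}

#' Hajek-normalize weights within treatment arms
#'
#' Divides each weight by the sum of weights in its treatment arm, so the
#' normalized weights sum to one within each arm.
#'
#' @param weights positive numeric vector.
#' @param x treatment indicator vector of the same length.
#' @return normalized weights.
#' @export
hajek_normalize <- function(weights, x) {
  stopifnot(length(weights) == length(x), all(weights > 0))
  out <- weights
  for (arm in unique(x)) {
    idx <- x == arm
    out[idx] <- weights[idx] / sum(weights[idx])
  }
  out
}

.contrast <- function(mu1, mu0, scale) {
  if (scale == "RD") return(mu1 - mu0)
  if (mu0 <= 0 || mu1 <= 0)
    estimate_failure("nonpositive standardized risk on the logRR scale")
  log(mu1 / mu0)
}

#' Inverse-odds-weighted transported effect
#'
#' Computes Hajek-weighted outcome means among the trial's treated and
#' untreated rows, with inverse odds weights from the linear probability
#' sampling model on the given adjustment set, and contrasts them on the
#' requested scale.
#'
#' @inheritParams fit_sampling_probabilities
#' @param scale `"RD"` or `"logRR"`.
#' @return the transported effect estimate (scalar).
#' @export
iow_estimate <- function(trial, target, adj, scale = c("RD", "logRR"),
                         eps = 1e-6) {
  scale <- match.arg(scale)
  x <- trial$X
  if (!all(x %in% c(0, 1))) stop("iow_estimate requires binary treatment")
  if (!any(x == 1) || !any(x == 0)) stop("empty treatment arm")
  fit <- fit_sampling_probabilities(trial, target, adj, eps)
  w <- inverse_odds_weights(fit)$weights
  y <- trial$Y
  i1 <- x == 1
  mu1 <- sum(w[i1] * y[i1]) / sum(w[i1])
  mu0 <- sum(w[!i1] * y[!i1]) / sum(w[!i1])
  .contrast(mu1, mu0, scale)
}

#' Transported per-unit effect of a continuous treatment via IOW
#'
#' Weighted least squares of the outcome on an intercept and the
#' continuous treatment among trial rows, with inverse odds weights;
#' returns the treatment coefficient (the transported effect per unit of
#' treatment).
#'
#' @inheritParams fit_sampling_probabilities
#' @return the estimated per-unit effect (scalar).
#' @export
iow_estimate_continuous <- function(trial, target, adj, eps = 1e-6) {
  x <- trial$X
  if (min(x) == max(x)) stop("degenerate treatment: no variance in X")
  fit <- fit_sampling_probabilities(trial, target, adj, eps)
  w <- inverse_odds_weights(fit)$weights
  X <- cbind(1, x)
  co <- .ols_coef(X, trial$Y, w)
  unname(co[2])
}

#' Outcome-model (G-computation) transported effect
#'
#' Fits, within each trial treatment arm, an ordinary least squares model
#' of the outcome on an intercept plus main effects of the adjustment-set
#' members (no interactions among members), predicts both potential
#' outcomes for every target row, and contrasts the target means on the
#' requested scale.
#'
#' @inheritParams iow_estimate
#' @return the transported effect estimate (scalar).
#' @export
outcome_model_estimate <- function(trial, target, adj,
                                   scale = c("RD", "logRR")) {
  scale <- match.arg(scale)
  members <- .members_of(adj)
  x <- trial$X
  if (!all(x %in% c(0, 1))) stop("binary treatment required")
  if (!any(x == 1) || !any(x == 0)) stop("empty treatment arm")
  mu <- numeric(2)
  for (arm in 0:1) {
    idx <- x == arm
    cols <- lapply(members, function(m) trial[[m]][idx])
    names(cols) <- members
    if (!length(cols)) cols <- list(.dummy = numeric(sum(idx)))
    Xd <- .design(cols, members)
    kept <- colnames(Xd)[-1]
    if (!length(kept)) {
      # intercept-only model: prediction is the arm mean, exactly
      mu[arm + 1L] <- mean(trial$Y[idx])
      next
    }
    co <- .ols_coef(Xd, trial$Y[idx])
    tcols <- lapply(kept, function(m) target[[m]])
    names(tcols) <- kept
    if (!length(tcols)) tcols <- list(.dummy = numeric(nrow(target)))
    Xt <- .design(tcols, kept)
    mu[arm + 1L] <- mean(drop(Xt %*% co[colnames(Xt)]))
  }
  .contrast(mu[2], mu[1], scale)
}

#' Outcome-model transported per-unit effect of a continuous treatment
#'
#' The continuous-treatment analogue of the stratified outcome model: a
#' single ordinary least squares fit of the outcome on the treatment, the
#' adjustment-set members, and treatment-by-member products (the products
#' supply the modification that stratification supplies for binary
#' treatment).  The transported effect is the target-population mean of
#' the fitted per-unit slope.
#'
#' @inheritParams iow_estimate_continuous
#' @return the estimated per-unit effect (scalar).
#' @export
outcome_model_estimate_continuous <- function(trial, target, adj) {
  members <- .members_of(adj)
  x <- trial$X
  if (min(x) == max(x)) stop("degenerate treatment: no variance in X")
  cols <- lapply(members, function(m) trial[[m]])
  names(cols) <- members
  cols[[".x"]] <- x
  Xd <- .design(cols, members)
  kept <- colnames(Xd)[-1]
  Xfull <- cbind(Xd, x, Xd[, kept, drop = FALSE] * x)
  colnames(Xfull) <- c(colnames(Xd), "X", paste0("X:", kept))
  co <- .ols_coef(Xfull, trial$Y)
  slope <- rep(co[["X"]], nrow(target))
  for (m in kept) slope <- slope + co[[paste0("X:", m)]] * target[[m]]
  mean(slope)
}

#' Crude (unadjusted) trial contrast
#'
#' Plain arm-mean contrast of the outcome in the trial, ignoring the
#' target population entirely.  Equals every transported estimate under
#' the empty adjustment set.
#'
#' @param trial trial population table.
#' @param scale `"RD"` or `"logRR"`.
#' @return the crude effect estimate (scalar).
#' @export
crude_estimate <- function(trial, scale = c("RD", "logRR")) {
  scale <- match.arg(scale)
  x <- trial$X
  if (!any(x == 1) || !any(x == 0)) stop("empty treatment arm")
  .contrast(mean(trial$Y[x == 1]), mean(trial$Y[x == 0]), scale)
}
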