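#' Per-state observed-vs-predicted summary
#'
#' Joins the per-state mean of non-missing valuations with model
#' predictions — the layout of the published comparison table. Design
#' states with no non-missing observation are dropped with a warning. If
#' full health is present its row is set to observed 1 / predicted 1 by
#' convention.
#'
#' @param study a \code{valuation_study}.
#' @param predictions a data frame with columns \code{state}, \code{mean}
#'   and optionally \code{sd} (as returned by [predict.npb_fit()]), or a
#'   [utility_posterior()].
#' @return Data frame of class \code{"prediction_summary"} with columns
#'   \code{state}, \code{observed_mean}, \code{n_obs},
#'   \code{predicted_mean}, \code{predicted_sd}.
#' @export
prediction_summary <- function(study, predictions) {
  if (inherits(predictions, "utility_posterior"))
    predictions <- data.frame(state = predictions$states,
                              mean = predictions$mean,
                              sd = sqrt(pmax(diag(predictions$cov), 0)))
  rec <- study$records[!study$records$missing, , drop = FALSE]
  obs <- tapply(rec$y, rec$state, mean)
  n_obs <- tapply(rec$y, rec$state, length)
  design <- unique(study$design_states)
  none <- setdiff(design, names(obs))
  if (length(none))
    warning(length(none), " design state(s) without observations dropped")
  states <- intersect(design, names(obs))
  missing_pred <- setdiff(states, predictions$state)
  if (length(missing_pred))
    stop("predictions do not cover design state(s): ",
         paste(utils::head(missing_pred, 3), collapse = ", "))
  pi <- match(states, predictions$state)
  out <- data.frame(state = states,
                    observed_mean = as.numeric(obs[states]),
                    n_obs = as.integer(n_obs[states]),
                    predicted_mean = predictions$mean[pi],
                    predicted_sd = if ("sd" %in% names(predictions))
                      predictions$sd[pi] else NA_real_,
                    row.names = NULL)
  fh <- out$state == "111111"
  out$observed_mean[fh] <- 1
  out$predicted_mean[fh] <- 1
  class(out) <- c("prediction_summary", "data.frame")
  out
}

summary_diffs <- function(summary, exclude_full_health = TRUE) {
  stopifnot(all(c("observed_mean", "predicted_mean") %in% names(summary)))
  keep <- if (exclude_full_health) summary$state != "111111" else
    rep(TRUE, nrow(summary))
  if (!any(keep)) stop("no rows left after exclusion")
  summary$observed_mean[keep] - summary$predicted_mean[keep]
}

#' Root mean square prediction error
#'
#' RMSE between observed per-state mean valuations and predicted utilities,
#' by convention over the valued states excluding full health (whose row is
#' exact by construction).
#'
#' @param summary a [prediction_summary()] (or any data frame with
#'   \code{state}, \code{observed_mean}, \code{predicted_mean}).
#' @param exclude_full_health drop the "111111" row (default TRUE).
#' @return RMSE (scalar).
#' @export
rmse <- function(summary, exclude_full_health = TRUE) {
  sqrt(mean(summary_diffs(summary, exclude_full_health)^2))
}

#' Mean prediction error
#'
#' Mean of observed minus predicted per-state values (positive = model
#' under-predicts). Always at least as small in magnitude as [rmse()].
#'
#' @inheritParams rmse
#' @return Mean error (scalar, signed).
#' @export
mean_error <- function(summary, exclude_full_health = TRUE) {
  mean(summary_diffs(summary, exclude_full_health))
}

#' Bland-Altman agreement statistics
#'
#' Mean bias, sample SD of the per-state differences, and the 95\% limits
#' of agreement (bias +/- 1.96 SD). The limits' length, 3.92 SD, is the
#' scalar the agreement plots summarize: narrower limits mean better
#' agreement between observed and model valuations.
#'
#' @inheritParams rmse
#' @return List of class \code{"bland_altman"}: \code{mean_bias},
#'   \code{sd_diff}, \code{loa_lower}, \code{loa_upper}, \code{loa_length},
#'   \code{n}.
#' @export
bland_altman <- function(summary, exclude_full_health = TRUE) {
  d <- summary_diffs(summary, exclude_full_health)
  if (length(d) < 2L) stop("need at least two differences")
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_bias = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 loa_length = 2 * 1.96 * s, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$n, "): bias ",
      signif(x$mean_bias, 4), ", SD ", signif(x$sd_diff, 4),
      ", 95% limits [", signif(x$loa_lower, 4), ", ",
      signif(x$loa_upper, 4), "] (length ", signif(x$loa_length, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Adjacent-pair monotonicity audit of a value set
#'
#' Samples \code{n_states} lattice states without replacement, picks one
#' neighbour of each uniformly at random (adjacent states always stand in a
#' dominance relation), and counts the pairs whose predicted utilities
#' conflict with dominance. With \code{ties = "nonmonotone"} (default) an
#' exact tie between a dominating and a dominated state counts as a
#' violation — a value set should strictly separate dominated states; set
#' \code{ties = "ok"} for the non-strict reading. The fraction is invariant
#' to strictly increasing transforms of the predictions.
#'
#' @param predict_fn vectorized function mapping a character vector of
#'   six-digit codes to predicted utilities.
#' @param spec an [sf6d_spec()].
#' @param n_states number of sampled states (and pairs).
#' @param seed optional seed.
#' @param ties tie handling, \code{"nonmonotone"} or \code{"ok"}.
#' @return Fraction of non-monotone pairs in [0, 1].
#' @export
monotonicity_audit <- function(predict_fn, spec = sf6d_spec(),
                               n_states = 10000, seed = NULL,
                               ties = c("nonmonotone", "ok")) {
  ties <- match.arg(ties)
  if (n_states > spec$n_states) stop("n_states exceeds the lattice size")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  states <- sample_states(spec, n_states)
  partner <- matrix(0L, n_states, 6)
  for (i in seq_len(n_states)) {
    nb <- neighbors(states[i, ], spec)
    partner[i, ] <- nb[sample.int(nrow(nb), 1L), ]
  }
  u1 <- predict_fn(state_code(states))
  u2 <- predict_fn(state_code(partner))
  # adjacent states differ in one dimension only: the one with the lower
  # level there dominates
  better_first <- rowSums(states) < rowSums(partner)
  ub <- ifelse(better_first, u1, u2)
  uw <- ifelse(better_first, u2, u1)
  bad <- if (ties == "nonmonotone") ub <= uw else ub < uw
  mean(bad)
}

#' Cost per quality-adjusted life year
#'
#' \code{cost / qaly_gain}, rounded to the nearest whole currency unit —
#' the arithmetic by which a utility difference between value sets
#' propagates to a funding decision.
#'
#' @param cost treatment cost (currency units).
#' @param qaly_gain QALY gain (> 0).
#' @return Cost per QALY, rounded.
#' @examples
#' cost_per_qaly(12000, 0.5)   # 24000
#' cost_per_qaly(12000, 0.61)  # 19672
#' @export
cost_per_qaly <- function(cost, qaly_gain) {
  if (any(qaly_gain <= 0)) stop("qaly_gain must be positive")
  round(cost / qaly_gain)
}
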