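#' @export
print.npb_fit <- function(x, ...) {
  cat("Nonparametric Bayesian valuation fit (", x$prior$mode, " prior)\n",
      sep = "")
  cat("  study:", x$study$name, "-", sum(!x$study$records$missing),
      "observed valuations,", length(x$states), "states (incl. full health)\n")
  cat("  chain:", x$control$iterations, "iterations, burn-in",
      x$control$burn_in, ", thin", x$control$thin, "->",
      nrow(x$draws$u), "draws\n")
  ar <- x$acceptance[!is.na(x$acceptance)]
  if (length(ar))
    cat("  acceptance:", paste(names(ar), round(ar, 2), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.npb_fit <- function(object, ...) {
  colMeans(object$draws$pars)
}

#' @export
summary.npb_fit <- function(object, prob = 0.95, ...) {
  q <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  pars <- object$draws$pars
  tab <- data.frame(mean = colMeans(pars),
                    sd = apply(pars, 2, stats::sd),
                    lower = apply(pars, 2, stats::quantile, q[1]),
                    upper = apply(pars, 2, stats::quantile, q[2]))
  pred <- predict(object)
  out <- list(parameters = tab, utilities = pred, prob = prob,
              acceptance = object$acceptance, study = object$study$name,
              mode = object$prior$mode)
  class(out) <- "summary.npb_fit"
  out
}

#' @export
print.summary.npb_fit <- function(x, ...) {
  cat("Hyperparameter posterior summaries (", x$prob * 100, "% intervals), ",
      x$mode, " fit of '", x$study, "':\n", sep = "")
  print(round(x$parameters, 4))
  cat("\nUtility posterior over", nrow(x$utilities), "design states:\n")
  print(utils::head(x$utilities, 5))
  if (nrow(x$utilities) > 5) cat("  ...\n")
  invisible(x)
}

# Per-draw values of u at arbitrary states. Design-state columns are the
# stored draws; off-design columns are per-draw conditional-normal means
# under the prior covariance (base + sigma^2 * kernel) given that draw's
# design-state values and hyperparameters, with the conditional covariance
# accumulated separately (law of total variance). The full-health anchor is
# automatic: it is a design state with every draw equal to 1.
joint_posterior_draws <- function(object, codes) {
  codes <- as.character(codes)
  U <- object$draws$u
  ndraw <- nrow(U)
  des <- object$states
  new <- setdiff(codes, des)
  M <- matrix(NA_real_, ndraw, length(codes), dimnames = list(NULL, codes))
  in_des <- intersect(codes, des)
  M[, in_des] <- U[, in_des, drop = FALSE]
  Vbar <- matrix(0, length(codes), length(codes),
                 dimnames = list(codes, codes))
  if (length(new)) {
    prior <- object$prior
    spec <- object$spec
    all_codes <- c(des, new)
    comp <- prior_components(all_codes, prior, spec)
    di <- seq_along(des)
    ni <- length(des) + seq_along(new)
    pars <- object$draws$pars
    th_names <- comp$par_names
    theta_draws <- as.matrix(pars[, th_names, drop = FALSE])
    sig_draws <- pars$sigma2
    b_sampled <- object$prior$estimate_b
    b_draws <- if (b_sampled)
      as.matrix(pars[, paste0("b", 1:6), drop = FALSE]) else NULL
    Cfull <- sg_correlation(comp$levels, comp$levels, prior$b, spec)
    Bd <- comp$base_cov[di, di, drop = FALSE]
    Bnd <- comp$base_cov[ni, di, drop = FALSE]
    Bnn <- comp$base_cov[ni, ni, drop = FALSE]
    pure_kernel <- prior$mode == "standalone"
    Vnew <- matrix(0, length(new), length(new))
    Mnew <- matrix(NA_real_, ndraw, length(new))
    A_fixed <- NULL
    for (t in seq_len(ndraw)) {
      if (b_sampled) {
        lv <- comp$levels
        Cfull <- sg_correlation(lv, lv, b_draws[t, ], spec)
      }
      Cdd <- Cfull[di, di, drop = FALSE]
      Cnd <- Cfull[ni, di, drop = FALSE]
      Cnn <- Cfull[ni, ni, drop = FALSE]
      s2 <- sig_draws[t]
      mu_all <- comp$base_mean + drop(comp$X %*% theta_draws[t, ])
      if (pure_kernel && !b_sampled) {
        # sigma^2 cancels in the kriging weights: compute A once
        if (is.null(A_fixed)) {
          Ch <- chol(Cdd + diag(1e-8, length(di)))
          A_fixed <- Cnd %*% chol2inv(Ch)
          Vk <- Cnn - A_fixed %*% t(Cnd)
          Vk <- (Vk + t(Vk)) / 2
        }
        A <- A_fixed
        Vt <- s2 * Vk
      } else {
        Sd <- Bd + s2 * Cdd
        Snd <- Bnd + s2 * Cnd
        Ch <- chol(Sd + diag(1e-8, length(di)))
        A <- Snd %*% chol2inv(Ch)
        Vt <- (Bnn + s2 * Cnn) - A %*% t(Snd)
        Vt <- (Vt + t(Vt)) / 2
      }
      Mnew[t, ] <- mu_all[ni] + drop(A %*% (U[t, des] - mu_all[di]))
      Vnew <- Vnew + Vt
    }
    M[, new] <- Mnew
    Vbar[new, new] <- Vnew / ndraw
  }
  list(M = M, Vbar = Vbar)
}

#' Posterior utilities at arbitrary health states
#'
#' For design states the posterior mean and SD are moments of the stored
#' draws. For any other lattice state the draws are extended by the
#' conditional-normal distribution of \eqn{u} under the prior covariance
#' given that draw's design-state values and hyperparameters; the reported
#' variance combines between-draw spread with the average conditional
#' variance. Full health always returns mean 1, SD 0.
#'
#' The reported utility is the posterior of \eqn{u(x)} itself, i.e. of the
#' population utility surface, not of the noisy respondent-level valuation.
#'
#' @param object an [npb_fit()].
#' @param states codes or level matrix (default: the fit's design states).
#' @param ... unused.
#' @return Data frame with \code{state}, \code{mean}, \code{sd}.
#' @export
predict.npb_fit <- function(object, states = NULL, ...) {
  if (is.null(states)) states <- object$states
  if (!is.character(states)) states <- state_code(states)
  parse_state(states, object$spec)  # validates against the lattice
  jp <- joint_posterior_draws(object, unique(states))
  mu <- colMeans(jp$M)
  v <- apply(jp$M, 2, stats::var) + diag(jp$Vbar)
  out <- data.frame(state = unique(states), mean = mu,
                    sd = sqrt(pmax(v, 0)), row.names = NULL)
  fh <- out$state == "111111"
  out$mean[fh] <- 1; out$sd[fh] <- 0
  out[match(states, out$state), , drop = FALSE]
}

#' Carry a fitted posterior forward as the next study's prior
#'
#' Summarizes the fit as a [utility_posterior()] — the per-state posterior
#' mean vector and full covariance matrix across draws (off-design states
#' included via conditional-normal extension, with the average conditional
#' covariance added to the between-draw covariance). This object is exactly
#' what [npb_prior()] consumes as \code{base}, so sequential multi-country
#' analyses are iterated applications of this function. Covariances
#' estimated from draws can be slightly indefinite; negative eigenvalues are
#' clipped to zero (with a warning reporting the clipped mass).
#'
#' @param fit an [npb_fit()].
#' @param states codes to carry forward (default: the fit's design states).
#' @param label label for the resulting posterior.
#' @return A [utility_posterior()].
#' @export
posterior_as_prior <- function(fit, states = NULL, label = NULL) {
  stopifnot(inherits(fit, "npb_fit"))
  if (nrow(fit$draws$u) < 2L) stop("need at least two retained draws")
  if (is.null(states)) states <- fit$states
  if (!is.character(states)) states <- state_code(states)
  states <- unique(states)
  jp <- joint_posterior_draws(fit, states)
  mu <- colMeans(jp$M)
  S <- stats::cov(jp$M) + jp$Vbar
  fh <- match("111111", states)
  if (!is.na(fh)) {
    mu[fh] <- 1
    S[fh, ] <- 0; S[, fh] <- 0
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ev$values) < 0) {
    clipped <- sum(pmin(ev$values, 0))
    if (clipped < -1e-8 * max(ev$values))
      warning("PSD repair clipped eigenvalue mass ", signif(-clipped, 3))
    S <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    S <- (S + t(S)) / 2
  }
  utility_posterior(states, mu, S,
                    label = label %||% paste0(fit$study$name, "_posterior"),
                    provenance = list(mode = fit$prior$mode,
                                      seed = fit$seed,
                                      draws = nrow(fit$draws$u)))
}

#' Residuals of a valuation fit
#'
#' \code{type = "state"}: per-design-state observed mean minus posterior
#' mean utility. \code{type = "record"}: per-record residual
#' \eqn{y_{ij} - [1 - \hat\alpha_j\{1 - \hat u(x_{ij})\}]} using posterior
#' means (requires \code{store_alpha = TRUE} in the control; otherwise
#' \eqn{\hat\alpha_j} is replaced by the posterior-mean population effect).
#'
#' @param object an [npb_fit()].
#' @param type "state" or "record".
#' @param ... unused.
#' @export
residuals.npb_fit <- function(object, type = c("state", "record"), ...) {
  type <- match.arg(type)
  rec <- object$study$records[!object$study$records$missing, , drop = FALSE]
  u_hat <- colMeans(object$draws$u)
  if (type == "state") {
    obs <- tapply(rec$y, rec$state, mean)
    common <- intersect(names(obs), names(u_hat))
    return(obs[common] - u_hat[common])
  }
  if (!is.null(object$draws$alpha)) {
    a_hat <- colMeans(object$draws$alpha)
  } else {
    ga <- colMeans(object$draws$pars)
    Tm <- respondent_covariates(object$study$respondents)
    gcols <- grep("^gamma_alpha_", colnames(object$draws$pars))
    a_hat <- exp(drop(Tm %*% colMeans(object$draws$pars)[gcols]))
  }
  ri <- match(rec$respondent, object$study$respondents$id)
  rec$y - (1 - a_hat[ri] * (1 - u_hat[rec$state]))
}

#' Diagnostic plots for a valuation fit
#'
#' \code{type = "fit"}: observed per-state means against posterior means
#' with a 45-degree reference line. \code{type = "bland_altman"}:
#' differences against averages with the mean bias and 95\% limits of
#' agreement. \code{type = "trace"}: hyperparameter trace plots.
#'
#' @param x an [npb_fit()].
#' @param type plot flavour.
#' @param ... passed to the underlying plotting call.
#' @export
plot.npb_fit <- function(x, type = c("fit", "bland_altman", "trace"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    pars <- x$draws$pars[, c("sigma2", "tau2", "upsilon2")]
    op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
    on.exit(graphics::par(op))
    for (nm in names(pars))
      graphics::plot(pars[[nm]], type = "l", ylab = nm, xlab = "")
    return(invisible(x))
  }
  ps <- prediction_summary(x$study, predict(x))
  if (type == "fit") {
    graphics::plot(ps$predicted_mean, ps$observed_mean,
                   xlab = "posterior mean utility",
                   ylab = "observed mean valuation", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    d <- ps$observed_mean - ps$predicted_mean
    avg <- (ps$observed_mean + ps$predicted_mean) / 2
    graphics::plot(avg, d, xlab = "average of observed and predicted",
                   ylab = "observed - predicted", ...)
    graphics::abline(h = mean(d))
    graphics::abline(h = mean(d) + c(-1.96, 1.96) * stats::sd(d), lty = 3)
  }
  invisible(x)
}

#' Simulate replicate studies from a fitted model
#'
#' Parametric posterior-predictive replication: each simulated study reuses
#' the fitted study's design (states per respondent, missing count) with the
#' posterior-mean utility surface and hyperparameters.
#'
#' @param object an [npb_fit()].
#' @param nsim number of replicate studies.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of \code{valuation_study} objects.
#' @export
simulate.npb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ce <- coef(object)
  u_hat <- colMeans(object$draws$u)
  truth <- structure(list(values = u_hat, spec = object$spec,
                          decrements = NULL, perturbation_scale = NA,
                          perturbation = NULL, floor = -1, seed = seed),
                     class = "true_utility")
  k <- sum(!object$study$records$missing[
    object$study$records$respondent == object$study$respondents$id[1]])
  k <- max(1L, round(nrow(object$study$records) /
                       nrow(object$study$respondents)))
  gcols <- grep("^gamma_alpha_", names(ce))
  lapply(seq_len(nsim), function(i) {
    rs <- if (is.null(seed)) NULL else seed + i - 1L
    resp <- simulate_respondents(nrow(object$study$respondents),
                                 gamma_alpha = unname(ce[gcols][1]),
                                 tau2 = unname(ce["tau2"]), seed = rs)
    simulate_study(truth, resp, setdiff(object$states, "111111"), k,
                   upsilon2 = unname(ce["upsilon2"]),
                   n_missing = sum(object$study$records$missing),
                   seed = if (is.null(rs)) NULL else rs + 10000L,
                   name = paste0(object$study$name, "_rep", i))
  })
}
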