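#' Lattice correlation function
#'
#' Squared-exponential correlation on the level lattice,
#' \deqn{c(x, x') = \exp\{-\sum_d b_d (x_d - x'_d)^2\},}
#' where \eqn{b_d \ge 0} is a roughness parameter for dimension \eqn{d}:
#' larger \eqn{b_d} lets the utility surface deviate faster from linearity in
#' that dimension. With all \eqn{b_d > 0} the correlation is 1 exactly when
#' the states coincide.
#'
#' @param x,x2 states as level matrices (rows) or six-digit codes.
#' @param b nonnegative roughness vector of length 6.
#' @param spec an [sf6d_spec()].
#' @return Matrix of correlations, \code{nrow(x)} by \code{nrow(x2)}.
#' @examples
#' sg_correlation("111111", "211111", b = c(log(2), 0, 0, 0, 0, 0))  # 0.5
#' @export
sg_correlation <- function(x, x2 = x, b = rep(0.1, 6), spec = sf6d_spec()) {
  if (any(b < 0)) stop("roughness parameters b must be nonnegative")
  if (is.character(x)) x <- parse_state(x, spec)
  if (is.character(x2)) x2 <- parse_state(x2, spec)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(dim(x2))) x2 <- matrix(x2, nrow = 1L)
  d2 <- matrix(0, nrow(x), nrow(x2))
  for (d in 1:6)
    d2 <- d2 + b[d] * outer(x[, d], x2[, d], function(a, bb) (a - bb)^2)
  exp(-d2)
}

#' Posterior (or prior) utility distribution over a set of states
#'
#' The object passed between countries: per-state posterior means
#' \eqn{E(u(x))} and the full covariance matrix
#' \eqn{cov(u(x), u(x'))}. Used both as a fit's summarized posterior and as
#' the informative prior ("posterior as prior") for the next study.
#'
#' @param states character vector of six-digit codes.
#' @param mean numeric vector of posterior means, same length.
#' @param cov symmetric positive-semidefinite covariance matrix.
#' @param label country / provenance label.
#' @param provenance free-form list recording how the object was produced.
#' @return An object of class \code{"utility_posterior"}.
#' @export
utility_posterior <- function(states, mean, cov, label = "unknown",
                              provenance = list()) {
  states <- as.character(states)
  n <- length(states)
  if (length(mean) != n || !all(dim(cov) == c(n, n)))
    stop("states, mean and cov dimensions disagree")
  if (max(abs(cov - t(cov))) > 1e-6 * max(1, max(abs(cov))))
    stop("covariance matrix is not symmetric")
  cov <- (cov + t(cov)) / 2
  ev_min <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6)
    stop("covariance matrix is not positive semi-definite (min eigenvalue ",
         signif(ev_min, 3), ")")
  fh <- match("111111", states)
  if (!is.na(fh) && (abs(mean[fh] - 1) > 1e-6 || cov[fh, fh] > 1e-6))
    warning("full health is present but not anchored at mean 1, variance 0")
  structure(list(states = states, mean = as.numeric(mean), cov = cov,
                 label = label, provenance = provenance),
            class = "utility_posterior")
}

#' @export
print.utility_posterior <- function(x, ...) {
  cat("Utility posterior [", x$label, "]: ", length(x$states), " states, ",
      "mean range [", round(min(x$mean), 3), ", ", round(max(x$mean), 3),
      "], median SD ", signif(stats::median(sqrt(pmax(diag(x$cov), 0))), 3),
      "\n", sep = "")
  invisible(x)
}

#' Prior specification for the utility model
#'
#' In standalone mode the prior over utilities at the design states is a
#' Gaussian process with mean \eqn{1 + \beta'(x - 1)} and covariance
#' \eqn{\sigma^2 c(x, x')}. In transfer mode (when \code{base} is supplied) a
#' previous country's posterior enters additively: mean
#' \eqn{E(u_{base}(x)) + \gamma_0 + \beta'(x - 1)} and covariance
#' \eqn{cov(u_{base}(x), u_{base}(x')) + \sigma^2 c(x, x')}. Either way the
#' prior is conditioned exactly on \eqn{u(111111) = 1}, so full health is
#' anchored; levels are centred as (level - 1) so the linear term vanishes at
#' full health. \eqn{\gamma_0}, \eqn{\beta} and \eqn{\sigma^2} are estimated;
#' the roughness \eqn{b} is fixed by default (sampling it is optional).
#'
#' Hyperpriors (weakly informative on the [-1, 1] utility scale):
#' \eqn{\gamma_0 \sim N(0,1)}, \eqn{\beta_d \sim N(0,1)},
#' \eqn{\log\sigma^2 \sim N(-4, 1.5^2)}, \eqn{\tau^2, \upsilon^2 \sim}
#' Inverse-Gamma(2, 0.05), \eqn{\gamma_\alpha \sim N(0, I)} for covariate
#' coefficients with the intercept shrunk as \eqn{N(0, 0.05^2)}, and, when
#' sampled, \eqn{\log b_d \sim N(\log 0.1, 0.5^2)}. The tight intercept
#' prior centres the median respondent effect at 1: the likelihood is
#' invariant under jointly rescaling \eqn{1 - u} and \eqn{1/\alpha}, and the
#' full-health anchor plus this centring are what pin the utility scale
#' down.
#'
#' @param base optional [utility_posterior()] to transfer from.
#' @param b roughness vector (default 0.1 in every dimension).
#' @param estimate_b logical; sample log b by random-walk Metropolis instead
#'   of fixing it.
#' @param hyper named list overriding individual hyperprior settings
#'   (\code{gamma0_sd}, \code{beta_sd}, \code{log_sigma2_mean},
#'   \code{log_sigma2_sd}, \code{tau2_shape}, \code{tau2_rate},
#'   \code{ups2_shape}, \code{ups2_rate}, \code{gamma_alpha_sd},
#'   \code{log_b_sd}).
#' @return An object of class \code{"npb_prior"}.
#' @export
npb_prior <- function(base = NULL, b = rep(0.1, 6), estimate_b = FALSE,
                      hyper = list()) {
  if (!is.null(base) && !inherits(base, "utility_posterior"))
    stop("base must be a utility_posterior (or NULL for standalone mode)")
  if (length(b) != 6 || any(b < 0)) stop("b must be six nonnegative reals")
  h <- list(gamma0_sd = 1, beta_sd = 1, log_sigma2_mean = -4,
            log_sigma2_sd = 1.5, tau2_shape = 2, tau2_rate = 0.05,
            ups2_shape = 2, ups2_rate = 0.05, gamma_alpha_sd = 1,
            gamma_alpha_int_sd = 0.05, log_b_mean = log(0.1), log_b_sd = 0.5)
  h[names(hyper)] <- hyper
  structure(list(mode = if (is.null(base)) "standalone" else "transfer",
                 base = base, b = as.numeric(b), estimate_b = estimate_b,
                 hyper = h),
            class = "npb_prior")
}

#' @export
print.npb_prior <- function(x, ...) {
  cat("npb_prior:", x$mode, "mode",
      if (x$mode == "transfer") paste0("(base: ", x$base$label, ")"), "\n")
  cat("  roughness b:", paste(signif(x$b, 3), collapse = " "),
      if (x$estimate_b) "(sampled)" else "(fixed)", "\n")
  invisible(x)
}

# Conditional-normal extension of a stored posterior to states it does not
# cover. The base posterior pins down (mean, cov) at its own states; new
# states are attached through the lattice kernel: kriging weights
# A = C_nb C_bb^{-1} (universal kriging about a linear-in-levels trend fitted
# to the base mean), new mean = trend + A * (base residual), joint covariance
# [[S, S A'], [A S, A S A' + V]] with V the kernel's conditional covariance
# scaled by the average base variance. The construction is a linear map plus
# independent noise, hence PSD by design.
extend_posterior <- function(base, new_codes, b, spec = sf6d_spec()) {
  keep <- setdiff(new_codes, base$states)
  Xb <- cbind(1, parse_state(base$states, spec) - 1)
  if (length(keep) == 0L) {
    return(list(states = base$states, mean = base$mean, cov = base$cov))
  }
  Xn <- cbind(1, parse_state(keep, spec) - 1)
  theta <- qr.coef(qr(Xb), base$mean)
  theta[is.na(theta)] <- 0
  Cbb <- sg_correlation(base$states, base$states, b, spec)
  diag(Cbb) <- diag(Cbb) + 1e-8
  Cnb <- sg_correlation(keep, base$states, b, spec)
  A <- Cnb %*% solve(Cbb)
  resid <- base$mean - drop(Xb %*% theta)
  m_new <- drop(Xn %*% theta) + drop(A %*% resid)
  # kriging variance scale: average posterior variance plus the spread of
  # the base mean about its trend — at states far from the base design the
  # extension knows only the trend, and must say so
  s2bar <- mean(pmax(diag(base$cov), 0)) + stats::var(resid)
  Cnn <- sg_correlation(keep, keep, b, spec)
  V <- s2bar * (Cnn - A %*% t(Cnb))
  V <- (V + t(V)) / 2
  ASA <- A %*% base$cov %*% t(A)
  cov_nn <- (ASA + t(ASA)) / 2 + V
  ev <- eigen(cov_nn, symmetric = TRUE)
  cov_nn <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  list(states = c(base$states, keep),
       mean = c(base$mean, m_new),
       cov = rbind(cbind(base$cov, base$cov %*% t(A)),
                   cbind(A %*% base$cov, cov_nn)))
}

# Assemble the pieces from which prior moments at `codes` are affine in the
# unknown trend parameters theta and linear in sigma^2:
#   mean(theta)  = base_mean + X theta
#   cov(sigma2)  = base_cov + sigma2 * C(b)
# Standalone: base_mean = 1, base_cov = 0, X = centred levels (beta only).
# Transfer: base moments come from the stored posterior (extended to any
# missing states), X gains an intercept column for gamma0.
prior_components <- function(codes, prior, spec = sf6d_spec()) {
  codes <- as.character(codes)
  lev <- parse_state(codes, spec)
  Xc <- lev - 1
  n <- length(codes)
  if (prior$mode == "standalone") {
    base_mean <- rep(1, n)
    base_cov <- matrix(0, n, n)
    X <- Xc
    par_names <- paste0("beta", 1:6)
  } else {
    ext <- extend_posterior(prior$base, codes, prior$b, spec)
    idx <- match(codes, ext$states)
    base_mean <- ext$mean[idx]
    base_cov <- ext$cov[idx, idx, drop = FALSE]
    X <- cbind(1, Xc)
    par_names <- c("gamma0", paste0("beta", 1:6))
  }
  list(codes = codes, levels = lev, base_mean = base_mean,
       base_cov = base_cov, X = X, par_names = par_names,
       fh = match("111111", codes))
}

# Correlation matrix for the prior's own covariance component.
prior_corr <- function(comp, b, spec = sf6d_spec()) {
  C <- sg_correlation(comp$levels, comp$levels, b, spec)
  diag(C) <- diag(C) + 1e-8
  C
}

#' Build the multivariate-normal prior over a set of design states
#'
#' Evaluates the prior mean vector and covariance matrix at the supplied
#' states for given values of the trend offset \eqn{\gamma_0}, linear
#' coefficients \eqn{\beta} and innovation scale \eqn{\sigma^2}, then
#' conditions exactly on \eqn{u(111111) = 1} (full health is appended if it
#' is not among the states). Mainly a building block for [npb_fit()], but
#' exported because the assembled moments are checkable against hand
#' calculations.
#'
#' @param states six-digit codes (or level matrix).
#' @param prior an [npb_prior()].
#' @param gamma0,beta,sigma2 trend and scale parameter values at which to
#'   evaluate the prior (\code{gamma0} is ignored in standalone mode).
#' @param anchor condition on full health = 1 (default TRUE).
#' @param spec an [sf6d_spec()].
#' @return List with \code{states}, \code{mean}, \code{cov}; when
#'   \code{anchor} is TRUE the full-health entry has mean 1 and variance 0.
#' @export
build_prior <- function(states, prior, gamma0 = 0, beta = rep(0, 6),
                        sigma2 = exp(-3), anchor = TRUE,
                        spec = sf6d_spec()) {
  if (!is.character(states)) states <- state_code(states)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  codes <- unique(c("111111", as.character(states)))
  comp <- prior_components(codes, prior, spec)
  C <- prior_corr(comp, prior$b, spec)
  theta <- if (prior$mode == "transfer") c(gamma0, beta) else beta
  m <- comp$base_mean + drop(comp$X %*% theta)
  S <- comp$base_cov + sigma2 * C
  if (anchor) {
    f <- comp$fh
    k <- S[-f, f] / S[f, f]
    m_a <- m[-f] + k * (1 - m[f])
    S_a <- S[-f, -f] - outer(k, S[f, -f])
    S_a <- (S_a + t(S_a)) / 2
    full_m <- numeric(length(codes)); full_S <- matrix(0, length(codes),
                                                       length(codes))
    full_m[f] <- 1
    full_m[-f] <- m_a
    full_S[-f, -f] <- S_a
    m <- full_m; S <- full_S
  }
  idx <- match(as.character(states), codes)
  list(states = as.character(states), mean = m[idx],
       cov = S[idx, idx, drop = FALSE])
}

#' Read a published per-state posterior as a transferable prior
#'
#' Turns one model's columns of the packaged comparison table (see
#' [load_table1()]) into a [utility_posterior()]: means are taken as printed
#' and the covariance is reconstructed as \eqn{D R D} where \eqn{D} is the
#' diagonal of printed SDs and \eqn{R} the lattice correlation with the
#' supplied roughness. The table prints no cross-state covariances, so this
#' correlation fill is an explicit approximation to the original posterior.
#'
#' @param which \code{"UK"}, \code{"HK"} or \code{"HKUK"}: which model's
#'   mean/SD columns to use.
#' @param b roughness vector for the correlation fill.
#' @param table the loaded table (defaults to the packaged fixture).
#' @param spec an [sf6d_spec()].
#' @return A [utility_posterior()] over the table's 198 states.
#' @export
table1_prior <- function(which = c("UK", "HK", "HKUK"), b = rep(0.1, 6),
                         table = load_table1(), spec = sf6d_spec()) {
  which <- match.arg(which)
  cols <- switch(which, UK = c("uk_mean", "uk_sd"),
                 HK = c("hk_mean", "hk_sd"),
                 HKUK = c("hkuk_mean", "hkuk_sd"))
  if (!all(cols %in% names(table))) stop("table lacks columns for ", which)
  sds <- table[[cols[2]]]
  if (anyNA(sds)) stop("missing SD in table for model ", which)
  R <- sg_correlation(table$state, table$state, b, spec)
  cov <- outer(sds, sds) * R
  utility_posterior(table$state, table[[cols[1]]], cov, label = which,
                    provenance = list(source = "published comparison table",
                                      correlation_fill_b = b))
}
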