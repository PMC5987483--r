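#' MCMC configuration for [npb_fit()]
#'
#' @param iterations total Metropolis-within-Gibbs iterations.
#' @param burn_in iterations discarded (must be < iterations).
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param adapt tune random-walk proposal scales during burn-in towards
#'   20--40\% acceptance.
#' @param fix named list of parameters to hold fixed instead of sampling:
#'   \code{alpha} (scalar or per-respondent vector), \code{gamma_alpha},
#'   \code{tau2}, \code{upsilon2}, \code{sigma2}, \code{trend} (the
#'   \eqn{\gamma_0}/\eqn{\beta} vector in prior-component order).
#' @param init named list of starting values (same names, plus \code{u}).
#' @param prop initial random-walk scales: \code{alpha}, \code{sigma2},
#'   \code{b} (log scale).
#' @param store_alpha keep per-respondent \eqn{\alpha_j} draws (memory-heavy
#'   for large studies).
#' @return List of class \code{"npb_control"}.
#' @export
npb_control <- function(iterations = 20000, burn_in = 5000, thin = 5,
                        adapt = TRUE, fix = list(), init = list(),
                        prop = list(), store_alpha = FALSE) {
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  p <- list(alpha = 0.25, sigma2 = 0.5, b = 0.25)
  p[names(prop)] <- prop
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 adapt = adapt, fix = fix, init = init, prop = p,
                 store_alpha = store_alpha),
            class = "npb_control")
}

#' Hierarchical log likelihood of a valuation study
#'
#' The measurement model contribution
#' \eqn{\sum_{ij} \log N(y_{ij};\, 1 - \alpha_j\{1 - u(x_{ij})\},
#' \upsilon^2)} over non-missing records, plus the respondent-effect
#' contribution \eqn{\sum_j \log LN(\alpha_j;\, t_j'\gamma_\alpha, \tau^2)}.
#'
#' @param study a \code{valuation_study}.
#' @param u named numeric vector of utilities covering every state with
#'   non-missing records.
#' @param params list with \code{alpha} (per-respondent, aligned with
#'   \code{study$respondents}), \code{gamma_alpha}, \code{tau2},
#'   \code{upsilon2}.
#' @return Log-likelihood (scalar).
#' @export
npb_loglik <- function(study, u, params) {
  rec <- study$records[!study$records$missing, , drop = FALSE]
  if (!all(rec$state %in% names(u)))
    stop("u must supply a value for every observed state")
  ri <- match(rec$respondent, study$respondents$id)
  alpha <- rep_len(params$alpha, nrow(study$respondents))
  mu <- 1 - alpha[ri] * (1 - u[rec$state])
  ll <- sum(stats::dnorm(rec$y, mu, sqrt(params$upsilon2), log = TRUE))
  Tm <- respondent_covariates(study$respondents)
  ll + sum(stats::dlnorm(alpha, drop(Tm %*% params$gamma_alpha),
                         sqrt(params$tau2), log = TRUE))
}

# covariate design matrix t_j: intercept plus whichever of age_c / sex the
# respondent table carries
respondent_covariates <- function(respondents) {
  extra <- intersect(c("age_c", "sex"), names(respondents))
  Tm <- cbind(intercept = rep(1, nrow(respondents)))
  for (v in extra) Tm <- cbind(Tm, respondents[[v]])
  colnames(Tm) <- c("intercept", extra)
  Tm
}

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1, shape, rate = rate)

# grouped sum with zeros for empty groups
group_sum <- function(x, g, ngroups) {
  out <- numeric(ngroups)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit the nonparametric Bayesian valuation model
#'
#' Metropolis-within-Gibbs sampler for the hierarchical model
#' \deqn{y_{ij} = 1 - \alpha_j\{1 - u(x_{ij})\} + \varepsilon_{ij}}
#' with \eqn{\alpha_j \sim LN(t_j'\gamma_\alpha, \tau^2)},
#' \eqn{\varepsilon_{ij} \sim N(0, \upsilon^2)}, and a Gaussian-process
#' prior on \eqn{u} over the design states ([npb_prior()]; standalone or
#' with a previous country's posterior as prior). Update blocks:
#' \itemize{
#' \item \eqn{u} at design states by its exact multivariate-normal full
#'   conditional (the likelihood is linear-Gaussian in \eqn{u} given
#'   \eqn{\alpha}), with \eqn{u(111111) = 1} imposed by exact conditioning;
#' \item \eqn{\log\alpha_j} by vectorized random-walk Metropolis;
#' \item \eqn{\gamma_\alpha}, \eqn{\tau^2}, \eqn{\upsilon^2} and the trend
#'   \eqn{(\gamma_0, \beta)} by conjugate draws;
#' \item \eqn{\log\sigma^2} (and optionally \eqn{\log b_d}) by random-walk
#'   Metropolis.
#' }
#' Identifiability of the multiplicative \eqn{\alpha} scale against the
#' \eqn{u} scale comes from anchoring \eqn{u} at full health together with
#' the \eqn{\gamma_\alpha} prior centring the median of \eqn{\alpha} at 1.
#' Missing records are dropped before fitting.
#'
#' @param study a \code{valuation_study} (see [simulate_study()] or
#'   [read_study()]).
#' @param prior an [npb_prior()].
#' @param control an [npb_control()].
#' @param seed integer seed for the chain.
#' @param spec an [sf6d_spec()].
#' @return Object of class \code{"npb_fit"} with elements \code{draws}
#'   (\code{u}: draws by states matrix; \code{pars}: hyperparameter draws;
#'   optionally \code{alpha}), \code{states}, \code{acceptance},
#'   \code{prior}, \code{control}, \code{study}, \code{seed}.
#' @export
npb_fit <- function(study, prior = npb_prior(), control = npb_control(),
                    seed = 1, spec = sf6d_spec()) {
  stopifnot(inherits(study, "valuation_study"))
  rec <- study$records[!study$records$missing, , drop = FALSE]
  if (nrow(rec) == 0L) stop("study has no observed records")
  codes <- unique(c("111111", sort(unique(rec$state))))
  if (length(codes) < 3L) stop("need at least two valued design states")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)

  comp <- prior_components(codes, prior, spec)
  h <- prior$hyper
  n <- length(codes)
  f <- comp$fh                      # == 1L by construction
  si <- match(rec$state, codes)
  ri <- match(rec$respondent, study$respondents$id)
  J <- nrow(study$respondents)
  N <- nrow(rec)
  y <- rec$y
  Tm <- respondent_covariates(study$respondents)
  p_cov <- ncol(Tm)
  fx <- control$fix

  # --- state ----------------------------------------------------------
  b_cur <- prior$b
  C <- prior_corr(comp, b_cur, spec)
  sigma2 <- if (!is.null(fx$sigma2)) fx$sigma2 else
    control$init$sigma2 %||% exp(h$log_sigma2_mean)
  theta_dim <- ncol(comp$X)
  trend <- if (!is.null(fx$trend)) rep_len(fx$trend, theta_dim) else
    rep_len(control$init$trend %||% 0, theta_dim)
  trend_sd <- if (prior$mode == "transfer")
    c(h$gamma0_sd, rep(h$beta_sd, 6)) else rep(h$beta_sd, 6)
  la <- log(rep_len(fx$alpha %||% control$init$alpha %||% 1, J))
  gamma_alpha <- rep_len(fx$gamma_alpha %||% control$init$gamma_alpha %||% 0,
                         p_cov)
  tau2 <- fx$tau2 %||% control$init$tau2 %||% 0.04
  upsilon2 <- fx$upsilon2 %||% control$init$upsilon2 %||% 0.01
  obs_mean <- group_sum(y, si, n) / pmax(group_sum(rep(1, N), si, n), 1)
  u_r <- control$init$u %||% pmin(pmax(obs_mean[-f], -0.99), 0.995)
  u_r[group_sum(rep(1, N), si, n)[-f] == 0] <-
    comp$base_mean[-f][group_sum(rep(1, N), si, n)[-f] == 0]

  # anchored prior pieces for the current (sigma2, b); recomputed on accept
  anchored <- function(sigma2, Cmat) {
    S <- comp$base_cov + sigma2 * Cmat
    k <- S[-f, f] / S[f, f]
    Sr <- S[-f, -f] - outer(k, S[f, -f])
    Sr <- (Sr + t(Sr)) / 2
    ch <- tryCatch(chol(Sr), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(k = k, Sr = Sr, chol = ch, P = chol2inv(ch),
         logdet = 2 * sum(log(diag(ch))),
         a = comp$base_mean[-f] + k * (1 - comp$base_mean[f]),
         W = comp$X[-f, , drop = FALSE] - outer(k, comp$X[f, ]))
  }
  anc <- anchored(sigma2, C)
  if (is.null(anc))
    stop("Cholesky failure for the anchored prior covariance at ",
         "initialization (matrix base_cov + sigma2*C)")
  prior_quad <- function(anc, u_r, trend) {
    d <- u_r - (anc$a + drop(anc$W %*% trend))
    -0.5 * anc$logdet - 0.5 * sum(d * (anc$P %*% d))
  }

  s_alpha <- control$prop$alpha
  s_sig <- control$prop$sigma2
  s_b <- control$prop$b
  acc <- c(alpha = 0, sigma2 = 0, b = 0)
  att <- c(alpha = 0, sigma2 = 0, b = 0)
  win_acc <- c(alpha = 0, sigma2 = 0, b = 0)
  win_att <- c(alpha = 0, sigma2 = 0, b = 0)

  keep <- seq(control$burn_in + control$thin, control$iterations,
              by = control$thin)
  ndraw <- length(keep)
  u_store <- matrix(NA_real_, ndraw, n, dimnames = list(NULL, codes))
  par_names <- c(comp$par_names, "sigma2", "tau2", "upsilon2",
                 paste0("gamma_alpha_", colnames(Tm)))
  if (prior$estimate_b) par_names <- c(par_names, paste0("b", 1:6))
  pars_store <- matrix(NA_real_, ndraw, length(par_names),
                       dimnames = list(NULL, par_names))
  alpha_store <- if (control$store_alpha)
    matrix(NA_real_, ndraw, J) else NULL
  kpos <- 1L

  for (it in seq_len(control$iterations)) {
    alpha <- exp(la)
    arec <- alpha[ri]

    ## u | rest: Gaussian full conditional on the anchored scale
    m_pr <- anc$a + drop(anc$W %*% trend)
    A_s <- group_sum(arec^2, si, n)[-f]
    b_s <- group_sum(arec * (y - 1 + arec), si, n)[-f]
    Q <- anc$P
    diag(Q) <- diag(Q) + A_s / upsilon2
    rhs <- drop(anc$P %*% m_pr) + b_s / upsilon2
    Lq <- chol(Q)
    mu_u <- backsolve(Lq, backsolve(Lq, rhs, transpose = TRUE))
    u_r <- mu_u + backsolve(Lq, stats::rnorm(n - 1L))
    u_all <- c(1, u_r)
    one_minus_u <- 1 - u_all[si]

    ## alpha_j | rest: vectorized RW Metropolis on the log scale
    if (is.null(fx$alpha)) {
      la_prop <- la + s_alpha * stats::rnorm(J)
      ll_cur <- -group_sum((y - 1 + arec * one_minus_u)^2, ri, J) /
        (2 * upsilon2)
      ll_prop <- -group_sum((y - 1 + exp(la_prop)[ri] * one_minus_u)^2,
                            ri, J) / (2 * upsilon2)
      pr_mu <- drop(Tm %*% gamma_alpha)
      lr <- (ll_prop - ll_cur) +
        stats::dnorm(la_prop, pr_mu, sqrt(tau2), log = TRUE) -
        stats::dnorm(la, pr_mu, sqrt(tau2), log = TRUE)
      ok <- log(stats::runif(J)) < lr
      la[ok] <- la_prop[ok]
      alpha <- exp(la); arec <- alpha[ri]
      att["alpha"] <- att["alpha"] + 1
      acc["alpha"] <- acc["alpha"] + mean(ok)
      win_att["alpha"] <- win_att["alpha"] + 1
      win_acc["alpha"] <- win_acc["alpha"] + mean(ok)
    }

    ## gamma_alpha | rest (conjugate normal)
    if (is.null(fx$gamma_alpha)) {
      ga_sd <- c(h$gamma_alpha_int_sd, rep(h$gamma_alpha_sd, p_cov - 1L))
      Vinv <- crossprod(Tm) / tau2 + diag(1 / ga_sd^2, p_cov)
      Lv <- chol(Vinv)
      mg <- backsolve(Lv, backsolve(Lv, drop(crossprod(Tm, la)) / tau2,
                                    transpose = TRUE))
      gamma_alpha <- mg + backsolve(Lv, stats::rnorm(p_cov))
    }

    ## tau2 | rest (conjugate inverse gamma)
    if (is.null(fx$tau2)) {
      rss_a <- sum((la - drop(Tm %*% gamma_alpha))^2)
      tau2 <- rinvgamma1(h$tau2_shape + J / 2, h$tau2_rate + rss_a / 2)
    }

    ## upsilon2 | rest (conjugate inverse gamma)
    resid <- y - (1 - arec * one_minus_u)
    if (is.null(fx$upsilon2))
      upsilon2 <- rinvgamma1(h$ups2_shape + N / 2,
                             h$ups2_rate + sum(resid^2) / 2)

    ## trend (gamma0, beta) | rest (conjugate normal)
    if (is.null(fx$trend)) {
      PW <- anc$P %*% anc$W
      Vinv <- crossprod(anc$W, PW) + diag(1 / trend_sd^2, theta_dim)
      Lv <- chol(Vinv)
      mt <- backsolve(Lv, backsolve(Lv, drop(crossprod(PW, u_r - anc$a)),
                                    transpose = TRUE))
      trend <- mt + backsolve(Lv, stats::rnorm(theta_dim))
    }

    ## sigma2 | rest (RW Metropolis on the log scale)
    if (is.null(fx$sigma2)) {
      ls <- log(sigma2)
      ls_p <- ls + s_sig * stats::rnorm(1)
      anc_p <- anchored(exp(ls_p), C)
      att["sigma2"] <- att["sigma2"] + 1
      win_att["sigma2"] <- win_att["sigma2"] + 1
      if (!is.null(anc_p)) {
        lr <- prior_quad(anc_p, u_r, trend) - prior_quad(anc, u_r, trend) +
          stats::dnorm(ls_p, h$log_sigma2_mean, h$log_sigma2_sd, TRUE) -
          stats::dnorm(ls, h$log_sigma2_mean, h$log_sigma2_sd, TRUE)
        if (log(stats::runif(1)) < lr) {
          sigma2 <- exp(ls_p); anc <- anc_p
          acc["sigma2"] <- acc["sigma2"] + 1
          win_acc["sigma2"] <- win_acc["sigma2"] + 1
        }
      }
    }

    ## b | rest (optional joint RW Metropolis on log scale)
    if (prior$estimate_b) {
      lb <- log(b_cur)
      lb_p <- lb + s_b * stats::rnorm(6)
      C_p <- prior_corr(comp, exp(lb_p), spec)
      anc_p <- anchored(sigma2, C_p)
      att["b"] <- att["b"] + 1
      win_att["b"] <- win_att["b"] + 1
      if (!is.null(anc_p)) {
        lr <- prior_quad(anc_p, u_r, trend) - prior_quad(anc, u_r, trend) +
          sum(stats::dnorm(lb_p, h$log_b_mean, h$log_b_sd, TRUE)) -
          sum(stats::dnorm(lb, h$log_b_mean, h$log_b_sd, TRUE))
        if (log(stats::runif(1)) < lr) {
          b_cur <- exp(lb_p); C <- C_p; anc <- anc_p
          acc["b"] <- acc["b"] + 1
          win_acc["b"] <- win_acc["b"] + 1
        }
      }
    }

    ## proposal adaptation during burn-in
    if (control$adapt && it <= control$burn_in && it %% 50L == 0L) {
      tune <- function(s, a, n) {
        if (n == 0) return(s)
        min(5, max(0.005, s * exp(0.6 * (a / n - 0.3))))
      }
      s_alpha <- tune(s_alpha, win_acc["alpha"], win_att["alpha"])
      s_sig <- tune(s_sig, win_acc["sigma2"], win_att["sigma2"])
      s_b <- tune(s_b, win_acc["b"], win_att["b"])
      win_acc[] <- 0; win_att[] <- 0
    }

    if (kpos <= ndraw && it == keep[kpos]) {
      u_store[kpos, ] <- u_all
      row <- c(trend, sigma2, tau2, upsilon2, gamma_alpha)
      if (prior$estimate_b) row <- c(row, b_cur)
      pars_store[kpos, ] <- row
      if (control$store_alpha) alpha_store[kpos, ] <- alpha
      kpos <- kpos + 1L
    }
  }

  structure(list(
    draws = list(u = u_store, pars = as.data.frame(pars_store),
                 alpha = alpha_store),
    states = codes, spec = spec, prior = prior, control = control,
    seed = seed, study = study,
    acceptance = ifelse(att > 0, acc / att, NA_real_)),
    class = "npb_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
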