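test_that("hierarchical log likelihood matches a hand computation", {
  study <- structure(list(
    records = data.frame(respondent = c(1L, 1L, 2L),
                         state = c("222222", "333333", "222222"),
                         y = c(0.75, 0.55, 0.82), missing = FALSE),
    respondents = data.frame(id = 1:2, alpha = NA_real_),
    design_states = c("222222", "333333"), name = "toy"),
    class = "valuation_study")
  u <- c("222222" = 0.8, "333333" = 0.6)
  params <- list(alpha = c(1.1, 0.9), gamma_alpha = 0.02, tau2 = 0.05,
                 upsilon2 = 0.01)
  by_hand <- dnorm(0.75, 1 - 1.1 * (1 - 0.8), 0.1, log = TRUE) +
    dnorm(0.55, 1 - 1.1 * (1 - 0.6), 0.1, log = TRUE) +
    dnorm(0.82, 1 - 0.9 * (1 - 0.8), 0.1, log = TRUE) +
    dlnorm(1.1, 0.02, sqrt(0.05), log = TRUE) +
    dlnorm(0.9, 0.02, sqrt(0.05), log = TRUE)
  expect_equal(npb_loglik(study, u, params), by_hand, tolerance = 1e-10)
  # inflating the error variance lowers the density of a perfect fit
  perfect <- study
  perfect$records$y <- 1 - params$alpha[perfect$records$respondent] *
    (1 - u[perfect$records$state])
  ll1 <- npb_loglik(perfect, u, params)
  params2 <- params; params2$upsilon2 <- 0.02
  expect_lt(npb_loglik(perfect, u, params2), ll1)
  expect_error(npb_loglik(study, u["222222"], params), "every observed")
})

test_that("noiseless data with unit alpha are reproduced exactly", {
  tu <- toy_truth()
  resp <- data.frame(id = 1:6, alpha = 1)
  st <- simulate_study(tu, resp, names(tu$values), 3, upsilon2 = 0,
                       seed = 9)
  fit <- npb_fit(st, npb_prior(),
                 quick_ctl(2000, 500, 1,
                           fix = list(alpha = 1, tau2 = 0.01,
                                      upsilon2 = 1e-8, trend = 0,
                                      gamma_alpha = 0)),
                 seed = 3)
  est <- colMeans(fit$draws$u)[names(tu$values)]
  expect_lt(max(abs(est - tu$values)), 1e-3)
})

test_that("u full conditional matches the conjugate closed form", {
  states <- c("222222", "333333", "423455")
  resp <- data.frame(id = 1:6, alpha = 1)
  st <- simulate_study(toy_truth(), resp, states, 3, upsilon2 = 0.02,
                       seed = 9)
  ups2 <- 0.02; sig2 <- 0.04
  # closed-form Gaussian linear-model posterior under the same prior
  pr <- build_prior(states, npb_prior(), beta = rep(0, 6), sigma2 = sig2)
  rec <- st$records
  ns <- as.numeric(table(factor(rec$state, levels = states)))
  ybar <- as.numeric(tapply(rec$y, factor(rec$state, levels = states),
                            mean))
  S0i <- solve(pr$cov)
  m_exact <- drop(solve(S0i + diag(ns) / ups2,
                        drop(S0i %*% pr$mean) + ns * ybar / ups2))
  fit <- npb_fit(st, npb_prior(),
                 quick_ctl(6000, 1000, 1,
                           fix = list(alpha = 1, tau2 = 0.01,
                                      upsilon2 = ups2, sigma2 = sig2,
                                      trend = 0, gamma_alpha = 0)),
                 seed = 3)
  m_mcmc <- colMeans(fit$draws$u)[states]
  # conservative Monte-Carlo SE (effective size ~ ndraw / 10)
  mcse <- apply(fit$draws$u[, states], 2, sd) /
    sqrt(nrow(fit$draws$u) / 10)
  expect_true(all(abs(m_mcmc - m_exact) < 3 * mcse))
})

test_that("chains are reproducible and anchored", {
  tu <- make_true_utility(seed = 2)
  resp <- simulate_respondents(30, seed = 3)
  des <- setdiff(state_code(sample_states(n = 12, seed = 4)), "111111")
  st <- simulate_study(tu, resp, des, 5, seed = 5)
  f1 <- npb_fit(st, npb_prior(), quick_ctl(600, 200, 2), seed = 77)
  f2 <- npb_fit(st, npb_prior(), quick_ctl(600, 200, 2), seed = 77)
  expect_identical(f1$draws$u, f2$draws$u)
  expect_identical(f1$draws$pars, f2$draws$pars)
  expect_true(all(f1$draws$u[, "111111"] == 1))
  p <- predict(f1)
  expect_equal(p$mean[p$state == "111111"], 1)
  expect_equal(p$sd[p$state == "111111"], 0)
})

test_that("the posterior recovers a synthetic utility surface", {
  tu <- make_true_utility(seed = 42)
  resp <- simulate_respondents(100, tau2 = 0.04, seed = 1)
  des <- setdiff(state_code(sample_states(n = 30, seed = 3)), "111111")
  st <- simulate_study(tu, resp, des, 8, upsilon2 = 0.01, seed = 2)
  fit <- npb_fit(st, npb_prior(), quick_ctl(3000, 1000, 2), seed = 7)
  u_hat <- colMeans(fit$draws$u)[-1]
  expect_gt(cor(u_hat, tu$values[names(u_hat)], method = "spearman"), 0.9)
  # summary and coef expose the hyperparameters
  ce <- coef(fit)
  expect_true(all(c("sigma2", "tau2", "upsilon2") %in% names(ce)))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.npb_fit")
  expect_true(all(sm$parameters$lower <= sm$parameters$upper))
})

test_that("off-design prediction collapses to the prior mean under a
           rough kernel", {
  tu <- toy_truth()
  resp <- data.frame(id = 1:8, alpha = 1)
  st <- simulate_study(tu, resp, names(tu$values), 3, upsilon2 = 0.005,
                       seed = 1)
  fit <- npb_fit(st, npb_prior(b = rep(8, 6)),
                 quick_ctl(1200, 400, 2,
                           fix = list(alpha = 1, gamma_alpha = 0,
                                      tau2 = 0.01)),
                 seed = 2)
  far <- "545545"
  p <- predict(fit, far)
  # with correlation ~ 0 to every design state the conditional mean is the
  # trend mean at that state, averaged over trend draws
  th <- as.matrix(fit$draws$pars[, paste0("beta", 1:6)])
  xc <- drop(parse_state(far)) - 1
  trend_mean <- mean(1 + th %*% xc)
  expect_equal(p$mean, trend_mean, tolerance = 1e-3)
})

test_that("posterior_as_prior reproduces and transports fit moments", {
  tu <- make_true_utility(seed = 2)
  resp <- simulate_respondents(40, seed = 3)
  des <- setdiff(state_code(sample_states(n = 15, seed = 4)), "111111")
  st <- simulate_study(tu, resp, des, 6, seed = 5)
  fit <- npb_fit(st, npb_prior(), quick_ctl(1000, 400, 2), seed = 6)
  post <- posterior_as_prior(fit)
  expect_s3_class(post, "utility_posterior")
  idx <- match(fit$states, post$states)
  expect_equal(post$mean[idx][-1], unname(colMeans(fit$draws$u))[-1],
               tolerance = 1e-10)
  draw_sd <- apply(fit$draws$u, 2, sd)[-1]
  expect_equal(unname(sqrt(diag(post$cov))[idx][-1]), unname(draw_sd),
               tolerance = 1e-6)
  # carrying forward extra states yields a PSD joint covariance
  extra <- c("645655", "334455")
  post2 <- posterior_as_prior(fit, states = c(fit$states, extra))
  expect_true(all(extra %in% post2$states))
  ev <- eigen(post2$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # and the off-design variance is at least the between-draw part
  pd <- predict(fit, extra)
  expect_true(all(pd$sd > 0))
})

test_that("residuals, plotting and replication interfaces run", {
  tu <- make_true_utility(seed = 2)
  resp <- simulate_respondents(25, seed = 3)
  des <- setdiff(state_code(sample_states(n = 10, seed = 4)), "111111")
  st <- simulate_study(tu, resp, des, 4, seed = 5)
  fit <- npb_fit(st, npb_prior(), quick_ctl(600, 200, 2), seed = 6)
  rs <- residuals(fit, type = "state")
  expect_true(all(is.finite(rs)))
  rr <- residuals(fit, type = "record")
  expect_equal(length(rr), sum(!st$records$missing))
  pdf(NULL)
  expect_silent(plot(fit))
  expect_silent(plot(fit, type = "bland_altman"))
  expect_silent(plot(fit, type = "trace"))
  dev.off()
  reps <- simulate(fit, nsim = 2, seed = 9)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "valuation_study")
})
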