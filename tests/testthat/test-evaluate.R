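make_ps <- function(state, obs, pred, sd = NA_real_) {
  s <- data.frame(state = state, observed_mean = obs,
                  n_obs = NA_integer_, predicted_mean = pred,
                  predicted_sd = sd)
  class(s) <- c("prediction_summary", "data.frame")
  s
}

test_that("prediction summaries join observed means with predictions", {
  study <- structure(list(
    records = data.frame(respondent = c(1L, 2L, 1L),
                         state = c("222222", "222222", "333333"),
                         y = c(0.4, 0.6, NA), missing = c(FALSE, FALSE,
                                                          TRUE)),
    respondents = data.frame(id = 1:2, alpha = NA_real_),
    design_states = c("222222", "333333"), name = "toy"),
    class = "valuation_study")
  preds <- data.frame(state = c("222222", "333333"), mean = c(0.55, 0.5),
                      sd = c(0.02, 0.03))
  expect_warning(ps <- prediction_summary(study, preds), "dropped")
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$observed_mean, 0.5)
  expect_equal(ps$n_obs, 2L)
  # full-health convention
  study$records <- rbind(study$records,
                         data.frame(respondent = 2L, state = "111111",
                                    y = 0.97, missing = FALSE))
  study$design_states <- c(study$design_states, "111111")
  preds <- rbind(preds, data.frame(state = "111111", mean = 0.99,
                                   sd = 0))
  ps2 <- suppressWarnings(prediction_summary(study, preds))
  fh <- ps2[ps2$state == "111111", ]
  expect_equal(fh$observed_mean, 1)
  expect_equal(fh$predicted_mean, 1)
  expect_error(suppressWarnings(
    prediction_summary(study, preds[preds$state != "222222", ])),
    "do not cover")
})

test_that("error statistics behave and relate as they must", {
  perfect <- make_ps(c("222222", "333333"), c(0.5, 0.4), c(0.5, 0.4))
  expect_equal(rmse(perfect), 0)
  expect_equal(mean_error(perfect), 0)
  s <- make_ps(c("222222", "333333", "444444"), c(0.6, 0.5, 0.3),
               c(0.55, 0.52, 0.33))
  expect_equal(mean_error(s), mean(c(0.05, -0.02, -0.03)))
  # rmse >= |mean error| with equality iff differences are constant
  set.seed(1)
  for (i in 1:20) {
    obs <- runif(10, -0.5, 1); pred <- obs + rnorm(10, 0, 0.05)
    si <- make_ps(sprintf("2222%d2", sample(1:4, 10, TRUE)), obs, pred)
    expect_gte(rmse(si) + 1e-12, abs(mean_error(si)))
  }
  const <- make_ps(c("222222", "333333"), c(0.5, 0.4), c(0.45, 0.35))
  expect_equal(rmse(const), abs(mean_error(const)), tolerance = 1e-12)
  expect_error(rmse(make_ps("111111", 1, 1)), "no rows")
})

test_that("Bland-Altman block is internally consistent", {
  const <- make_ps(c("222222", "333333", "444444"), c(0.5, 0.4, 0.3),
                   c(0.45, 0.35, 0.25))
  ba <- bland_altman(const)
  expect_equal(ba$mean_bias, 0.05)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_length, 0)
  s <- make_ps(c("222222", "333333", "444444", "234512"),
               c(0.6, 0.5, 0.3, 0.2), c(0.52, 0.55, 0.28, 0.25))
  ba2 <- bland_altman(s)
  d <- s$observed_mean - s$predicted_mean
  expect_equal(ba2$sd_diff, sd(d))               # sample (n-1) denominator
  expect_equal(ba2$loa_length, 3.92 * ba2$sd_diff, tolerance = 1e-15)
  expect_equal(ba2$loa_upper - ba2$loa_lower, ba2$loa_length)
  expect_true(ba2$loa_lower <= ba2$mean_bias &&
                ba2$mean_bias <= ba2$loa_upper)
  expect_error(bland_altman(make_ps(c("111111", "222222"), c(1, 0.5),
                                    c(1, 0.5))), "at least two")
})

test_that("monotonicity audit scores value sets against dominance", {
  tu <- make_true_utility(perturbation_scale = 0)
  mono <- function(codes) tu$values[codes]
  expect_equal(monotonicity_audit(mono, n_states = 400, seed = 3), 0)
  expect_equal(monotonicity_audit(function(codes) -tu$values[codes],
                                  n_states = 400, seed = 3), 1)
  # invariant to strictly increasing transforms
  f1 <- monotonicity_audit(function(cc) pnorm(10 * tu$values[cc] - 4),
                           n_states = 400, seed = 3)
  expect_equal(f1, 0)
  noisy <- function(codes) {
    set.seed(sum(utf8ToInt(paste(codes, collapse = ""))) %% 1000)
    tu$values[codes] + rnorm(length(codes), 0, 0.2)
  }
  fr <- monotonicity_audit(noisy, n_states = 300, seed = 4)
  expect_equal(monotonicity_audit(function(cc) log(1 + exp(noisy(cc))),
                                  n_states = 300, seed = 4), fr)
  # ties count as violations by default, not under ties = "ok"
  expect_equal(monotonicity_audit(function(cc) rep(0.5, length(cc)),
                                  n_states = 200, seed = 5), 1)
  expect_equal(monotonicity_audit(function(cc) rep(0.5, length(cc)),
                                  n_states = 200, seed = 5, ties = "ok"), 0)
  expect_error(monotonicity_audit(mono, n_states = 20000), "lattice size")
})

test_that("cost per QALY is exact arithmetic", {
  expect_identical(cost_per_qaly(12000, 1), 12000)
  expect_error(cost_per_qaly(12000, 0), "positive")
  expect_equal(cost_per_qaly(c(12000, 12000), c(0.5, 0.61)),
               c(24000, 19672))
})
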