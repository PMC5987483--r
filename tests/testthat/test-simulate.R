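test_that("true utility surface honours its construction invariants", {
  zero_dec <- lapply(sf6d_spec()$level_counts, function(L) numeric(L))
  flat <- make_true_utility(decrements = zero_dec, perturbation_scale = 0)
  expect_true(all(flat$values == 1))

  tu <- make_true_utility(perturbation_scale = 0)
  expect_identical(unname(tu$values["111111"]), 1)
  # monotone w.r.t. dominance: sufficient to check all adjacent pairs
  st <- enumerate_states()
  for (d in 1:6) {
    worse <- st
    worse[, d] <- worse[, d] + 1L
    ok <- worse[, d] <= sf6d_spec()$level_counts[d]
    expect_true(all(tu$values[state_code(st[ok, ])] >
                      tu$values[state_code(worse[ok, ])]))
  }

  seeded <- make_true_utility(seed = 42)
  expect_identical(names(which.min(seeded$values)), "645655")
  expect_identical(seeded$values, make_true_utility(seed = 42)$values)
  expect_identical(unname(seeded$values["111111"]), 1)

  bad <- default_decrements()
  bad[[3]][1] <- 0.05
  expect_error(make_true_utility(decrements = bad), "full health")
  bad2 <- default_decrements()
  bad2[[2]] <- c(0, 0.05, 0.02, 0.07)
  expect_error(make_true_utility(decrements = bad2), "nondecreasing")
})

test_that("respondent effects follow the log-normal model", {
  r0 <- simulate_respondents(50, gamma_alpha = 0, tau2 = 0, seed = 1)
  expect_true(all(r0$alpha == 1))
  expect_identical(simulate_respondents(200, tau2 = 0.04, seed = 9)$alpha,
                   simulate_respondents(200, tau2 = 0.04, seed = 9)$alpha)
  # Monte-Carlo moment check at J = 5000
  r <- simulate_respondents(5000, gamma_alpha = 0, tau2 = 0.04, seed = 3)
  expect_lt(abs(mean(log(r$alpha))), 3 * sqrt(0.04 / 5000))
  expect_error(simulate_respondents(10, tau2 = -1), "nonnegative")
  ras <- simulate_respondents(100, covariates = "age_sex",
                              gamma_alpha = c(0, 0.05, -0.1), tau2 = 0.01,
                              seed = 2)
  expect_true(all(c("age_c", "sex") %in% names(ras)))
  expect_true(all(ras$alpha > 0))
})

test_that("study simulation reproduces the measurement model", {
  tu <- toy_truth()
  resp <- data.frame(id = 1:6, alpha = 1)
  noiseless <- simulate_study(tu, resp, names(tu$values), 3, upsilon2 = 0,
                              seed = 4)
  expect_equal(noiseless$records$y,
               unname(tu$values[noiseless$records$state]))
  # bounds hold even under extreme noise and heterogeneity
  wild <- simulate_study(make_true_utility(seed = 1),
                         simulate_respondents(200, tau2 = 1, seed = 2),
                         state_code(sample_states(n = 50, seed = 3)), 5,
                         upsilon2 = 1, seed = 5)
  expect_true(all(wild$records$y[!wild$records$missing] >= -1))
  expect_true(all(wild$records$y[!wild$records$missing] <= 1))
  expect_error(simulate_study(tu, resp, names(tu$values), 4),
               "exceeds")
})

test_that("state allocation is balanced and missingness exact", {
  tu <- make_true_utility(seed = 1)
  resp <- simulate_respondents(40, seed = 2)
  des <- state_code(sample_states(n = 16, seed = 3))
  st <- simulate_study(tu, resp, des, 4, n_missing = 7, seed = 4)
  expect_equal(sum(st$records$missing), 7L)
  expect_true(all(is.na(st$records$y[st$records$missing])))
  counts <- table(st$records$state)
  expect_lte(max(counts) - min(counts), 1)
  per_resp <- tapply(st$records$state, st$records$respondent,
                     function(s) anyDuplicated(s) == 0L)
  expect_true(all(per_resp))
})

test_that("per-state means converge to 1 - E[alpha](1 - u)", {
  tu <- toy_truth()
  tau2 <- 0.04
  resp <- simulate_respondents(4000, tau2 = tau2, seed = 6)
  st <- simulate_study(tu, resp, names(tu$values), 3, upsilon2 = 0.01,
                       seed = 7)
  rec <- st$records
  for (s in names(tu$values)) {
    y <- rec$y[rec$state == s]
    expected <- 1 - exp(tau2 / 2) * (1 - tu$values[[s]])
    se <- sqrt(((1 - tu$values[[s]])^2 * (exp(tau2) - 1) * exp(tau2) +
                  0.01) / length(y))
    expect_lt(abs(mean(y) - expected), 3 * se)
  }
})

test_that("clamping at -1 is rare under default parameters", {
  tu <- make_true_utility(seed = 10)
  resp <- simulate_respondents(500, seed = 11)
  st <- simulate_study(tu, resp, state_code(sample_states(n = 100,
                                                          seed = 12)),
                       8, seed = 13)
  expect_lt(mean(st$records$y <= -1, na.rm = TRUE), 0.01)
})

test_that("two-country scenario is seeded and shaped like the surveys", {
  base <- make_two_country_scenario(seed = 5, shift = 0,
                                    dimension_reweights = rep(1, 6),
                                    a_n_states = 30, a_respondents = 20,
                                    a_per_respondent = 4, a_missing = 2,
                                    b_n_states = 20, b_respondents = 10,
                                    b_per_respondent = 4, b_missing = 1)
  expect_identical(base$truth_a$values, base$truth_b$values)

  sc1 <- make_two_country_scenario(seed = 8, a_n_states = 30,
                                   a_respondents = 20, a_per_respondent = 4,
                                   a_missing = 2, b_n_states = 20,
                                   b_respondents = 10, b_per_respondent = 4,
                                   b_missing = 1)
  sc2 <- make_two_country_scenario(seed = 8, a_n_states = 30,
                                   a_respondents = 20, a_per_respondent = 4,
                                   a_missing = 2, b_n_states = 20,
                                   b_respondents = 10, b_per_respondent = 4,
                                   b_missing = 1)
  expect_identical(sc1$study_a$records, sc2$study_a$records)
  expect_identical(sc1$study_b$records, sc2$study_b$records)
  expect_false(identical(sc1$truth_a$values, sc1$truth_b$values))
  expect_identical(unname(sc1$truth_b$values["111111"]), 1)
  expect_equal(length(unique(sc1$study_a$design_states)), 30L)
  expect_equal(length(unique(sc1$study_b$design_states)), 20L)
})
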