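#' Default per-dimension utility decrements
#'
#' Per-dimension decrements whose maxima sum to 0.64, so the pits state has
#' true utility about 0.36 before perturbation — in the range value sets
#' for this descriptive system place it. Dimension weights give physical
#' functioning and pain the largest losses. Levels are spaced by a convex
#' power curve (\code{shape} > 1): moves near the worst level cost
#' disproportionately more than moves near full health, the uneven spacing
#' empirical value sets show; \code{shape = 1} gives linear spacing.
#'
#' @param spec an [sf6d_spec()].
#' @param max_dec per-dimension decrement at the worst level.
#' @param shape exponent of the within-dimension level curve.
#' @return List of six nondecreasing decrement vectors (first entry 0).
#' @export
default_decrements <- function(spec = sf6d_spec(),
                               max_dec = c(0.16, 0.07, 0.10, 0.15,
                                           0.10, 0.06),
                               shape = 1.5) {
  lapply(1:6, function(d) {
    L <- spec$level_counts[d]
    max_dec[d] * ((seq_len(L) - 1) / max(L - 1, 1))^shape
  })
}

# Zero-mean unit-variance Gaussian field on the full lattice with the
# separable squared-exponential correlation; sampled through the Kronecker
# structure (per-dimension Cholesky factors applied mode by mode), so the
# 18,000-point field never requires an 18,000^2 matrix. Returned in the
# canonical enumeration order (dimension 1 slowest).
lattice_gp_sample <- function(spec, b) {
  L <- spec$level_counts
  z <- stats::rnorm(prod(L))
  # array dims fastest-first: dimension 6 varies fastest in enumeration order
  dims <- rev(L)
  arr <- array(z, dim = dims)
  for (mode in seq_along(dims)) {
    d <- 7L - mode                     # lattice dimension of this array mode
    Cd <- exp(-b[d] * outer(seq_len(L[d]), seq_len(L[d]), "-")^2)
    Ld <- t(chol(Cd + diag(1e-10, L[d])))
    perm <- c(mode, setdiff(seq_along(dims), mode))
    ap <- aperm(arr, perm)
    mat <- Ld %*% matrix(ap, nrow = dims[mode])
    arr <- aperm(array(mat, dim = dims[perm]), order(perm))
  }
  as.numeric(arr)
}

#' Construct a true utility surface over the lattice
#'
#' The generator's truth is additive decrements plus a smooth Gaussian-field
#' perturbation: \eqn{u(x) = 1 - \sum_d dec_d(x_d) + s\,z(x)}, where
#' \eqn{z} has the lattice correlation of [sg_correlation()] and is
#' conditioned to vanish at full health so that \eqn{u(111111) = 1} exactly.
#' If the lattice minimum falls below \code{floor}, all losses \eqn{1 - u}
#' are rescaled proportionally (preserving the anchor and monotonicity).
#' With \code{perturbation_scale = 0} the surface is exactly monotone with
#' respect to [dominates()].
#'
#' @param spec an [sf6d_spec()].
#' @param decrements list of six nonnegative nondecreasing vectors, one per
#'   dimension, first entry 0 (otherwise full health would not map to 1).
#' @param perturbation_scale standard deviation of the smooth field.
#' @param perturbation_b roughness of the field.
#' @param floor lower bound the rescaling enforces on the surface.
#' @param seed optional seed.
#' @return Object of class \code{"true_utility"}: \code{values} (named
#'   vector over the whole lattice), the generator inputs, and the raw field.
#' @export
make_true_utility <- function(spec = sf6d_spec(),
                              decrements = default_decrements(spec),
                              perturbation_scale = 0.06,
                              perturbation_b = rep(0.1, 6),
                              floor = -1, seed = NULL) {
  if (length(decrements) != 6) stop("decrements must list six dimensions")
  for (d in 1:6) {
    dec <- decrements[[d]]
    if (length(dec) != spec$level_counts[d])
      stop("decrements[[", d, "]] must have ", spec$level_counts[d],
           " entries")
    if (dec[1] != 0)
      stop("decrements[[", d, "]][1] must be 0, otherwise u(full health) != 1")
    if (any(dec < 0) || is.unsorted(dec))
      stop("decrements[[", d, "]] must be nonnegative and nondecreasing")
  }
  if (perturbation_scale < 0) stop("perturbation_scale must be nonnegative")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  states <- enumerate_states(spec)
  loss <- numeric(nrow(states))
  for (d in 1:6) loss <- loss + decrements[[d]][states[, d]]
  if (perturbation_scale > 0) {
    z <- lattice_gp_sample(spec, perturbation_b)
    # condition the field to 0 at full health (kernel-weighted subtraction)
    rho <- sg_correlation(states, states[1, , drop = FALSE], perturbation_b,
                          spec)[, 1]
    z <- z - rho * z[1]
  } else z <- numeric(nrow(states))
  u <- 1 - loss + perturbation_scale * z
  if (min(u) < floor) u <- 1 - (1 - u) * (1 - floor) / (1 - min(u))
  names(u) <- rownames(states)
  structure(list(values = u, spec = spec, decrements = decrements,
                 perturbation_scale = perturbation_scale,
                 perturbation_b = perturbation_b,
                 perturbation = z, floor = floor, seed = seed),
            class = "true_utility")
}

#' @export
print.true_utility <- function(x, ...) {
  cat("True utility surface:", length(x$values), "states, range [",
      round(min(x$values), 3), ",", round(max(x$values), 3),
      "], perturbation scale", x$perturbation_scale, "\n")
  invisible(x)
}

#' Simulate respondents with multiplicative valuation effects
#'
#' Each respondent j carries a latent positive effect
#' \eqn{\alpha_j \sim LN(t_j'\gamma_\alpha, \tau^2)} that scales their
#' distance-from-full-health; \eqn{t_j} is an intercept plus optional
#' centred-age and sex covariates.
#'
#' @param J number of respondents.
#' @param covariates \code{"none"} (intercept only) or \code{"age_sex"}.
#' @param gamma_alpha coefficient vector for the log-scale mean (length 1,
#'   or 3 with \code{"age_sex"}).
#' @param tau2 log-scale variance (\eqn{\tau^2 = 0} gives degenerate
#'   \eqn{\alpha_j = \exp(t_j'\gamma_\alpha)}).
#' @param seed optional seed.
#' @return Data frame with columns \code{id}, \code{alpha} and any
#'   covariates.
#' @export
simulate_respondents <- function(J, covariates = c("none", "age_sex"),
                                 gamma_alpha = 0, tau2 = 0.04, seed = NULL) {
  covariates <- match.arg(covariates)
  if (tau2 < 0) stop("tau2 must be nonnegative")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  out <- data.frame(id = seq_len(J))
  if (covariates == "age_sex") {
    if (length(gamma_alpha) != 3)
      stop("gamma_alpha must have length 3 with age_sex covariates")
    out$age_c <- (sample(18:80, J, replace = TRUE) - 49) / 10
    out$sex <- sample(0:1, J, replace = TRUE)
    Tm <- cbind(1, out$age_c, out$sex)
  } else {
    if (length(gamma_alpha) != 1)
      stop("gamma_alpha must be a scalar with intercept-only covariates")
    Tm <- matrix(1, J, 1)
  }
  mu <- drop(Tm %*% gamma_alpha)
  out$alpha <- exp(mu + sqrt(tau2) * stats::rnorm(J))
  out
}

#' Simulate a standard-gamble valuation study
#'
#' Generates records under the measurement model
#' \deqn{y_{ij} = 1 - \alpha_j\{1 - u(x_{ij})\} + \varepsilon_{ij},\quad
#'       \varepsilon_{ij} \sim N(0, \upsilon^2),}
#' then clamps values to [-1, 1] (values below -1 are bounded at -1 as in SG
#' practice; the bound is a data-preparation fact, not part of the
#' likelihood). States are allocated to respondents by balanced
#' randomization: each respondent values \code{states_per_respondent}
#' distinct design states, chosen among the currently least-used with random
#' tie-breaking, so every design state is valued approximately equally
#' often. Records can be flagged missing completely at random, either at a
#' rate or as an exact count; missing records carry \code{y = NA}.
#'
#' @param true_u a [make_true_utility()] surface.
#' @param respondents data frame from [simulate_respondents()].
#' @param design_states six-digit codes (or level matrix) of the states the
#'   study values.
#' @param states_per_respondent states valued by each respondent (at most
#'   the number of design states).
#' @param upsilon2 measurement-error variance.
#' @param missing_rate proportion of records flagged missing.
#' @param n_missing exact missing count (overrides \code{missing_rate}).
#' @param seed optional seed.
#' @param name study label.
#' @return Object of class \code{"valuation_study"}: \code{records}
#'   (respondent, state, y, missing), \code{respondents},
#'   \code{design_states}, \code{name}.
#' @export
simulate_study <- function(true_u, respondents, design_states,
                           states_per_respondent, upsilon2 = 0.01,
                           missing_rate = 0, n_missing = NULL, seed = NULL,
                           name = "synthetic") {
  if (!is.character(design_states)) design_states <- state_code(design_states)
  design_states <- as.character(design_states)
  S <- length(design_states)
  k <- as.integer(states_per_respondent)
  if (k > S) stop("states_per_respondent exceeds the number of design states")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  J <- nrow(respondents)
  counts <- integer(S)
  assign_idx <- matrix(0L, J, k)
  for (j in seq_len(J)) {
    pick <- order(counts + stats::runif(S))[seq_len(k)]
    assign_idx[j, ] <- pick
    counts[pick] <- counts[pick] + 1L
  }
  resp_id <- rep(respondents$id, each = k)
  alpha <- rep(respondents$alpha, each = k)
  codes <- design_states[as.vector(t(assign_idx))]
  u <- true_u$values[codes]
  if (anyNA(u)) stop("design states missing from the true utility surface")
  y <- 1 - alpha * (1 - u) + stats::rnorm(J * k, 0, sqrt(upsilon2))
  y <- pmin(1, pmax(-1, y))
  N <- length(y)
  miss <- rep(FALSE, N)
  if (!is.null(n_missing)) {
    if (n_missing > N) stop("n_missing exceeds the record count")
    miss[sample.int(N, n_missing)] <- TRUE
  } else if (missing_rate > 0) {
    miss <- stats::runif(N) < missing_rate
  }
  y[miss] <- NA_real_
  records <- data.frame(respondent = resp_id, state = codes, y = y,
                        missing = miss, stringsAsFactors = FALSE)
  structure(list(records = records, respondents = respondents,
                 design_states = design_states, name = name),
            class = "valuation_study")
}

#' @export
print.valuation_study <- function(x, ...) {
  cat("Valuation study '", x$name, "': ", nrow(x$respondents),
      " respondents, ", sum(!x$records$missing), " observed valuations (",
      sum(x$records$missing), " missing) across ",
      length(unique(x$design_states)), " design states\n", sep = "")
  invisible(x)
}

#' Two-country synthetic valuation scenario
#'
#' Emulates the data situation the transfer model addresses: a large,
#' completed study in country A and a (possibly much smaller) study in
#' country B whose population values health systematically differently.
#' Country B's truth is A's truth with per-dimension decrement reweighting
#' plus a smooth level-linear shift, so the cross-country difference has
#' exactly the additive \eqn{\gamma_0 + \beta'x} form the transfer prior
#' corrects for; both truths share A's perturbation field. Defaults mirror
#' the published survey designs: A values 249 states with 611 respondents at
#' 6 states each (148 missing), B values 197 states with 582 respondents at
#' 8 states each (60 missing).
#'
#' @param seed integer seed; all stage seeds derive from it.
#' @param shift total extra utility loss in B at the worst state, spread
#'   linearly over levels (0 = none).
#' @param dimension_reweights per-dimension multipliers on A's decrements.
#' @param a_n_states,b_n_states design sizes.
#' @param a_respondents,b_respondents sample sizes.
#' @param a_per_respondent,b_per_respondent valuations per respondent.
#' @param a_missing,b_missing missing-record counts.
#' @param tau2,upsilon2 respondent-effect and error variances (both
#'   countries).
#' @param perturbation_scale smoothness deviation of the shared truth.
#' @param spec an [sf6d_spec()].
#' @return List with \code{truth_a}, \code{truth_b}, \code{study_a},
#'   \code{study_b} and the \code{config} that produced them.
#' @export
make_two_country_scenario <- function(seed = 1, shift = 0.05,
    dimension_reweights = c(1.15, 0.9, 1.1, 1.0, 0.9, 1.05),
    a_n_states = 249, a_respondents = 611, a_per_respondent = 6,
    a_missing = 148,
    b_n_states = 197, b_respondents = 582, b_per_respondent = 8,
    b_missing = 60,
    tau2 = 0.04, upsilon2 = 0.01, perturbation_scale = 0.06,
    spec = sf6d_spec()) {
  config <- list(seed = seed, shift = shift,
                 dimension_reweights = dimension_reweights,
                 a_n_states = a_n_states, a_respondents = a_respondents,
                 a_per_respondent = a_per_respondent, a_missing = a_missing,
                 b_n_states = b_n_states, b_respondents = b_respondents,
                 b_per_respondent = b_per_respondent, b_missing = b_missing,
                 tau2 = tau2, upsilon2 = upsilon2,
                 perturbation_scale = perturbation_scale)
  truth_a <- make_true_utility(spec, perturbation_scale = perturbation_scale,
                               seed = derive_seed(seed, "truth"))
  # B's decrements: reweighted A decrements plus a level-linear extra loss
  total_span <- sum(spec$level_counts - 1)
  dec_b <- lapply(1:6, function(d) {
    dimension_reweights[d] * truth_a$decrements[[d]] +
      shift * (seq_len(spec$level_counts[d]) - 1) / total_span
  })
  states <- enumerate_states(spec)
  loss_b <- numeric(nrow(states))
  for (d in 1:6) loss_b <- loss_b + dec_b[[d]][states[, d]]
  u_b <- 1 - loss_b + perturbation_scale * truth_a$perturbation
  if (min(u_b) < truth_a$floor)
    u_b <- 1 - (1 - u_b) * (1 - truth_a$floor) / (1 - min(u_b))
  names(u_b) <- rownames(states)
  truth_b <- structure(list(values = u_b, spec = spec, decrements = dec_b,
                            perturbation_scale = perturbation_scale,
                            perturbation_b = truth_a$perturbation_b,
                            perturbation = truth_a$perturbation,
                            floor = truth_a$floor, seed = seed),
                       class = "true_utility")
  non_fh <- rownames(states)[-1]
  des_a <- sample_states_from(non_fh, a_n_states,
                              derive_seed(seed, "design_a"))
  des_b <- sample_states_from(non_fh, b_n_states,
                              derive_seed(seed, "design_b"))
  resp_a <- simulate_respondents(a_respondents, tau2 = tau2,
                                 seed = derive_seed(seed, "resp_a"))
  resp_b <- simulate_respondents(b_respondents, tau2 = tau2,
                                 seed = derive_seed(seed, "resp_b"))
  study_a <- simulate_study(truth_a, resp_a, des_a, a_per_respondent,
                            upsilon2 = upsilon2, n_missing = a_missing,
                            seed = derive_seed(seed, "study_a"),
                            name = "country_A")
  study_b <- simulate_study(truth_b, resp_b, des_b, b_per_respondent,
                            upsilon2 = upsilon2, n_missing = b_missing,
                            seed = derive_seed(seed, "study_b"),
                            name = "country_B")
  list(truth_a = truth_a, truth_b = truth_b, study_a = study_a,
       study_b = study_b, config = config)
}

# seeded sample of n codes from a pool (without replacement)
sample_states_from <- function(pool, n, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  sample(pool, n)
}
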