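#' Deterministic per-stage seed derivation
#'
#' Expands one global seed into reproducible per-stage seeds, so that any
#' pipeline stage can be re-run in isolation. The scheme is a fixed
#' congruential hash of the stage label folded into the seed:
#' \code{(seed * 48271 + hash(label)) mod (2^31 - 1) + 1}, where
#' \code{hash} sums the label's character codes weighted by position.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  hm <- 2147483647
  hsh <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% hm
  as.integer((as.numeric(seed) %% hm * 48271 + hsh) %% hm + 1)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write / read a valuation study as CSV
#'
#' Columns: \code{respondent_id}, \code{state}, \code{y}, \code{missing},
#' then one column per respondent covariate (repeated across that
#' respondent's records). Numeric values are written with 17 significant
#' digits so the round trip is bit-exact. The latent \eqn{\alpha_j} is not
#' part of the interchange format (it is unobservable); [read_study()]
#' returns respondents with \code{alpha = NA}.
#'
#' @param study a \code{valuation_study}.
#' @param path CSV file path.
#' @return \code{write_study}: the path, invisibly. \code{read_study}: a
#'   \code{valuation_study}.
#' @export
write_study <- function(study, path) {
  rec <- study$records
  ridx <- match(rec$respondent, study$respondents$id)
  out <- data.frame(respondent_id = rec$respondent, state = rec$state,
                    y = fmt_num(rec$y), missing = rec$missing)
  for (v in intersect(c("age_c", "sex"), names(study$respondents)))
    out[[v]] <- fmt_num(study$respondents[[v]][ridx])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_study
#' @param name study label for the reconstructed object.
#' @export
read_study <- function(path, name = basename(path)) {
  raw <- utils::read.csv(path, colClasses = c(state = "character"))
  need <- c("respondent_id", "state", "y", "missing")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("study file lacks column(s): ", paste(miss, collapse = ", "))
  records <- data.frame(respondent = raw$respondent_id, state = raw$state,
                        y = as.numeric(raw$y),
                        missing = as.logical(raw$missing),
                        stringsAsFactors = FALSE)
  cov_cols <- intersect(c("age_c", "sex"), names(raw))
  first <- !duplicated(raw$respondent_id)
  respondents <- data.frame(id = raw$respondent_id[first])
  for (v in cov_cols) respondents[[v]] <- as.numeric(raw[[v]][first])
  respondents$alpha <- NA_real_
  structure(list(records = records, respondents = respondents,
                 design_states = unique(records$state), name = name),
            class = "valuation_study")
}

#' Write / read a true utility surface as CSV (columns state, utility)
#'
#' @param true_u a \code{true_utility} (or any named utility vector).
#' @param path CSV file path.
#' @export
write_true_utility <- function(true_u, path) {
  v <- if (inherits(true_u, "true_utility")) true_u$values else true_u
  utils::write.csv(data.frame(state = names(v), utility = fmt_num(v)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_true_utility
#' @export
read_true_utility <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(state = "character"))
  v <- as.numeric(tab$utility)
  names(v) <- tab$state
  v
}

#' Serialize / restore a utility posterior (mean CSV + covariance CSV)
#'
#' \code{prefix_mean.csv} holds (state, mean); \code{prefix_cov.csv} the
#' dense covariance with state codes as header. Round trip is bit-exact.
#'
#' @param post a [utility_posterior()].
#' @param prefix file path prefix.
#' @export
write_posterior <- function(post, prefix) {
  utils::write.csv(data.frame(state = post$states, mean = fmt_num(post$mean)),
                   paste0(prefix, "_mean.csv"), row.names = FALSE,
                   quote = FALSE)
  cov_chr <- apply(post$cov, 2, fmt_num)
  colnames(cov_chr) <- post$states
  utils::write.csv(cov_chr, paste0(prefix, "_cov.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(prefix)
}

#' @rdname write_posterior
#' @param label label for the restored object.
#' @export
read_posterior <- function(prefix, label = basename(prefix)) {
  m <- utils::read.csv(paste0(prefix, "_mean.csv"),
                       colClasses = c(state = "character"))
  cv <- as.matrix(utils::read.csv(paste0(prefix, "_cov.csv"),
                                  check.names = FALSE))
  utility_posterior(m$state, as.numeric(m$mean),
                    matrix(as.numeric(cv), nrow(cv), ncol(cv)),
                    label = label)
}

#' Serialize / restore a fit (draw CSVs + JSON metadata)
#'
#' Writes \code{u_draws.csv}, \code{par_draws.csv} and \code{meta.json}
#' (chain configuration, seed, acceptance rates, study name) into a
#' directory. [read_fit_draws()] restores the draws and metadata — enough
#' to recompute any posterior summary; the original study file is the
#' companion needed to rebuild a full \code{npb_fit}.
#'
#' @param fit an [npb_fit()].
#' @param dir output directory (created if absent).
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  u <- apply(fit$draws$u, 2, fmt_num)
  colnames(u) <- colnames(fit$draws$u)
  utils::write.csv(u, file.path(dir, "u_draws.csv"), row.names = FALSE,
                   quote = FALSE)
  p <- vapply(fit$draws$pars, fmt_num, character(nrow(fit$draws$pars)))
  utils::write.csv(p, file.path(dir, "par_draws.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(states = fit$states, seed = fit$seed,
               mode = fit$prior$mode, b = fit$prior$b,
               study = fit$study$name,
               iterations = fit$control$iterations,
               burn_in = fit$control$burn_in, thin = fit$control$thin,
               acceptance = as.list(fit$acceptance))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit_draws <- function(dir) {
  u <- as.matrix(utils::read.csv(file.path(dir, "u_draws.csv"),
                                 check.names = FALSE))
  u <- matrix(as.numeric(u), nrow(u), ncol(u),
              dimnames = list(NULL, colnames(u)))
  p <- utils::read.csv(file.path(dir, "par_draws.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  list(u = u, pars = p, meta = meta)
}

#' Simulate a two-country scenario to files
#'
#' Orchestration: builds [make_two_country_scenario()] from a configuration
#' (a named list or a YAML/JSON file of its arguments), writes the two
#' study CSVs, the two truth CSVs, a config echo (YAML) and run metadata
#' (JSON) into a directory. Re-running with the same config reproduces the
#' files byte-identically.
#'
#' @param config named list of [make_two_country_scenario()] arguments (or
#'   a path to a YAML/JSON file of them); must include \code{seed}.
#' @param outdir output directory.
#' @return The scenario, invisibly.
#' @export
run_simulate <- function(config = list(seed = 1), outdir) {
  config <- load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- do.call(make_two_country_scenario, config)
  write_study(sc$study_a, file.path(outdir, "study_a.csv"))
  write_study(sc$study_b, file.path(outdir, "study_b.csv"))
  write_true_utility(sc$truth_a, file.path(outdir, "truth_a.csv"))
  write_true_utility(sc$truth_b, file.path(outdir, "truth_b.csv"))
  yaml::write_yaml(sc$config, file.path(outdir, "config.yaml"))
  jsonlite::write_json(list(stage = "simulate", seed = sc$config$seed,
                            n_records_a = nrow(sc$study_a$records),
                            n_records_b = nrow(sc$study_b$records)),
                       file.path(outdir, "meta.json"), auto_unbox = TRUE)
  invisible(sc)
}

#' Fit a study file and write posterior artefacts
#'
#' Orchestration: reads a study CSV, resolves the prior source, fits the
#' model, and writes the draws, the carried-forward posterior and the
#' per-state prediction summary.
#'
#' @param study_file CSV from [write_study()].
#' @param prior_source \code{"none"} (standalone), a posterior file prefix
#'   (see [write_posterior()]), or \code{"table1:UK"} / \code{"table1:HK"} /
#'   \code{"table1:HKUK"}.
#' @param outdir output directory.
#' @param control an [npb_control()].
#' @param seed chain seed.
#' @param b roughness vector for the prior.
#' @return The fit, invisibly.
#' @export
run_fit <- function(study_file, prior_source = "none", outdir,
                    control = npb_control(), seed = 1, b = rep(0.1, 6)) {
  study <- read_study(study_file)
  prior <- if (identical(prior_source, "none")) {
    npb_prior(b = b)
  } else if (grepl("^table1:", prior_source)) {
    npb_prior(base = table1_prior(sub("^table1:", "", prior_source), b = b),
              b = b)
  } else {
    npb_prior(base = read_posterior(prior_source), b = b)
  }
  fit <- npb_fit(study, prior, control, seed = seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fit(fit, file.path(outdir, "fit"))
  write_posterior(posterior_as_prior(fit), file.path(outdir, "posterior"))
  ps <- prediction_summary(study, predict(fit))
  utils::write.csv(ps, file.path(outdir, "prediction_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(fit)
}

#' Evaluate prediction summaries and write a comparison report
#'
#' Orchestration: reads one or more prediction-summary CSVs (the layout of
#' the packaged comparison table: \code{state}, \code{observed_mean},
#' \code{predicted_mean}, ...), computes RMSE, mean error and the
#' Bland-Altman block for each, and writes the report as JSON and CSV.
#'
#' @param summary_files character vector of CSV paths.
#' @param outdir output directory.
#' @return The report data frame, invisibly.
#' @export
run_evaluate <- function(summary_files, outdir) {
  if (length(summary_files) < 1L) stop("need at least one summary file")
  rows <- lapply(summary_files, function(f) {
    s <- utils::read.csv(f, colClasses = c(state = "character"))
    need <- c("state", "observed_mean", "predicted_mean")
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop("summary file ", f, " lacks column(s): ",
           paste(miss, collapse = ", "))
    ba <- bland_altman(s)
    data.frame(file = f, n = ba$n, rmse = rmse(s),
               mean_error = mean_error(s), mean_bias = ba$mean_bias,
               sd_diff = ba$sd_diff, loa_lower = ba$loa_lower,
               loa_upper = ba$loa_upper, loa_length = ba$loa_length)
  })
  report <- do.call(rbind, rows)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report, file.path(outdir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}
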