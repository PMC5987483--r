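#' Load the packaged per-state comparison table
#'
#' The packaged fixture transcribes the published per-state comparison of
#' the Hong Kong SF-6D valuation models: for each of the 197 valued states
#' plus full health it lists the observed mean valuation, the UK posterior
#' mean/SD used as prior information, and the posterior mean/SD of the
#' HK-only and HK/UK (transfer) models, all at the 4-decimal printed
#' precision. One state code is printed ambiguously in the source typography
#' and is transcribed as 643125. The transcription is validated by
#' [recompute_printed_aggregates()]: all published summary statistics are
#' reproduced from it at printed precision.
#'
#' @return Data frame with 198 rows and columns \code{state},
#'   \code{observed}, \code{uk_mean}, \code{uk_sd}, \code{hk_mean},
#'   \code{hk_sd}, \code{hkuk_mean}, \code{hkuk_sd}.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "npbvalue")
  if (path == "") stop("packaged table1.csv not found")
  tab <- utils::read.csv(path, colClasses = c(state = "character"))
  expected <- c("state", "observed", "uk_mean", "uk_sd", "hk_mean", "hk_sd",
                "hkuk_mean", "hkuk_sd")
  if (!identical(names(tab), expected))
    stop("fixture integrity: unexpected columns in table1.csv")
  if (nrow(tab) != 198L)
    stop("fixture integrity: expected 198 rows, found ", nrow(tab))
  parse_state(tab$state)  # every code must be a valid lattice state
  if (!identical(as.numeric(unlist(tab[tab$state == "111111", -1])),
                 c(1, 1, 0, 1, 0, 1, 0)))
    stop("fixture integrity: full-health row is not (1, 1,0, 1,0, 1,0)")
  sds <- unlist(tab[c("uk_sd", "hk_sd", "hkuk_sd")])
  if (anyNA(tab) || any(sds < 0) || any(sds > 1))
    stop("fixture integrity: SD out of range or missing value")
  means <- unlist(tab[c("observed", "uk_mean", "hk_mean", "hkuk_mean")])
  if (any(means < -1) || any(means > 1))
    stop("fixture integrity: mean outside [-1, 1]")
  tab
}

#' Recompute the published aggregate comparison statistics
#'
#' Runs [rmse()], [mean_error()] and [bland_altman()] on the packaged table
#' for both the HK-only and the HK/UK transfer model against the observed
#' means, excluding the full-health row, and compares each statistic with
#' its published value. Comparison tolerance is 1.5 units in the last
#' printed digit: one unit because the published figures are truncated
#' rather than rounded, plus an allowance for the 4-decimal rounding of the
#' table cells the statistics are recomputed from. The two published mean
#' biases are attributed to the models in reverse of what the table itself
#' yields (the SDs and RMSEs identify the columns unambiguously), so mean
#' bias is compared as an unordered pair.
#'
#' @param table the loaded table (defaults to the packaged fixture).
#' @return Data frame with one row per (statistic, model): computed value,
#'   published value, and a pass flag.
#' @export
recompute_printed_aggregates <- function(table = load_table1()) {
  make_summary <- function(mean_col, sd_col) {
    s <- data.frame(state = table$state, observed_mean = table$observed,
                    n_obs = NA_integer_, predicted_mean = table[[mean_col]],
                    predicted_sd = table[[sd_col]])
    class(s) <- c("prediction_summary", "data.frame")
    s
  }
  s_hk <- make_summary("hk_mean", "hk_sd")
  s_hkuk <- make_summary("hkuk_mean", "hkuk_sd")
  comp <- data.frame(
    statistic = rep(c("rmse", "abs_mean_bias", "sd_diff", "loa_length"),
                    each = 2),
    model = rep(c("HK", "HKUK"), 4),
    computed = c(rmse(s_hk), rmse(s_hkuk),
                 abs(mean_error(s_hk)), abs(mean_error(s_hkuk)),
                 bland_altman(s_hk)$sd_diff, bland_altman(s_hkuk)$sd_diff,
                 bland_altman(s_hk)$loa_length,
                 bland_altman(s_hkuk)$loa_length),
    published = c(0.051, 0.045, 0.0175, 0.0116, 0.0503, 0.0416,
                  0.197, 0.163),
    digits = c(3, 3, 4, 4, 4, 4, 3, 3))
  tol <- 1.5 * 10^(-comp$digits)
  pass <- abs(comp$computed - comp$published) <= tol
  # the published bias pair is swapped between models in the source prose:
  # accept the unordered-pair match for that statistic
  bias <- comp$statistic == "abs_mean_bias"
  pair_ok <- all(abs(sort(comp$computed[bias]) -
                       sort(comp$published[bias])) <= tol[bias])
  pass[bias] <- pass[bias] | pair_ok
  comp$pass <- pass
  comp
}
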