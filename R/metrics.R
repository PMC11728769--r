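#' @title Verification and validation metrics
#' @description Observed-versus-predicted goodness-of-fit R-squared with
#'   qualitative classification bands, Kolmogorov-Smirnov normality testing
#'   with a log-transformation retry, and percent elevation of group means.
#' @name metrics
NULL

#' Classify an R-squared value into a qualitative band
#'
#' Bands: excellent (R^2 > 0.9), good (0.4 <= R^2 <= 0.9), modest
#' (0.1 <= R^2 < 0.4), poor (below 0.1). The printed band ranges overlap at
#' their endpoints; boundaries are assigned to the closed side shown here.
#'
#' @param r2 Numeric R-squared value(s).
#' @return Character vector of band labels.
#' @export
classify_r2 <- function(r2) {
  ifelse(r2 > 0.9, "excellent",
         ifelse(r2 >= 0.4, "good",
                ifelse(r2 >= 0.1, "modest", "poor")))
}

#' Goodness-of-fit R-squared between observed and predicted values
#'
#' `R^2 = 1 - SSE/SST` where SSE is the sum of squared observed-minus-
#' predicted differences and SST the total sum of squares of the observed
#' values about their mean. Computed on whatever scale the caller supplies
#' (log-transform log-modeled variables first if desired).
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 3).
#' @return An object of class `gof_result`: `r_squared`, `band`, `n`.
#' @examples
#' gof_r2(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
gof_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop_config("observed and predicted must have equal length")
  }
  if (length(observed) < 3) stop_config("need at least 3 pairs")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop_config("observed vector is constant; R^2 undefined")
  sse <- sum((observed - predicted)^2)
  r2 <- 1 - sse / sst
  structure(list(r_squared = r2, band = classify_r2(r2),
                 n = length(observed)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("GOF R^2 = %.4f (%s), n = %d\n", x$r_squared, x$band, x$n))
  invisible(x)
}

#' Kolmogorov-Smirnov normality check with log-transformation retry
#'
#' One-sample KS test against a normal with the sample's estimated mean and
#' sd. If normality is rejected at `alpha` and `try_log = TRUE`, the test is
#' repeated on the log values and the result reports which scale conformed
#' (`"raw"`, `"log"`, or `"neither"`). With estimated parameters the plain
#' KS test is conservative; `lilliefors = TRUE` uses the Lilliefors
#' correction instead (requires the nortest package).
#'
#' @param values Numeric vector, n >= 20, non-degenerate.
#' @param try_log Retry on the log scale when the raw scale is rejected
#'   (requires all values > 0).
#' @param alpha Rejection level, default 0.05.
#' @param lilliefors Use `nortest::lillie.test()` instead of the plain KS
#'   test.
#' @return List with `statistic`, `p_value` (of the reported scale),
#'   `scale`, and the per-scale results in `raw` and `log`.
#' @export
ks_normality <- function(values, try_log = FALSE, alpha = 0.05,
                         lilliefors = FALSE) {
  if (length(values) < 20) stop_config("need at least 20 values")
  if (stats::sd(values) == 0) stop_config("degenerate (constant) distribution")
  if (try_log && any(values <= 0)) {
    stop_config("log retry requires all values > 0")
  }
  run_test <- function(x) {
    if (lilliefors) {
      if (!requireNamespace("nortest", quietly = TRUE)) {
        stop_config("lilliefors = TRUE requires the nortest package")
      }
      t <- nortest::lillie.test(x)
    } else {
      t <- suppressWarnings(
        stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
    }
    list(statistic = unname(t$statistic), p_value = t$p.value)
  }
  raw <- run_test(values)
  if (raw$p_value >= alpha || !try_log) {
    scale <- if (raw$p_value >= alpha) "raw" else "neither"
    return(list(statistic = raw$statistic, p_value = raw$p_value,
                scale = scale, raw = raw, log = NULL))
  }
  lg <- run_test(log(values))
  scale <- if (lg$p_value >= alpha) "log" else "neither"
  list(statistic = lg$statistic, p_value = lg$p_value, scale = scale,
       raw = raw, log = lg)
}

#' Percent elevation of a group mean over a reference mean
#'
#' `100 * (group_mean / reference_mean - 1)`; returned unrounded (round only
#' at presentation).
#'
#' @param group_mean Group mean (numeric).
#' @param reference_mean Reference mean (> 0).
#' @return Percent difference.
#' @examples
#' percent_elevation(249.3, 153.3) # ~62.6
#' @export
percent_elevation <- function(group_mean, reference_mean) {
  if (any(reference_mean <= 0)) {
    stop_config("reference mean must be positive")
  }
  100 * (group_mean / reference_mean - 1)
}

#' Observed-versus-predicted GOF across the network
#'
#' The verification/validation procedure: take the observed primaries of
#' `observed`, predict every secondary variable deterministically through
#' the network ([predict_cohort()]), and compute the GOF R-squared per
#' variable. Log-modeled variables are compared on the log (modeled) scale
#' by default.
#'
#' @param observed A patient table with observed primaries and secondaries.
#' @param coefs A [coefficient_set()].
#' @param scale `"model"` (log-modeled variables compared on the log scale)
#'   or `"natural"`.
#' @return Data frame: variable, scale, r_squared, band, n.
#' @export
network_gof <- function(observed, coefs = default_coefficients(),
                        scale = c("model", "natural")) {
  scale <- match.arg(scale)
  profiles <- data.frame(tumor = observed$tumor, sex = observed$sex,
                         origin = observed$origin, ecog = observed$ecog,
                         age = observed$age_years, stringsAsFactors = FALSE)
  pred <- predict_cohort(profiles, coefs)
  cols <- var_columns()
  rows <- lapply(coefs$equations, function(eq) {
    cn <- cols[[eq$response]]
    if (!cn %in% names(observed)) return(NULL)
    obs <- observed[[cn]]
    prd <- pred[[cn]]
    keep <- !is.na(obs)
    obs <- obs[keep]; prd <- prd[keep]
    use_log <- scale == "model" && eq$scale == "log"
    if (use_log) { obs <- log(obs); prd <- log(prd) }
    g <- gof_r2(obs, prd)
    data.frame(variable = eq$response,
               scale = if (use_log) "log" else "linear",
               r_squared = g$r_squared, band = g$band, n = g$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
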