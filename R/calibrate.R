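#' Calibrate residual sds against marginal SD targets
#'
#' The published per-stage residual variances are not available, so this
#' routine solves for them: for each targeted response (processed in network
#' order, so upstream calibrations feed downstream stages), it bisects on
#' the stage's residual sd until the simulated marginal SD of that variable
#' (natural scale) matches the target within 2% relative. If the marginal SD
#' induced by upstream variability alone (stage sd 0) already exceeds the
#' target, the stage is reported as saturated and its sd set to 0.
#'
#' The same primary profiles and the same residual random stream are reused
#' across bisection evaluations, making the solved sd deterministic given
#' `seed`.
#'
#' @param coefs A [coefficient_set()].
#' @param spec A [population_spec()] describing the population the targets
#'   refer to.
#' @param targets Named numeric vector: response variable -> target marginal
#'   SD on the natural scale.
#' @param n_sim Simulation size per evaluation (>= 10000).
#' @param residuals Starting [residual_spec()]; untargeted stages keep these
#'   sds.
#' @param seed Seed for the calibration simulations.
#' @return A [residual_spec()] with calibrated sds; attribute `"saturated"`
#'   lists any saturated stages.
#' @export
calibrate_residuals <- function(coefs, spec, targets, n_sim = 10000,
                                residuals = default_residuals(), seed = 1L) {
  if (n_sim < 10000) stop_config("n_sim must be >= 10000")
  bad <- setdiff(names(targets),
                 vapply(coefs$equations, function(e) e$response, character(1)))
  if (length(bad)) {
    stop_config("target '%s' is not a response of the network", bad[1L])
  }
  spec_sim <- spec
  spec_sim$n <- as.integer(n_sim)
  profiles <- sample_primaries(spec_sim, seed = seed)
  column_of <- var_columns()
  saturated <- character(0)

  current <- residuals
  for (eq in coefs$equations) {
    v <- eq$response
    if (!v %in% names(targets)) next
    target <- as.numeric(targets[[v]])
    sim_sd <- function(sd_try) {
      current$sds[v] <- sd_try
      tab <- simulate_cohort(profiles, coefs, current,
                             seed = derive_subseed(seed, v))
      stats::sd(tab[[column_of[v]]])
    }
    f0 <- sim_sd(0)
    if (f0 >= target) {
      message(sprintf("stage %d (%s): upstream variability alone gives sd %.4g >= target %.4g; saturated, sd set to 0",
                      eq$id, v, f0, target))
      current$sds[v] <- 0
      saturated <- c(saturated, v)
      next
    }
    hi <- max(target / 2, 0.05)
    while (sim_sd(hi) < target && hi < 1e4) hi <- hi * 2
    lo <- 0
    for (i in seq_len(60)) {
      mid <- (lo + hi) / 2
      val <- sim_sd(mid)
      if (abs(val - target) / target <= 0.02) { lo <- hi <- mid; break }
      if (val < target) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-10) break
    }
    current$sds[v] <- (lo + hi) / 2
  }
  attr(current, "saturated") <- saturated
  current
}
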