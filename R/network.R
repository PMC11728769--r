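#' @title Network evaluation
#' @description Deterministic stage means, residual sampling, and full-cohort
#'   simulation through the regression cascade.
#' @name network
NULL

#' Per-stage residual error model
#'
#' One entry per response variable: a Gaussian residual standard deviation on
#' the stage's modeled scale (0 gives the deterministic mean exactly), plus
#' physiologic bounds on the natural scale and the policy applied when a
#' draw falls outside them (`"resample"` redraws up to 1000 rounds then
#' clamps; `"clamp"` clamps immediately; `"none"` accepts the draw).
#'
#' @param sds Named numeric vector of residual sds by response variable.
#' @param bounds Named list of `c(low, high)` natural-scale bounds.
#' @param policy Named character vector of bound policies.
#' @return An object of class `residual_spec`.
#' @export
residual_spec <- function(sds, bounds = NULL, policy = NULL) {
  if (any(unlist(sds) < 0)) stop_config("residual sds must be >= 0")
  d <- default_residuals()
  out <- d
  for (v in names(sds)) {
    if (!v %in% names(var_columns())) stop_config("unknown variable '%s'", v)
    out$sds[v] <- as.numeric(sds[[v]])
  }
  for (v in names(bounds %||% list())) out$bounds[[v]] <- as.numeric(bounds[[v]])
  for (v in names(policy %||% character())) out$policy[v] <- policy[[v]]
  stopifnot(all(out$policy %in% c("resample", "clamp", "none")))
  out
}

#' Default residual error model
#'
#' Residual sds: 0.1 on every log-modeled scale, 4 cm for height, 0.3 g/dL
#' for albumin, 1.0 g/dL for haemoglobin and 2.0% for haematocrit. The
#' published residual variances themselves are not available, so these
#' defaults are deliberate, documented placeholders of physiologic
#' magnitude; [calibrate_residuals()] adjusts them to match user-supplied
#' marginal SD targets. Bounds: albumin 1–6 g/dL, Hb 5–20 g/dL, HTC 15–60%,
#' all other variables positive; policy `"resample"` everywhere.
#'
#' @return An object of class `residual_spec`.
#' @export
default_residuals <- function() {
  sds <- c(height = 4, weight = 0.1, aag = 0.1, albumin = 0.3, hb = 1.0,
           nl_ratio = 0.1, pl_ratio = 0.1, crp = 0.1, ldh = 0.1, htc = 2.0)
  bounds <- list(height = c(0, Inf), weight = c(0, Inf), aag = c(0, Inf),
                 albumin = c(1, 6), hb = c(5, 20), nl_ratio = c(0, Inf),
                 pl_ratio = c(0, Inf), crp = c(0, Inf), ldh = c(0, Inf),
                 htc = c(15, 60))
  policy <- stats::setNames(rep("resample", length(sds)), names(sds))
  structure(list(sds = sds, bounds = bounds, policy = policy),
            class = "residual_spec")
}

# evaluate one term for a data environment (named list of vectors);
# errors name the stage and the missing covariate
term_value <- function(t, data, stage_id) {
  get_var <- function(v) {
    x <- data[[v]]
    if (is.null(x)) {
      stop_config("stage %d: missing covariate '%s'", stage_id, v)
    }
    x
  }
  switch(t$kind,
    numeric = {
      x <- get_var(t$var)
      if (t$transform == "log") log(x) else x
    },
    indicator = as.numeric(as.character(get_var(t$var)) %in% t$levels),
    interaction = {
      x <- get_var(t$var)
      x <- if (t$transform == "log") log(x) else x
      x * as.numeric(as.character(get_var(t$by)) %in% t$by_levels)
    },
    stop_config("stage %d: unknown term kind '%s'", stage_id, t$kind))
}

# design matrix (without intercept) for an equation over a data environment;
# zero columns for an intercept-only equation
stage_design <- function(eq, data) {
  if (!length(eq$terms)) {
    n <- if (is.data.frame(data)) nrow(data)
         else if (length(data)) length(data[[1L]]) else 1L
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  }
  cols <- lapply(eq$terms, term_value, data = data, stage_id = eq$id)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(eq$terms, term_label, character(1))
  m
}

#' Deterministic stage mean
#'
#' Evaluates the linear predictor of one equation on its modeled scale:
#' intercept plus the sum of coefficient times (possibly transformed)
#' covariate. Pure function; vectorized over the rows of `covariates`.
#'
#' @param eq An [equation_spec()].
#' @param covariates Named list or data.frame of covariate values on their
#'   natural scales (e.g. AAG in mg/dL even where the equation uses log AAG).
#' @return Numeric vector on the stage's modeled scale.
#' @examples
#' eq <- default_coefficients()$equations[[1]]
#' stage_mean(eq, list(age = 60, sex = "female", origin = "European"))
#' @export
stage_mean <- function(eq, covariates) {
  X <- stage_design(eq, covariates)
  betas <- vapply(eq$terms, function(t) t$coef, numeric(1))
  as.numeric(eq$intercept + X %*% betas)
}

#' Sample one stage with residual error
#'
#' Adds a Gaussian residual (sd taken from `residuals` for the stage's
#' response) to the stage mean on the modeled scale, back-transforms
#' log-scale responses by exponentiation, and applies the bounds policy on
#' the natural scale. With sd 0 the result is exactly the (back-transformed)
#' stage mean.
#'
#' @param eq An [equation_spec()].
#' @param covariates As in [stage_mean()].
#' @param residuals A [residual_spec()].
#' @param seed Optional seed.
#' @return Numeric vector on the response's natural scale.
#' @export
stage_sample <- function(eq, covariates, residuals = default_residuals(),
                         seed = NULL) {
  mu <- stage_mean(eq, covariates)
  r <- eq$response
  sd <- if (r %in% names(residuals$sds)) residuals$sds[[r]] else 0
  bounds <- residuals$bounds[[r]] %||% c(-Inf, Inf)
  policy <- if (r %in% names(residuals$policy)) residuals$policy[[r]] else "none"
  back <- function(z) if (eq$scale == "log") exp(z) else z
  with_seed(seed, {
    if (sd == 0) return(back(mu))
    y <- back(mu + stats::rnorm(length(mu), 0, sd))
    if (policy == "none") return(y)
    bad <- which(y < bounds[1] | y > bounds[2])
    if (policy == "resample") {
      attempts <- 0L
      while (length(bad) && attempts < 1000L) {
        y[bad] <- back(mu[bad] + stats::rnorm(length(bad), 0, sd))
        bad <- which(y < bounds[1] | y > bounds[2])
        attempts <- attempts + 1L
      }
      if (length(bad)) {
        warning(sprintf("stage %d (%s): %d draw(s) clamped after 1000 resampling rounds",
                        eq$id, eq$response, length(bad)))
      }
    }
    bad <- which(y < bounds[1] | y > bounds[2])
    if (length(bad)) y[bad] <- pmin(pmax(y[bad], bounds[1]), bounds[2])
    y
  })
}

#' Mosteller body surface area
#'
#' `BSA (m^2) = sqrt(height_cm * weight_kg / 3600)`.
#'
#' @param height Height in cm (> 0).
#' @param weight Weight in kg (> 0).
#' @return BSA in m^2.
#' @examples
#' derive_bsa(165, 72.6)
#' @export
derive_bsa <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0)) {
    stop_config("derive_bsa: height and weight must be positive")
  }
  sqrt(height * weight / 3600)
}

#' Body mass index
#'
#' `BMI (kg/m^2) = weight_kg / (height_m)^2`.
#'
#' @inheritParams derive_bsa
#' @return BMI in kg/m^2.
#' @export
derive_bmi <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0)) {
    stop_config("derive_bmi: height and weight must be positive")
  }
  weight / (height / 100)^2
}

#' Columns of a patient table
#'
#' The fixed, documented column set of every cohort emitted or accepted by
#' the package.
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "tumor", "sex", "origin", "ecog", "age_years",
    "height_cm", "weight_kg", "bsa_m2", "bmi_kg_m2", "aag_mg_dl",
    "albumin_g_dl", "hb_g_dl", "nl_ratio", "pl_ratio", "crp_mg_l",
    "ldh_u_l", "htc_pct")
}

#' Simulate a full virtual cohort
#'
#' Evaluates the network stages in order for each patient, each stage
#' consuming the previously simulated values, then derives BSA (Mosteller)
#' and BMI from the simulated height and weight.
#'
#' @param profiles Data frame of primary profiles as returned by
#'   [sample_primaries()] (columns tumor, sex, origin, ecog, age).
#' @param coefs A [coefficient_set()]; default [default_coefficients()].
#' @param residuals A [residual_spec()]; default [default_residuals()].
#' @param seed Optional seed for the residual draws.
#' @return A `data.frame` of class `cohort` with the columns of
#'   [cohort_columns()], plus attributes `spec_hash`, `coef_hash` and `seed`.
#' @export
simulate_cohort <- function(profiles, coefs = default_coefficients(),
                            residuals = default_residuals(), seed = NULL) {
  stopifnot(inherits(coefs, "coefficient_set"))
  need <- primary_vars()
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    stop_config("profiles missing column(s): %s", paste(miss, collapse = ", "))
  }
  data <- as.list(profiles[need])
  with_seed(seed, {
    for (eq in coefs$equations) {
      data[[eq$response]] <- stage_sample(eq, data, residuals)
    }
    n <- nrow(profiles)
    out <- data.frame(
      patient_id = seq_len(n),
      tumor = data$tumor, sex = data$sex, origin = data$origin,
      ecog = as.integer(data$ecog), age_years = data$age,
      height_cm = data$height, weight_kg = data$weight,
      bsa_m2 = derive_bsa(data$height, data$weight),
      bmi_kg_m2 = derive_bmi(data$height, data$weight),
      aag_mg_dl = data$aag, albumin_g_dl = data$albumin,
      hb_g_dl = data$hb, nl_ratio = data$nl_ratio,
      pl_ratio = data$pl_ratio, crp_mg_l = data$crp,
      ldh_u_l = data$ldh, htc_pct = data$htc,
      stringsAsFactors = FALSE)
    structure(out,
              spec_hash = object_hash(profiles[need]),
              coef_hash = object_hash(coefs),
              seed = seed,
              class = c("cohort", "data.frame"))
  })
}

#' Predict secondary variables deterministically from primaries
#'
#' Runs the cascade with all residual sds set to 0: each secondary variable
#' is its modeled (back-transformed) mean given the simulated values of the
#' earlier stages. This is the prediction path used for verification and
#' validation against an observed table.
#'
#' @param profiles Primary profiles (tumor, sex, origin, ecog, age).
#' @param coefs A [coefficient_set()].
#' @return A `cohort` data frame (no residual noise).
#' @export
predict_cohort <- function(profiles, coefs = default_coefficients()) {
  zero <- default_residuals()
  zero$sds[] <- 0
  simulate_cohort(profiles, coefs, zero)
}
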