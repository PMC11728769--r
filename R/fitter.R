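#' @title Stage-wise network fitting
#' @description The inverse path: ordinary least squares refitting of each
#'   network stage from a patient table, using observed upstream covariates
#'   (never model-predicted ones), with optional stepwise covariate
#'   selection. Enables parameter-recovery testing and refitting the network
#'   to new data.
#' @name fitting
NULL

#' Split a table into training and validation subsets
#'
#' Simple random split: the training set has `round(fraction * n)` rows.
#'
#' @param table A patient table (any data.frame).
#' @param fraction Training fraction in (0, 1); default 0.7.
#' @param seed Seed for the permutation.
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
split_train_validation <- function(table, fraction = 0.7, seed = 1L) {
  n <- nrow(table)
  if (is.null(n) || n < 10) stop_config("need at least 10 rows to split")
  if (fraction <= 0 || fraction >= 1) stop_config("fraction must be in (0, 1)")
  n_train <- round(fraction * n)
  with_seed(seed, {
    perm <- sample.int(n)
    list(train = sort(perm[seq_len(n_train)]),
         validation = sort(perm[-seq_len(n_train)]))
  })
}

# pull the model-scale response and design matrix for an equation template
# from an observed table; complete-case rows only
stage_fit_data <- function(table, eq) {
  cols <- var_columns()
  need_vars <- unique(c(eq$response, equation_covariates(eq)))
  need_cols <- cols[need_vars]
  miss <- setdiff(need_cols, names(table))
  if (length(miss)) {
    stop_config("stage %d (%s): table is missing column '%s'",
                eq$id, eq$response, miss[1L])
  }
  data <- stats::setNames(lapply(need_vars, function(v) table[[cols[v]]]),
                          need_vars)
  keep <- Reduce(`&`, lapply(data, function(x) !is.na(x)))
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("stage %d (%s): dropped %d incomplete row(s)",
                    eq$id, eq$response, n_dropped))
    data <- lapply(data, function(x) x[keep])
  }
  y <- data[[eq$response]]
  if (eq$scale == "log") y <- log(y)
  X <- stage_design(eq, data)
  list(y = y, X = X, n_dropped = n_dropped)
}

#' Fit one network stage by ordinary least squares
#'
#' Regresses the stage's response (log-transformed when the stage is modeled
#' on the log scale) on the covariate terms of `eq_template`, using the
#' observed values in `table`. Rows with missing required values are dropped
#' (complete-case) and counted. Residual sd is `sqrt(SSE / (n - p))`;
#' standard errors are the classical homoscedastic OLS ones.
#'
#' @param table Patient table with the columns of [cohort_columns()] (at
#'   least those the stage needs).
#' @param eq_template An [equation_spec()] defining response, scale and
#'   candidate terms; its coefficient values are ignored.
#' @return An object of class `fit_result`: the estimated [equation_spec()]
#'   plus `residual_sd`, `std_errors` (named, including `(Intercept)`),
#'   `n_used`, `n_dropped` and `r_squared`.
#' @export
fit_stage <- function(table, eq_template) {
  fd <- stage_fit_data(table, eq_template)
  y <- fd$y
  X <- cbind(`(Intercept)` = 1, fd$X)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 5) {
    stop_config("stage %d (%s): only %d complete rows for %d parameters",
                eq_template$id, eq_template$response, n, p)
  }
  qx <- qr(X)
  if (qx$rank < p) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop_config("stage %d (%s): rank-deficient design; collinear column(s): %s",
                eq_template$id, eq_template$response,
                paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - as.numeric(X %*% beta)
  sse <- sum(res^2)
  sigma2 <- sse / (n - p)
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- colnames(X)
  sst <- sum((y - mean(y))^2)
  fitted_eq <- eq_template
  fitted_eq$intercept <- unname(beta[1L])
  for (i in seq_along(fitted_eq$terms)) {
    fitted_eq$terms[[i]]$coef <- unname(beta[i + 1L])
  }
  structure(list(stage = eq_template$id,
                 equation = fitted_eq,
                 residual_sd = sqrt(sigma2),
                 std_errors = se,
                 n_used = n,
                 n_dropped = fd$n_dropped,
                 r_squared = if (sst > 0) 1 - sse / sst else NA_real_),
            class = "fit_result")
}

#' Refit the whole network from a patient table
#'
#' Fits all stages of `network_template` in order by [fit_stage()]. Each
#' stage is fitted independently on the observed covariates, so permuting a
#' downstream column never changes an upstream fit.
#'
#' @param table Patient table.
#' @param network_template A [coefficient_set()] giving the stage structure;
#'   defaults to the shipped network.
#' @return An object of class `network_fit`: list of `fit_result` in stage
#'   order.
#' @export
fit_network <- function(table, network_template = default_coefficients()) {
  fits <- lapply(network_template$equations, function(eq) {
    fit_stage(table, eq)
  })
  structure(list(fits = fits, htc_scale = network_template$htc_scale),
            class = "network_fit")
}

#' Extract a coefficient set from a network fit
#'
#' Makes fit -> simulate round trips possible: the returned object plugs
#' straight into [simulate_cohort()].
#'
#' @param fit A `network_fit`.
#' @return A [coefficient_set()] of the estimated equations.
#' @export
coefficients_from_fit <- function(fit) {
  stopifnot(inherits(fit, "network_fit"))
  coefficient_set(lapply(fit$fits, function(f) f$equation),
                  htc_scale = fit$htc_scale)
}

#' Residual sds estimated by a network fit
#'
#' @param fit A `network_fit`.
#' @return A [residual_spec()] whose sds are the per-stage OLS residual sds.
#' @export
residuals_from_fit <- function(fit) {
  stopifnot(inherits(fit, "network_fit"))
  sds <- vapply(fit$fits, function(f) f$residual_sd, numeric(1))
  names(sds) <- vapply(fit$fits, function(f) f$equation$response, character(1))
  residual_spec(sds)
}

#' Stepwise covariate selection for one stage
#'
#' Bidirectional stepwise search over the candidate terms of `eq_template`,
#' starting from the intercept-only model, minimizing AIC (default), BIC, or
#' using backward elimination at a p-value threshold of 0.05. Returns the
#' selected term subset refitted by [fit_stage()].
#'
#' @param table Patient table.
#' @param eq_template [equation_spec()] listing the candidate terms.
#' @param criterion `"AIC"`, `"BIC"` or `"p"`.
#' @return A `fit_result` for the selected model (possibly intercept-only,
#'   with a notice).
#' @export
stepwise_select <- function(table, eq_template,
                            criterion = c("AIC", "BIC", "p")) {
  criterion <- match.arg(criterion)
  fd <- stage_fit_data(table, eq_template)
  df <- as.data.frame(fd$X)
  labels <- colnames(fd$X)
  safe <- make.names(labels, unique = TRUE)
  names(df) <- safe
  df$.y <- fd$y
  n <- nrow(df)

  keep_idx <- if (criterion == "p") {
    active <- seq_along(safe)
    repeat {
      if (!length(active)) break
      fml <- stats::reformulate(safe[active], response = ".y")
      fit <- stats::lm(fml, data = df)
      pv <- summary(fit)$coefficients[-1, 4]
      worst <- which.max(pv)
      if (pv[worst] <= 0.05) break
      active <- active[-worst]
    }
    active
  } else {
    k <- if (criterion == "AIC") 2 else log(n)
    null_fit <- stats::lm(.y ~ 1, data = df)
    full <- stats::reformulate(safe, response = ".y")
    sel <- stats::step(null_fit,
                       scope = list(lower = ~1, upper = full),
                       direction = "both", k = k, trace = 0)
    match(setdiff(names(stats::coef(sel)), "(Intercept)"), safe)
  }

  if (!length(keep_idx)) {
    message(sprintf("stage %d (%s): no candidate improved over the intercept-only model",
                    eq_template$id, eq_template$response))
  }
  selected <- eq_template
  selected$terms <- eq_template$terms[sort(keep_idx)]
  fit_stage(table, selected)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Stage %d fit (%s, %s scale): n = %d, residual sd = %.4g, R^2 = %.4f\n",
              x$stage, x$equation$response, x$equation$scale, x$n_used,
              x$residual_sd, x$r_squared))
  print(x$equation)
  invisible(x)
}

#' @export
print.network_fit <- function(x, ...) {
  cat(sprintf("Network fit: %d stages\n", length(x$fits)))
  for (f in x$fits) {
    cat(sprintf("  stage %2d %-9s n=%6d  sd=%.4g  R^2=%.3f\n",
                f$stage, f$equation$response, f$n_used, f$residual_sd,
                f$r_squared))
  }
  invisible(x)
}
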