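#' @title The regression network
#' @description The cascade of ten linear regression equations that turns a
#'   primary profile into a complete patient record. Each stage models one
#'   response (on the linear or natural-log scale) as a linear combination
#'   of primaries and earlier responses.
#' @name equations
NULL

# canonical variable names and their patient-table columns
var_columns <- function() {
  c(tumor = "tumor", sex = "sex", origin = "origin", ecog = "ecog",
    age = "age_years", height = "height_cm", weight = "weight_kg",
    aag = "aag_mg_dl", albumin = "albumin_g_dl", hb = "hb_g_dl",
    nl_ratio = "nl_ratio", pl_ratio = "pl_ratio", crp = "crp_mg_l",
    ldh = "ldh_u_l", htc = "htc_pct")
}

primary_vars <- function() c("tumor", "sex", "origin", "ecog", "age")

categorical_vars <- function() c("tumor", "sex", "origin", "ecog")

#' Terms of a network equation
#'
#' Three kinds of term are supported, mirroring how the published equations
#' are written:
#' * `term_numeric(var, coef, transform)` — a continuous covariate, entered
#'   as-is (`transform = "identity"`) or as its natural log
#'   (`transform = "log"`), e.g. albumin or log AAG;
#' * `term_indicator(var, levels, coef)` — an indicator for a categorical
#'   covariate taking any of `levels` (reference levels carry an implicit
#'   coefficient of 0), e.g. `+ 6.42 if Sub-Saharan African`;
#' * `term_interaction(var, by, by_levels, coef, transform)` — a continuous
#'   covariate times an indicator, e.g. the height-by-female interaction in
#'   the log-weight equation.
#'
#' @param var Covariate name (canonical names: tumor, sex, origin, ecog, age,
#'   height, weight, aag, albumin, hb, nl_ratio, pl_ratio, crp, ldh, htc).
#' @param coef Coefficient.
#' @param transform `"identity"` or `"log"` for continuous covariates.
#' @param levels Character vector of levels activating the indicator.
#' @param by,by_levels Categorical variable and levels gating an interaction.
#' @return A term list used by [equation_spec()].
#' @export
term_numeric <- function(var, coef, transform = "identity") {
  stopifnot(transform %in% c("identity", "log"))
  list(kind = "numeric", var = var, coef = as.numeric(coef),
       transform = transform)
}

#' @rdname term_numeric
#' @export
term_indicator <- function(var, levels, coef) {
  list(kind = "indicator", var = var, levels = as.character(levels),
       coef = as.numeric(coef))
}

#' @rdname term_numeric
#' @export
term_interaction <- function(var, by, by_levels, coef,
                             transform = "identity") {
  stopifnot(transform %in% c("identity", "log"))
  list(kind = "interaction", var = var, by = by,
       by_levels = as.character(by_levels), coef = as.numeric(coef),
       transform = transform)
}

#' Create one stage of the regression network
#'
#' @param id Stage number (its position in the cascade).
#' @param response Canonical name of the response variable.
#' @param scale `"linear"` or `"log"`: the scale the linear predictor models;
#'   log-scale responses are exponentiated when simulated.
#' @param intercept Intercept on the modeled scale.
#' @param terms List of terms from [term_numeric()] and friends.
#' @return An object of class `equation_spec`.
#' @export
equation_spec <- function(id, response, scale, intercept, terms) {
  stopifnot(scale %in% c("linear", "log"))
  if (!response %in% names(var_columns())) {
    stop_config("unknown response variable '%s'", response)
  }
  structure(list(id = as.integer(id), response = response, scale = scale,
                 intercept = as.numeric(intercept), terms = terms),
            class = "equation_spec")
}

# human-readable label for a term (used as design-matrix column name)
term_label <- function(t) {
  base <- if (identical(t$transform %||% "identity", "log")) {
    paste0("log(", t$var, ")")
  } else t$var
  switch(t$kind,
    numeric = base,
    indicator = paste0(t$var, "=", paste(t$levels, collapse = "|")),
    interaction = paste0(base, ":", t$by, "=",
                         paste(t$by_levels, collapse = "|")))
}

# variables an equation reads
equation_covariates <- function(eq) {
  unique(unlist(lapply(eq$terms, function(t) c(t$var, t$by))))
}

#' Bundle equations into a network
#'
#' Validates the hierarchy: each stage may only reference primary variables
#' or the responses of strictly earlier stages (the network is a DAG by
#' construction).
#'
#' @param equations List of [equation_spec()] objects, in evaluation order.
#' @param htc_scale `"linear"` (default) or `"log"`; see Details.
#' @details The final haematocrit stage is printed with a log-scale left-hand
#'   side in the source, but its coefficients only yield physiologic
#'   haematocrits (roughly 30–45%) when the response is read on the linear
#'   scale; the linear reading is therefore the default, and
#'   `htc_scale = "log"` restores the literal printed form.
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(equations, htc_scale = c("linear", "log")) {
  htc_scale <- match.arg(htc_scale)
  available <- primary_vars()
  for (eq in equations) {
    if (!inherits(eq, "equation_spec")) {
      stop_config("all elements must be equation_spec objects")
    }
    used <- equation_covariates(eq)
    bad <- setdiff(used, available)
    if (length(bad)) {
      stop_config("stage %d (%s) references '%s' before it is defined: the network must be acyclic and hierarchical",
                  eq$id, eq$response, bad[1L])
    }
    available <- c(available, eq$response)
  }
  structure(list(equations = equations, htc_scale = htc_scale),
            class = "coefficient_set")
}

#' The default network coefficients
#'
#' The ten published equations, in development order: height; log weight
#' (with the sex-conditional height slope: 0.012 per cm for males, 0.008 for
#' females, i.e. a -0.004 height-by-female interaction); log alpha-1 acid
#' glycoprotein; albumin; haemoglobin; log neutrophil-lymphocyte ratio; log
#' platelet-lymphocyte ratio; log C-reactive protein; log lactate
#' dehydrogenase; and haematocrit. Reference levels (male, East Asian,
#' ECOG-PS 0, tumours outside the named groups) carry coefficient 0.
#'
#' @param htc_scale Passed to [coefficient_set()].
#' @return A [coefficient_set()].
#' @export
default_coefficients <- function(htc_scale = "linear") {
  SSA <- "Sub-Saharan African"; EUR <- "European"
  phg <- c("pancreatic", "hepatic", "gastric")
  eqs <- list(
    equation_spec(1, "height", "linear", 179.9, list(
      term_numeric("age", -0.16),
      term_indicator("sex", "female", -12.81),
      term_indicator("origin", SSA, 6.42),
      term_indicator("origin", EUR, 3.83))),
    equation_spec(2, "weight", "log", 2.10, list(
      term_numeric("height", 0.012),
      term_interaction("height", "sex", "female", -0.004),
      term_indicator("sex", "female", 0.562),
      term_indicator("origin", SSA, 0.262),
      term_indicator("origin", EUR, 0.144))),
    equation_spec(3, "aag", "log", 4.32, list(
      term_indicator("ecog", "1", 0.161),
      term_indicator("ecog", "2", 0.449),
      term_indicator("origin", SSA, 0.634),
      term_indicator("origin", EUR, 0.370),
      term_indicator("tumor", "ovarian", 0.622))),
    equation_spec(4, "albumin", "linear", 5.546, list(
      term_numeric("age", -0.004),
      term_numeric("aag", -0.292, transform = "log"),
      term_indicator("ecog", "1", -0.128),
      term_indicator("ecog", "2", -0.429),
      term_indicator("origin", SSA, 0.276),
      term_indicator("origin", EUR, 0.248),
      term_indicator("tumor", phg, -0.339))),
    equation_spec(5, "hb", "linear", 12.35, list(
      term_numeric("albumin", 0.575),
      term_numeric("aag", -0.793, transform = "log"),
      term_indicator("sex", "female", -0.680))),
    equation_spec(6, "nl_ratio", "log", 1.47, list(
      term_numeric("aag", -0.0073, transform = "log"),
      term_numeric("albumin", -0.16))),
    equation_spec(7, "pl_ratio", "log", 5.52, list(
      term_numeric("hb", -0.057),
      term_numeric("aag", 0.0016),
      term_numeric("nl_ratio", 0.0622),
      term_indicator("tumor", phg, -0.204))),
    equation_spec(8, "crp", "log", 1.394, list(
      term_numeric("pl_ratio", 0.002),
      term_indicator("ecog", "1", 0.368),
      term_indicator("ecog", "2", 0.598),
      term_indicator("tumor", "breast", -2.22))),
    equation_spec(9, "ldh", "log", 5.709, list(
      term_numeric("crp", 0.001))),
    equation_spec(10, "htc", if (htc_scale == "log") "log" else "linear",
                  5.93, list(
      term_numeric("aag", 0.04, transform = "log"),
      term_numeric("hb", 2.515))))
  coefficient_set(eqs, htc_scale = htc_scale)
}

#' @export
print.equation_spec <- function(x, ...) {
  lhs <- if (x$scale == "log") paste0("log(", x$response, ")") else x$response
  rhs <- paste(vapply(x$terms, function(t) {
    sprintf("%+g*%s", t$coef, term_label(t))
  }, character(1)), collapse = " ")
  cat(sprintf("[%d] %s = %g %s\n", x$id, lhs, x$intercept, rhs))
  invisible(x)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("Regression network: %d stages (htc scale: %s)\n",
              length(x$equations), x$htc_scale))
  for (eq in x$equations) print(eq)
  invisible(x)
}
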