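#' @title Configuration documents
#' @description YAML serialization of the population specification, the
#'   network coefficients and the residual error model, with strict schema
#'   validation (unknown keys are rejected by name). The shipped default
#'   document reproduces the published network verbatim.
#' @name config
NULL

config_schema_version <- 1L

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_config("unknown key '%s' in %s", unknown[1L], where)
  }
}

#' Assemble a configuration document
#'
#' @param population A [population_spec()].
#' @param coefficients A [coefficient_set()].
#' @param residuals A [residual_spec()].
#' @return An object of class `config_document`.
#' @export
config_document <- function(population = reference_population(),
                            coefficients = default_coefficients(),
                            residuals = default_residuals()) {
  stopifnot(inherits(population, "population_spec"),
            inherits(coefficients, "coefficient_set"),
            inherits(residuals, "residual_spec"))
  structure(list(schema_version = config_schema_version,
                 population = population,
                 coefficients = coefficients,
                 residuals = residuals),
            class = "config_document")
}

#' The shipped default configuration
#'
#' Reference population, published coefficients, documented residual
#' defaults.
#' @return A [config_document()].
#' @export
default_config <- function() config_document()

# ---- serialization to plain lists -----------------------------------------

term_to_list <- function(t) {
  out <- list(kind = t$kind, var = t$var, coef = t$coef)
  if (!is.null(t$transform) && t$transform != "identity") {
    out$transform <- t$transform
  }
  if (t$kind == "indicator") out$levels <- as.list(t$levels)
  if (t$kind == "interaction") {
    out$by <- t$by
    out$by_levels <- as.list(t$by_levels)
  }
  out
}

term_from_list <- function(l, where) {
  check_keys(l, c("kind", "var", "coef", "transform", "levels", "by",
                  "by_levels"), where)
  kind <- l$kind %||% "numeric"
  switch(kind,
    numeric = term_numeric(l$var, l$coef, l$transform %||% "identity"),
    indicator = term_indicator(l$var, unlist(l$levels), l$coef),
    interaction = term_interaction(l$var, l$by, unlist(l$by_levels), l$coef,
                                   l$transform %||% "identity"),
    stop_config("unknown term kind '%s' in %s", kind, where))
}

config_to_list <- function(doc) {
  pop <- doc$population
  age_targets <- lapply(pop$age_targets, function(t) {
    if (!is.null(t$shape)) list(shape = t$shape, scale = t$scale)
    else list(mean = t$mean, sd = t$sd)
  })
  list(
    schema_version = doc$schema_version,
    population = list(
      n = pop$n,
      seed = pop$seed,
      tumor_probs = as.list(pop$tumor_probs),
      sex_given_tumor = as.list(pop$sex_given_tumor),
      origin_probs = as.list(pop$origin_probs),
      ecog_probs = as.list(pop$ecog_probs),
      age_targets = age_targets,
      age_bounds = as.list(pop$age_bounds)),
    coefficients = list(
      htc_scale = doc$coefficients$htc_scale,
      stages = lapply(doc$coefficients$equations, function(eq) {
        list(id = eq$id, response = eq$response, scale = eq$scale,
             intercept = eq$intercept,
             terms = lapply(eq$terms, term_to_list))
      })),
    residuals = list(
      sds = as.list(doc$residuals$sds),
      bounds = lapply(doc$residuals$bounds, as.list),
      policy = as.list(doc$residuals$policy)))
}

config_from_list <- function(x) {
  check_keys(x, c("schema_version", "population", "coefficients",
                  "residuals"), "config")
  if (is.null(x$population) || is.null(x$coefficients) ||
      is.null(x$residuals)) {
    stop_config("config must contain population, coefficients and residuals sections")
  }
  p <- x$population
  check_keys(p, c("n", "seed", "tumor_probs", "sex_given_tumor",
                  "origin_probs", "ecog_probs", "age_targets", "age_bounds"),
             "config$population")
  pop <- population_spec(
    n = p$n, tumor_probs = p$tumor_probs,
    sex_given_tumor = p$sex_given_tumor,
    origin_probs = p$origin_probs, ecog_probs = p$ecog_probs,
    age_targets = p$age_targets,
    age_bounds = unlist(p$age_bounds %||% c(18, 95)),
    seed = p$seed %||% 1L)

  co <- x$coefficients
  check_keys(co, c("htc_scale", "stages"), "config$coefficients")
  eqs <- lapply(co$stages, function(s) {
    where <- sprintf("config$coefficients stage %s", s$id %||% "?")
    check_keys(s, c("id", "response", "scale", "intercept", "terms"), where)
    equation_spec(s$id, s$response, s$scale, s$intercept,
                  lapply(s$terms, term_from_list, where = where))
  })
  coefs <- coefficient_set(eqs, htc_scale = co$htc_scale %||% "linear")

  re <- x$residuals
  check_keys(re, c("sds", "bounds", "policy"), "config$residuals")
  res <- residual_spec(re$sds,
                       bounds = lapply(re$bounds %||% list(), unlist),
                       policy = unlist(re$policy %||% character()))

  config_document(pop, coefs, res)
}

#' Load a configuration document from YAML
#'
#' All nested invariants (probability renormalization, category spellings,
#' network acyclicity) are enforced at load time; unknown keys are rejected
#' with the offending key named.
#'
#' @param path YAML file path; default the shipped configuration.
#' @return A [config_document()].
#' @export
load_config <- function(path = system.file("extdata",
                                           "default_config.yaml",
                                           package = "oncopop")) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  config_from_list(yaml::read_yaml(path))
}

#' Save a configuration document as YAML
#'
#' Round-trip safe: `load_config(save_config(doc, path))` reproduces `doc`.
#'
#' @param doc A [config_document()].
#' @param path Output file path.
#' @export
save_config <- function(doc, path) {
  stopifnot(inherits(doc, "config_document"))
  yaml::write_yaml(config_to_list(doc), path, precision = 15)
  invisible(path)
}

#' @export
print.config_document <- function(x, ...) {
  cat(sprintf("Configuration (schema %d, hash %s)\n", x$schema_version,
              object_hash(x)))
  print(x$population)
  cat(sprintf("  network: %d stages; residual sds: %s\n",
              length(x$coefficients$equations),
              paste(sprintf("%s %.3g", names(x$residuals$sds),
                            x$residuals$sds), collapse = ", ")))
  invisible(x)
}
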