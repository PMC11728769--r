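#' @title Extrapolation scenario library
#' @description The nine shipped population specifications: the reference
#'   population plus eight extrapolation cohorts that force a single primary
#'   characteristic (single origin, single sex, ECOG-PS 2 only, or a single
#'   tumour type) while every unspecified field inherits the reference
#'   values exactly.
#' @name scenarios
NULL

# overrides per scenario; anything not listed inherits the reference spec
scenario_overrides <- function() {
  all_male_sgt <- reference_sex_given_tumor()
  all_male_sgt[setdiff(names(all_male_sgt), female_only_tumors())] <- 1
  all_female_sgt <- reference_sex_given_tumor()
  all_female_sgt[] <- 0
  list(
    reference = list(n = 1259),
    only_east_asians = list(
      origin_probs = c("East Asian" = 1)),
    only_sub_saharan_africans = list(
      origin_probs = c("Sub-Saharan African" = 1)),
    only_europeans = list(
      origin_probs = c("European" = 1)),
    only_males = list(
      sex_given_tumor = all_male_sgt,
      tumor_probs = c(colon = 0.02, gastric = 0.02, hepatic = 0.03,
                      lung = 0.76, pancreatic = 0.11, sarcoma = 0.06)),
    only_females = list(
      sex_given_tumor = all_female_sgt,
      tumor_probs = c(breast = 0.10, colon = 0.02, endometrial = 0.10,
                      gastric = 0.01, hepatic = 0.01, lung = 0.30,
                      ovarian = 0.40, pancreatic = 0.03, sarcoma = 0.03)),
    only_ecog2 = list(
      ecog_probs = c("0" = 0, "1" = 0, "2" = 1)),
    only_pancreatic = list(
      tumor_probs = c(pancreatic = 1)),
    only_ovarian = list(
      tumor_probs = c(ovarian = 1))
  )
}

#' Names of the shipped scenarios
#'
#' @return Character vector: `"reference"` plus the eight extrapolation
#'   cohorts.
#' @export
scenario_names <- function() names(scenario_overrides())

#' Build the population specification of a named scenario
#'
#' Starts from [reference_population()] and applies the scenario's
#' overrides; every field not overridden equals the reference value exactly.
#' Extrapolation scenarios default to n = 1200; the reference to its
#' training-set size 1259. The pancreatic-only scenario leaves sex to the
#' conditional male-given-pancreatic probability (43/66); the ovarian-only
#' scenario is all-female by the female-only tumour rule.
#'
#' @param name One of [scenario_names()].
#' @param n Optional cohort-size override.
#' @param seed Seed stored in the spec.
#' @return A [population_spec()].
#' @export
build_scenario <- function(name, n = NULL, seed = 1L) {
  ovr <- scenario_overrides()
  if (!name %in% names(ovr)) {
    stop_config("unknown scenario '%s'; valid names: %s", name,
                paste(names(ovr), collapse = ", "))
  }
  o <- ovr[[name]]
  ref <- reference_population(seed = seed)
  args <- list(
    n = n %||% o$n %||% 1200,
    tumor_probs = o$tumor_probs %||% ref$tumor_probs,
    sex_given_tumor = o$sex_given_tumor %||% ref$sex_given_tumor,
    origin_probs = o$origin_probs %||% ref$origin_probs,
    ecog_probs = o$ecog_probs %||% ref$ecog_probs,
    age_targets = o$age_targets %||% ref$age_targets,
    age_bounds = o$age_bounds %||% ref$age_bounds,
    seed = seed)
  suppressMessages(do.call(population_spec, args))
}

#' Run the extrapolation exercise
#'
#' Simulates one cohort per scenario and summarizes the distribution of each
#' simulated variable. Each scenario gets an independent sub-seed derived
#' deterministically from the master seed and the scenario *name*, so adding
#' or reordering scenarios never perturbs another scenario's draws.
#'
#' @param names Scenario names; default the eight extrapolation cohorts.
#' @param n Cohort size per scenario (default 1200).
#' @param coefs A [coefficient_set()].
#' @param residuals A [residual_spec()].
#' @param seed Master seed.
#' @param summaries Also compute [density_summary()] for the ten simulated
#'   variables (default TRUE).
#' @return Named list per scenario: `list(cohort=, densities=)`.
#' @export
run_extrapolation <- function(names = setdiff(scenario_names(), "reference"),
                              n = 1200,
                              coefs = default_coefficients(),
                              residuals = default_residuals(),
                              seed = 1L,
                              summaries = TRUE) {
  out <- lapply(names, function(nm) {
    sub <- derive_subseed(seed, nm)
    spec <- build_scenario(nm, n = n, seed = sub)
    profiles <- sample_primaries(spec)
    cohort <- simulate_cohort(profiles, coefs, residuals,
                              seed = derive_subseed(seed, paste0(nm, "/sim")))
    densities <- if (summaries) {
      responses <- vapply(coefs$equations, function(e) e$response,
                          character(1))
      stats::setNames(lapply(responses, function(v) {
        density_summary(cohort, v)
      }), responses)
    } else NULL
    list(cohort = cohort, densities = densities)
  })
  stats::setNames(out, names)
}
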