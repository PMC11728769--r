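#' @title Population specifications
#' @description Constructors and validators for the specification of the
#'   primary (fixed) variables of a virtual oncology cohort: tumour type,
#'   sex conditional on tumour, biogeographic origin, ECOG performance
#'   status, and the Weibull age model.
#' @name population
NULL

#' Canonical category sets
#'
#' The nine tumour types, three biogeographic origins and three ECOG-PS
#' levels the network is parameterized for. Spellings are fixed and
#' case-sensitive; maps supplied to [population_spec()] must use them.
#'
#' @return Character (or integer, for ECOG) vector of category labels.
#' @export
tumor_categories <- function() {
  c("breast", "colon", "endometrial", "gastric", "hepatic",
    "lung", "ovarian", "pancreatic", "sarcoma")
}

#' @rdname tumor_categories
#' @export
origin_categories <- function() {
  c("European", "Sub-Saharan African", "East Asian")
}

#' @rdname tumor_categories
#' @export
ecog_categories <- function() c(0L, 1L, 2L)

# tumour types that occur in females only
female_only_tumors <- function() c("breast", "endometrial", "ovarian")

#' Create a population specification
#'
#' A `population_spec` fully determines the primary-variable sampling model:
#' category probabilities for tumour, origin and ECOG-PS, the probability of
#' male sex conditional on each tumour type, and the age model per
#' (sex, sarcoma) group. All probability maps are renormalized to sum to 1,
#' so callers may pass the percentages of a published table directly.
#'
#' @param n Cohort size (positive integer).
#' @param tumor_probs Named numeric vector/list over the nine tumour types
#'   (see [tumor_categories()]). Missing categories default to 0.
#' @param sex_given_tumor Named numeric vector/list: probability of *male*
#'   sex given each tumour type. Must be 0 for breast, endometrial and
#'   ovarian tumours. Missing categories default to the reference values.
#' @param origin_probs Named numeric vector/list over the three origins.
#' @param ecog_probs Named numeric vector/list over ECOG-PS `"0"`, `"1"`, `"2"`.
#' @param age_targets Named list with elements `male_nonsarcoma`,
#'   `male_sarcoma`, `female_nonsarcoma`, `female_sarcoma`; each either
#'   `list(mean=, sd=)` moment targets (years) or explicit
#'   `list(shape=, scale=)` Weibull parameters.
#' @param age_bounds Truncation bounds for age in years, default `c(18, 95)`
#'   (adult oncology cohort).
#' @param seed Integer seed stored with the spec and used by
#'   [sample_primaries()].
#'
#' @return An object of class `population_spec`.
#' @seealso [reference_population()], [sample_primaries()]
#' @export
population_spec <- function(n,
                            tumor_probs,
                            sex_given_tumor,
                            origin_probs,
                            ecog_probs,
                            age_targets,
                            age_bounds = c(18, 95),
                            seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop_config("cohort size `n` must be a positive integer")
  }
  n <- as.integer(n)

  tumor_probs <- complete_map(tumor_probs, tumor_categories(), 0)
  tumor_probs <- renormalize_probs(tumor_probs, "tumor_probs")

  ref_sex <- reference_sex_given_tumor()
  sex_given_tumor <- complete_map(sex_given_tumor, tumor_categories(), ref_sex)
  sgt <- unlist(sex_given_tumor)[tumor_categories()]
  if (any(sgt < 0 | sgt > 1)) {
    stop_config("sex_given_tumor values must be probabilities in [0, 1]")
  }
  bad <- intersect(female_only_tumors(), names(sgt)[sgt > 0])
  if (length(bad)) {
    stop_config("sex_given_tumor must be 0 (always female) for: %s",
                paste(bad, collapse = ", "))
  }

  origin_probs <- complete_map(origin_probs, origin_categories(), 0)
  origin_probs <- renormalize_probs(origin_probs, "origin_probs")

  ecog_probs <- complete_map(ecog_probs, as.character(ecog_categories()), 0)
  ecog_probs <- renormalize_probs(ecog_probs, "ecog_probs")

  age_targets <- validate_age_targets(age_targets)

  if (!is.numeric(age_bounds) || length(age_bounds) != 2L ||
      age_bounds[1] >= age_bounds[2]) {
    stop_config("age_bounds must be c(low, high) with low < high")
  }

  structure(
    list(n = n,
         tumor_probs = tumor_probs,
         sex_given_tumor = sgt,
         origin_probs = origin_probs,
         ecog_probs = ecog_probs,
         age_targets = age_targets,
         age_bounds = as.numeric(age_bounds),
         seed = as.integer(seed)),
    class = "population_spec")
}

# fill a partial named map over `categories`; `default` is a scalar or a
# named vector of per-category defaults
complete_map <- function(x, categories, default) {
  x <- unlist(x)
  if (is.null(x)) x <- numeric(0)
  unknown <- setdiff(names(x), categories)
  if (length(unknown)) {
    stop_config("unknown category '%s' (valid: %s)", unknown[1L],
                paste(categories, collapse = ", "))
  }
  out <- if (length(default) == 1L) {
    stats::setNames(rep(as.numeric(default), length(categories)), categories)
  } else {
    default[categories]
  }
  out[names(x)] <- as.numeric(x)
  out
}

age_group_names <- function() {
  c("male_nonsarcoma", "male_sarcoma", "female_nonsarcoma", "female_sarcoma")
}

validate_age_targets <- function(age_targets) {
  need <- age_group_names()
  if (!is.list(age_targets)) stop_config("age_targets must be a list")
  missing <- setdiff(need, names(age_targets))
  if (length(missing)) {
    stop_config("age_targets missing group(s): %s",
                paste(missing, collapse = ", "))
  }
  out <- lapply(need, function(g) {
    t <- age_targets[[g]]
    if (all(c("shape", "scale") %in% names(t))) {
      weibull_params(t$shape, t$scale, group = g)
    } else if (all(c("mean", "sd") %in% names(t))) {
      if (t$mean <= 0 || t$sd <= 0) {
        stop_config("age_targets$%s: mean and sd must be positive", g)
      }
      list(mean = as.numeric(t$mean), sd = as.numeric(t$sd), group = g)
    } else {
      stop_config("age_targets$%s needs either (mean, sd) or (shape, scale)", g)
    }
  })
  stats::setNames(out, need)
}

# resolve a (mean, sd) target into Weibull parameters; pass-through if explicit
resolve_age_params <- function(target) {
  if (!is.null(target$shape)) return(target)
  p <- weibull_from_moments(target$mean, target$sd)
  p$group <- target$group
  p
}

#' Default male-given-tumour probabilities
#'
#' Conditional probability of male sex given tumour type, taken as the ratio
#' of the published sex-stratified counts of the source cohort (e.g. lung:
#' 513 males of 865; pancreatic: 43 of 66). Female-only tumours (breast,
#' endometrial, ovarian) are 0.
#'
#' @return Named numeric vector over [tumor_categories()].
#' @export
reference_sex_given_tumor <- function() {
  c(breast      = 0,
    colon       = 12 / 22,
    endometrial = 0,
    gastric     = 5 / 7,
    hepatic     = 9 / 16,
    lung        = 513 / 865,
    ovarian     = 0,
    pancreatic  = 43 / 66,
    sarcoma     = 33 / 70)
}

#' The reference oncology population
#'
#' The primary-variable composition of the training cohort the network was
#' developed on: 96/2/2% European/Sub-Saharan African/East Asian origin,
#' ECOG-PS 35/55/5% (printed percentages; renormalized), the nine-tumour mix
#' led by lung (48%) and ovarian (28%), sex fixed conditionally on tumour
#' type, and sex-specific Weibull age models moment-matched to mean (SD)
#' ages of 62.3 (9.3) years for males and 59.1 (11.2) for females.
#'
#' @param n Cohort size; defaults to the training-set size 1259.
#' @param seed Seed stored in the spec.
#' @return A [population_spec()].
#' @export
reference_population <- function(n = 1259, seed = 1L) {
  suppressMessages(population_spec(
    n = n,
    tumor_probs = c(breast = 0.07, colon = 0.01, endometrial = 0.07,
                    gastric = 0.01, hepatic = 0.01, lung = 0.48,
                    ovarian = 0.28, pancreatic = 0.04, sarcoma = 0.03),
    sex_given_tumor = reference_sex_given_tumor(),
    origin_probs = c("European" = 0.96, "Sub-Saharan African" = 0.02,
                     "East Asian" = 0.02),
    ecog_probs = c("0" = 0.35, "1" = 0.55, "2" = 0.05),
    age_targets = list(
      male_nonsarcoma   = list(mean = 62.3, sd = 9.3),
      male_sarcoma      = list(mean = 62.3, sd = 9.3),
      female_nonsarcoma = list(mean = 59.1, sd = 11.2),
      female_sarcoma    = list(mean = 59.1, sd = 11.2)),
    seed = seed))
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Population specification\n")
  cat(sprintf("  n = %d, seed = %d, age bounds [%g, %g] years\n",
              x$n, x$seed, x$age_bounds[1], x$age_bounds[2]))
  cat("  tumor:", paste(sprintf("%s %.3f", names(x$tumor_probs),
                                x$tumor_probs), collapse = ", "), "\n")
  cat("  origin:", paste(sprintf("%s %.3f", names(x$origin_probs),
                                 x$origin_probs), collapse = ", "), "\n")
  cat("  ECOG-PS:", paste(sprintf("%s %.3f", names(x$ecog_probs),
                                  x$ecog_probs), collapse = ", "), "\n")
  invisible(x)
}
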