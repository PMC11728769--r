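#' @title Primary-variable sampling
#' @description Samplers for the fixed variables of a virtual cohort. Tumour
#'   type, origin and ECOG-PS are multinomial draws; sex is Bernoulli
#'   conditional on tumour type; age is a truncated Weibull per
#'   (sex, sarcoma) group.
#' @name primary-sampling
NULL

#' Sample categories from a probability map
#'
#' Inverse-CDF multinomial sampling over the fixed category ordering given by
#' the names of `probs` (after renormalization), for platform-stable
#' reproducibility.
#'
#' @param probs Named probability map (renormalized internally).
#' @param n Number of draws.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Character vector of length `n`.
#' @export
sample_categories <- function(probs, n, seed = NULL) {
  p <- renormalize_probs(probs, "probability map")
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_config("n must be a positive integer")
  }
  with_seed(seed, {
    u <- stats::runif(n)
    names(p)[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
  })
}

#' Sample sex conditional on tumour type
#'
#' Sex probability is fixed by the observed tumour type: each patient's sex
#' is a Bernoulli draw with P(male) = `sex_given_tumor[tumor]`.
#'
#' @param tumors Character vector of tumour categories.
#' @param sex_given_tumor Named map tumour -> probability of male.
#' @param seed Optional seed.
#' @return Character vector `"male"`/`"female"` of the same length.
#' @export
sample_sex_given_tumor <- function(tumors,
                                   sex_given_tumor = reference_sex_given_tumor(),
                                   seed = NULL) {
  sgt <- unlist(sex_given_tumor)
  unknown <- setdiff(unique(tumors), names(sgt))
  if (length(unknown)) {
    stop_config("no sex probability for tumour category '%s'", unknown[1L])
  }
  p_male <- unname(sgt[tumors])
  with_seed(seed, {
    ifelse(stats::runif(length(tumors)) < p_male, "male", "female")
  })
}

#' Sample truncated Weibull ages
#'
#' Rejection sampling within `bounds`; draws falling outside are redrawn (up
#' to 1000 rounds), any stragglers are clamped to the nearer bound. Errors if
#' the bounds exclude more than 99% of the distribution's mass.
#'
#' @param params [weibull_params()] for the group.
#' @param n Number of draws.
#' @param bounds `c(low, high)` truncation bounds in years; use
#'   `c(0, Inf)` for untruncated sampling.
#' @param seed Optional seed.
#' @return Numeric vector of ages, all within `bounds`.
#' @export
sample_age <- function(params, n, bounds = c(18, 95), seed = NULL) {
  if (bounds[1] >= bounds[2]) stop_config("age bounds must satisfy low < high")
  mass <- stats::pweibull(bounds[2], params$shape, params$scale) -
    stats::pweibull(max(bounds[1], 0), params$shape, params$scale)
  if (mass < 0.01) {
    stop_config("age bounds [%g, %g] exclude %.1f%% of the distribution mass",
                bounds[1], bounds[2], 100 * (1 - mass))
  }
  with_seed(seed, {
    x <- stats::rweibull(n, params$shape, params$scale)
    bad <- which(x < bounds[1] | x > bounds[2])
    attempts <- 0L
    while (length(bad) && attempts < 1000L) {
      x[bad] <- stats::rweibull(length(bad), params$shape, params$scale)
      bad <- which(x < bounds[1] | x > bounds[2])
      attempts <- attempts + 1L
    }
    if (length(bad)) x[bad] <- pmin(pmax(x[bad], bounds[1]), bounds[2])
    x
  })
}

#' Sample the primary profiles of a cohort
#'
#' Sampling order: tumour type first, then sex conditional on tumour, then
#' origin, ECOG-PS and age independently. The age group is the (sex, sarcoma)
#' cell of the spec's `age_targets`; moment targets are resolved to Weibull
#' parameters once per group. Fully reproducible from `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A `data.frame` with columns `tumor`, `sex`, `origin`, `ecog`
#'   (integer) and `age` (years), `spec$n` rows.
#' @export
sample_primaries <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  seed <- seed %||% spec$seed
  params <- lapply(spec$age_targets, resolve_age_params)
  with_seed(seed, {
    n <- spec$n
    tumor <- sample_categories(spec$tumor_probs, n)
    sex <- sample_sex_given_tumor(tumor, spec$sex_given_tumor)
    origin <- sample_categories(spec$origin_probs, n)
    ecog <- as.integer(sample_categories(spec$ecog_probs, n))
    group <- paste0(sex, "_", ifelse(tumor == "sarcoma",
                                     "sarcoma", "nonsarcoma"))
    age <- numeric(n)
    for (g in unique(group)) {
      idx <- which(group == g)
      age[idx] <- sample_age(params[[g]], length(idx), spec$age_bounds)
    }
    data.frame(tumor = tumor, sex = sex, origin = origin, ecog = ecog,
               age = age, stringsAsFactors = FALSE)
  })
}
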