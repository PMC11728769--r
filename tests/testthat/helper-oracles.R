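# Independent hand-written evaluation of the ten network equations,
# transcribed directly from the published table (kept separate from the
# package's term machinery so it can serve as its oracle).

oracle_stage_means <- function(d) {
  female <- d$sex == "female"
  ssa <- d$origin == "Sub-Saharan African"
  eur <- d$origin == "European"
  e1 <- d$ecog == 1
  e2 <- d$ecog == 2
  phg <- d$tumor %in% c("pancreatic", "hepatic", "gastric")
  list(
    height = 179.9 - 0.16 * d$age - 12.81 * female + 6.42 * ssa + 3.83 * eur,
    weight = 2.10 + ifelse(female, 0.008, 0.012) * d$height +
      0.562 * female + 0.262 * ssa + 0.144 * eur,
    aag = 4.32 + 0.161 * e1 + 0.449 * e2 + 0.634 * ssa + 0.370 * eur +
      0.622 * (d$tumor == "ovarian"),
    albumin = 5.546 - 0.004 * d$age - 0.292 * log(d$aag) - 0.128 * e1 -
      0.429 * e2 + 0.276 * ssa + 0.248 * eur - 0.339 * phg,
    hb = 12.35 + 0.575 * d$albumin - 0.793 * log(d$aag) - 0.680 * female,
    nl_ratio = 1.47 - 0.0073 * log(d$aag) - 0.16 * d$albumin,
    pl_ratio = 5.52 - 0.057 * d$hb + 0.0016 * d$aag + 0.0622 * d$nl_ratio -
      0.204 * phg,
    crp = 1.394 + 0.002 * d$pl_ratio + 0.368 * e1 + 0.598 * e2 -
      2.22 * (d$tumor == "breast"),
    ldh = 5.709 + 0.001 * d$crp,
    htc = 5.93 + 0.04 * log(d$aag) + 2.515 * d$hb)
}

# random covariate environments on physiologic natural scales
random_covariates <- function(n) {
  data.frame(
    tumor = sample(tumor_categories(), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    origin = sample(origin_categories(), n, replace = TRUE),
    ecog = sample(0:2, n, replace = TRUE),
    age = runif(n, 20, 90),
    height = runif(n, 140, 200),
    weight = runif(n, 40, 120),
    aag = runif(n, 50, 400),
    albumin = runif(n, 2, 5.5),
    hb = runif(n, 7, 17),
    nl_ratio = runif(n, 1, 10),
    pl_ratio = runif(n, 80, 500),
    crp = runif(n, 0.5, 80),
    ldh = runif(n, 150, 900),
    stringsAsFactors = FALSE)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

zero_residuals <- function() {
  r <- default_residuals()
  r$sds[] <- 0
  r
}

# small simulated cohort for I/O and fitting tests
make_test_cohort <- function(n = 500, seed = 11, residuals = default_residuals()) {
  spec <- reference_population(n = n, seed = seed)
  simulate_cohort(sample_primaries(spec), default_coefficients(), residuals,
                  seed = seed + 1)
}
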