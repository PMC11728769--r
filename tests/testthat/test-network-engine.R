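# The regression cascade: stage means, residual sampling, full simulation.

coefs <- default_coefficients()
eqs <- setNames(coefs$equations,
                vapply(coefs$equations, function(e) e$response, character(1)))

test_that("stage means reproduce hand-computed values", {
  # height: 179.9 - 0.16*60 - 12.81 + 3.83
  expect_equal(
    stage_mean(eqs$height, list(age = 60, sex = "female",
                                origin = "European")),
    161.32, tolerance = 1e-12)
  # log AAG at all reference levels is the bare intercept
  expect_equal(
    stage_mean(eqs$aag, list(ecog = 0, origin = "East Asian",
                             tumor = "lung")),
    4.32, tolerance = 1e-12)
  # log AAG with every positive indicator active
  expect_equal(
    stage_mean(eqs$aag, list(ecog = 2, origin = "Sub-Saharan African",
                             tumor = "ovarian")),
    4.32 + 0.449 + 0.634 + 0.622, tolerance = 1e-12)
})

test_that("stage sampling at sd 0 is the exact back-transformed mean", {
  r0 <- zero_residuals()
  # log weight, male European of height 173: exp(2.10 + 0.012*173 + 0.144)
  w <- stage_sample(eqs$weight, list(height = 173, sex = "male",
                                     origin = "European"), r0)
  expect_equal(w, exp(4.320), tolerance = 1e-9)
  # female slope is 0.008 (0.012 - 0.004 interaction)
  wf <- stage_sample(eqs$weight, list(height = 173, sex = "female",
                                      origin = "European"), r0)
  expect_equal(wf, exp(2.10 + 0.008 * 173 + 0.562 + 0.144), tolerance = 1e-9)
  # log LDH at CRP 0
  ldh <- stage_sample(eqs$ldh, list(crp = 0), r0)
  expect_equal(ldh, exp(5.709), tolerance = 1e-9)
  # determinism at zero noise without any seed
  expect_identical(stage_sample(eqs$ldh, list(crp = 12), r0),
                   stage_sample(eqs$ldh, list(crp = 12), r0))
})

test_that("missing covariates raise errors naming stage and covariate", {
  expect_error(stage_mean(eqs$height, list(age = 60, sex = "female")),
               "stage 1.*origin")
  expect_error(stage_mean(eqs$albumin, list(age = 60)), "stage 4")
})

test_that("stage means agree with an independent symbolic oracle", {
  set.seed(123)
  d <- random_covariates(100)
  oracle <- oracle_stage_means(d)
  for (v in names(oracle)) {
    expect_equal(stage_mean(eqs[[v]], d), oracle[[v]], tolerance = 1e-12,
                 info = v)
  }
})

test_that("zero-noise simulation is a deterministic function of primaries", {
  spec <- reference_population(n = 400, seed = 5)
  prof <- sample_primaries(spec)
  a <- predict_cohort(prof)
  b <- predict_cohort(prof)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # HTC equals the stage-10 formula applied to the record's own AAG and Hb
  expect_equal(a$htc_pct,
               5.93 + 0.04 * log(a$aag_mg_dl) + 2.515 * a$hb_g_dl,
               tolerance = 1e-12)
  # BSA/BMI recomputable from the emitted columns
  expect_identical(a$bsa_m2, derive_bsa(a$height_cm, a$weight_kg))
  expect_identical(a$bmi_kg_m2, derive_bmi(a$height_cm, a$weight_kg))
  # all laboratory values strictly positive
  labs <- c("aag_mg_dl", "albumin_g_dl", "hb_g_dl", "nl_ratio", "pl_ratio",
            "crp_mg_l", "ldh_u_l", "htc_pct")
  for (v in labs) expect_true(all(a[[v]] > 0), info = v)
})

test_that("log-scale responses stay positive under heavy residual noise", {
  r <- default_residuals()
  r$sds[c("weight", "aag", "crp")] <- 2  # extreme noise
  r$policy[] <- "none"
  spec <- reference_population(n = 2000, seed = 31)
  coh <- simulate_cohort(sample_primaries(spec), coefs, r, seed = 32)
  expect_true(all(coh$weight_kg > 0))
  expect_true(all(coh$aag_mg_dl > 0))
  expect_true(all(coh$crp_mg_l > 0))
})

test_that("coefficient directions propagate exactly at zero noise", {
  base <- list(age = 60, sex = "male", origin = "European", ecog = 0,
               tumor = "lung")
  f <- modifyList(base, list(sex = "female"))
  expect_equal(stage_mean(eqs$height, base) - stage_mean(eqs$height, f),
               12.81, tolerance = 1e-12)
  e2 <- modifyList(base, list(ecog = 2))
  expect_equal(stage_mean(eqs$aag, e2) - stage_mean(eqs$aag, base),
               0.449, tolerance = 1e-12)
  br <- list(pl_ratio = 200, ecog = 0, tumor = "breast")
  ot <- modifyList(br, list(tumor = "lung"))
  expect_equal(stage_mean(eqs$crp, ot) - stage_mean(eqs$crp, br),
               2.22, tolerance = 1e-12)
})

test_that("ECOG-driven AAG ordering emerges in large simulated cohorts", {
  spec <- reference_population(n = 100000, seed = 77)
  coh <- simulate_cohort(sample_primaries(spec), coefs,
                         default_residuals(), seed = 78)
  m <- tapply(log(coh$aag_mg_dl), coh$ecog, mean)
  expect_true(m[["2"]] > m[["1"]] && m[["1"]] > m[["0"]])
})

test_that("body-size formulas match worked examples", {
  expect_equal(derive_bsa(165.0, 72.6), 1.824, tolerance = 5e-4)
  expect_equal(round(derive_bsa(165.0, 72.6), 1), 1.8)
  expect_equal(derive_bsa(60, 60), 1.0, tolerance = 1e-12)
  expect_equal(derive_bsa(173, 81), 1.973, tolerance = 5e-4)
  expect_equal(derive_bmi(100, 25), 25.0, tolerance = 1e-12)
  expect_equal(derive_bmi(165, 72.6), 26.67, tolerance = 5e-3)
  expect_equal(derive_bmi(173, 81), 27.06, tolerance = 5e-3)
  expect_error(derive_bsa(-1, 70), "positive")
  expect_error(derive_bmi(170, 0), "positive")
})

test_that("the literal log reading of the haematocrit stage is available", {
  log_net <- default_coefficients(htc_scale = "log")
  htc_eq <- log_net$equations[[10]]
  expect_identical(htc_eq$scale, "log")
  v <- stage_sample(htc_eq, list(aag = 100, hb = 12), zero_residuals())
  expect_equal(v, exp(5.93 + 0.04 * log(100) + 2.515 * 12), tolerance = 1e-9)
})
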