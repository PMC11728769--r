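# Stage-wise OLS refitting, stepwise selection, splitting, calibration.

coefs <- default_coefficients()

test_that("train/validation split sizes and determinism", {
  tab <- data.frame(x = 1:1793)
  s <- split_train_validation(tab, 0.7, seed = 1)
  expect_length(s$train, 1255)           # round(0.7 * 1793)
  expect_length(s$validation, 538)
  expect_length(intersect(s$train, s$validation), 0)
  expect_setequal(c(s$train, s$validation), 1:1793)

  s2 <- split_train_validation(data.frame(x = 1:10), 0.5, seed = 2)
  expect_length(s2$train, 5)
  expect_length(s2$validation, 5)

  expect_identical(split_train_validation(tab, 0.7, seed = 9),
                   split_train_validation(tab, 0.7, seed = 9))
  expect_error(split_train_validation(data.frame(x = 1:5), 0.7), "10 rows")
  expect_error(split_train_validation(tab, 1.2), "fraction")
})

test_that("a single-covariate exact line is recovered with zero residual", {
  eq <- equation_spec(1, "height", "linear", 0,
                      list(term_numeric("age", 0)))
  tab <- data.frame(age_years = c(0, 1, 2, 10, 20, 30, 40),
                    height_cm = 2 * c(0, 1, 2, 10, 20, 30, 40) + 1)
  f <- fit_stage(tab, eq)
  expect_equal(f$equation$intercept, 1, tolerance = 1e-10)
  expect_equal(f$equation$terms[[1]]$coef, 2, tolerance = 1e-10)
  expect_equal(f$residual_sd, 0, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("zero-noise simulation is inverted exactly by the network fit", {
  coh <- make_test_cohort(n = 3000, seed = 21, residuals = zero_residuals())
  fit <- fit_network(coh, coefs)
  for (i in seq_along(coefs$equations)) {
    gen <- coefs$equations[[i]]
    est <- fit$fits[[i]]$equation
    expect_equal(est$intercept, gen$intercept, tolerance = 1e-8,
                 info = paste("stage", i, "intercept"))
    for (j in seq_along(gen$terms)) {
      expect_equal(est$terms[[j]]$coef, gen$terms[[j]]$coef,
                   tolerance = 1e-8,
                   info = paste("stage", i, "term", j))
    }
    expect_lt(fit$fits[[i]]$residual_sd, 1e-8)
  }
  # fit -> simulate round trip: extracted coefficients regenerate the data
  coefs2 <- coefficients_from_fit(fit)
  prof <- data.frame(tumor = coh$tumor, sex = coh$sex, origin = coh$origin,
                     ecog = coh$ecog, age = coh$age_years)
  coh2 <- predict_cohort(prof, coefs2)
  expect_equal(coh2$htc_pct, coh$htc_pct, tolerance = 1e-6)
})

test_that("noisy refits land within sampling error of the generators", {
  coh <- make_test_cohort(n = 20000, seed = 22)
  fit <- fit_network(coh, coefs)
  for (i in seq_along(coefs$equations)) {
    gen <- coefs$equations[[i]]
    f <- fit$fits[[i]]
    se <- f$std_errors
    expect_lt(abs(f$equation$intercept - gen$intercept) / se["(Intercept)"],
              4, label = paste("stage", i, "intercept z"))
    labels <- names(se)[-1]
    for (j in seq_along(gen$terms)) {
      z <- abs(f$equation$terms[[j]]$coef - gen$terms[[j]]$coef) /
        se[labels[j]]
      expect_lt(z, 4, label = paste("stage", i, labels[j], "z"))
    }
  }
})

test_that("coefficient error shrinks like 1/sqrt(n)", {
  ns <- c(1000, 10000, 100000)
  eq1 <- coefs$equations[[1]]
  err <- vapply(seq_along(ns), function(i) {
    # height-stage data built directly: mean + Gaussian(4 cm) residual
    mean(vapply(1:5, function(s) {
      spec <- reference_population(n = ns[i], seed = 100 * i + s)
      prof <- sample_primaries(spec)
      tab <- data.frame(tumor = prof$tumor, sex = prof$sex,
                        origin = prof$origin, ecog = prof$ecog,
                        age_years = prof$age)
      tab$height_cm <- with_seed_local(200 * i + s,
        stage_mean(eq1, prof) + rnorm(ns[i], 0, 4))
      f <- fit_stage(tab, eq1)
      abs(f$equation$terms[[1]]$coef - (-0.16)) # age slope
    }, numeric(1)))
  }, numeric(1))
  slope <- unname(coef(lm(log10(err) ~ log10(ns)))[2])
  expect_gt(slope, -0.7)
  expect_lt(slope, -0.3)
})

test_that("fitting uses observed covariates, not predicted ones", {
  coh <- make_test_cohort(n = 4000, seed = 24)
  f_before <- fit_stage(coh, coefs$equations[[3]])  # log AAG stage
  shuffled <- coh
  shuffled$crp_mg_l <- sample(shuffled$crp_mg_l)    # downstream response
  f_after <- fit_stage(shuffled, coefs$equations[[3]])
  expect_identical(f_before$equation, f_after$equation)
})

test_that("missing columns are reported by stage and name", {
  coh <- make_test_cohort(n = 600, seed = 25)
  coh$hb_g_dl <- NULL
  expect_error(fit_network(coh, coefs), "stage 5.*hb_g_dl")
})

test_that("rank-deficient designs name the collinear columns", {
  eq <- equation_spec(1, "height", "linear", 0, list(
    term_numeric("age", 1), term_numeric("age", 0)))
  tab <- data.frame(age_years = 1:30, height_cm = 1:30 + rnorm(30))
  expect_error(fit_stage(tab, eq), "collinear")
})

test_that("stepwise selection keeps true terms and drops decoys", {
  set.seed(301)
  n <- 20000
  spec <- reference_population(n = n, seed = 301)
  coh <- simulate_cohort(sample_primaries(spec), coefs,
                         default_residuals(), seed = 302)
  # height stage with a decoy covariate whose generating coefficient is zero
  template <- equation_spec(1, "height", "linear", 0, list(
    term_numeric("age", 0),
    term_indicator("sex", "female", 0),
    term_indicator("origin", "Sub-Saharan African", 0),
    term_indicator("origin", "European", 0),
    term_indicator("tumor", "colon", 0)))  # decoy: no effect on height
  sel <- stepwise_select(coh, template, criterion = "AIC")
  kept <- vapply(sel$equation$terms, oncopop:::term_label, character(1))
  expect_true("age" %in% kept)
  expect_true("sex=female" %in% kept)
  expect_false("tumor=colon" %in% kept)
})

test_that("stepwise returns intercept-only under a null truth, with notice", {
  set.seed(303)
  tab <- data.frame(age_years = runif(5000, 20, 80),
                    height_cm = rnorm(5000, 165, 5))
  template <- equation_spec(1, "height", "linear", 0,
                            list(term_numeric("age", 0)))
  expect_message(sel <- stepwise_select(tab, template, criterion = "BIC"),
                 "intercept-only")
  expect_length(sel$equation$terms, 0)
})

test_that("residual calibration hits a marginal sd target and saturates", {
  spec <- reference_population(n = 10000, seed = 41)
  targets <- c(height = 9.0)
  cal <- calibrate_residuals(coefs, spec, targets, n_sim = 10000, seed = 41)
  coh <- simulate_cohort(sample_primaries(spec), coefs, cal, seed = 42)
  expect_equal(sd(coh$height_cm), 9.0, tolerance = 0.05)

  # a target below the sd induced by upstream variability alone saturates
  base <- simulate_cohort(sample_primaries(spec), coefs, zero_residuals(),
                          seed = 43)
  low_target <- c(height = sd(base$height_cm) * 0.5)
  expect_message(
    cal2 <- calibrate_residuals(coefs, spec, low_target, n_sim = 10000,
                                seed = 44),
    "saturated")
  expect_equal(unname(cal2$sds["height"]), 0)
})
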