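# Sampling of the fixed variables: tumour, sex|tumour, origin, ECOG, age.

test_that("category sampling respects degenerate and renormalized maps", {
  expect_identical(sample_categories(c(lung = 1), 5, seed = 1),
                   rep("lung", 5))
  # printed ECOG percentages sum to 95; maps are renormalized before use
  expect_message(p <- renormalize_probs(c("0" = 0.35, "1" = 0.55, "2" = 0.05),
                                        "ecog"),
                 "renormalized")
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p), c(35, 55, 5) / 95, tolerance = 1e-12)
  # idempotence: renormalizing a normalized map changes nothing
  expect_silent(p2 <- renormalize_probs(p, "ecog"))
  expect_equal(p2, p, tolerance = 0)
})

test_that("category sampling rejects invalid maps", {
  expect_error(sample_categories(c(a = -0.1, b = 1.1), 5), "negative")
  expect_error(sample_categories(c(a = 0, b = 0), 5), "zero")
  expect_error(sample_categories(numeric(0), 5), "empty")
})

test_that("empirical origin counts match binomial expectation", {
  # reference origins: P(European) = 0.96; at n = 1200 the European count
  # has mean 1152 and sd sqrt(1200 * .96 * .04) = 6.79; a fixed seed should
  # land within 4 sd
  draws <- sample_categories(
    c("European" = 0.96, "Sub-Saharan African" = 0.02, "East Asian" = 0.02),
    1200, seed = 2024)
  count <- sum(draws == "European")
  expect_true(abs(count - 1152) <= 4 * sqrt(1200 * 0.96 * 0.04))
})

test_that("sex is fixed conditionally on tumour type", {
  expect_identical(
    sample_sex_given_tumor(rep("breast", 50), seed = 3),
    rep("female", 50))
  # male fraction given lung converges to the published count ratio 513/865
  lung <- sample_sex_given_tumor(rep("lung", 40000), seed = 4)
  expect_equal(mean(lung == "male"), 513 / 865, tolerance = 0.02)
  panc <- sample_sex_given_tumor(rep("pancreatic", 40000), seed = 5)
  expect_equal(mean(panc == "male"), 43 / 66, tolerance = 0.02)
  expect_error(sample_sex_given_tumor("brain"), "brain")
})

test_that("female-only tumours never yield males, any seed", {
  for (s in 1:5) {
    spec <- suppressMessages(population_spec(
      n = 300,
      tumor_probs = c(breast = 0.4, endometrial = 0.3, ovarian = 0.3),
      sex_given_tumor = reference_sex_given_tumor(),
      origin_probs = c("European" = 1),
      ecog_probs = c("0" = 1),
      age_targets = list(male_nonsarcoma = list(mean = 62.3, sd = 9.3),
                         male_sarcoma = list(mean = 62.3, sd = 9.3),
                         female_nonsarcoma = list(mean = 59.1, sd = 11.2),
                         female_sarcoma = list(mean = 59.1, sd = 11.2)),
      seed = s))
    prof <- sample_primaries(spec)
    expect_true(all(prof$sex == "female"))
  }
})

test_that("population_spec rejects male probability for female-only tumours", {
  sgt <- reference_sex_given_tumor()
  sgt["ovarian"] <- 0.5
  expect_error(
    population_spec(10, c(lung = 1), sgt, c("European" = 1), c("0" = 1),
                    age_targets = reference_population()$age_targets),
    "ovarian")
})

test_that("Weibull moment matching solves the stated special cases", {
  # cv = 1 is the exponential: shape 1, scale = mean
  p <- weibull_from_moments(40, 40)
  expect_equal(p$shape, 1, tolerance = 1e-8)
  expect_equal(p$scale, 40, tolerance = 1e-6)
  # cohort age summaries round-trip to 1e-6 relative
  for (t in list(c(62.3, 9.3), c(59.1, 11.2))) {
    m <- weibull_moments(weibull_from_moments(t[1], t[2]))
    expect_equal(unname(m["mean"]), t[1], tolerance = 1e-6)
    expect_equal(unname(m["sd"]), t[2], tolerance = 1e-6)
  }
  expect_error(weibull_from_moments(10, 60), "cv")
  expect_error(weibull_from_moments(-1, 2), "positive")
})

test_that("truncated age sampling respects bounds and moments", {
  # large shape concentrates at the scale
  x <- sample_age(weibull_params(5000, 60), 500, bounds = c(0, Inf), seed = 6)
  expect_true(all(abs(x - 60) < 1))
  # untruncated sample mean approaches the analytic mean
  p <- weibull_from_moments(62.3, 9.3)
  x <- sample_age(p, 100000, bounds = c(0, Inf), seed = 7)
  expect_equal(mean(x), 62.3, tolerance = 0.2 / 62.3)
  # truncation contract
  x <- sample_age(p, 5000, bounds = c(18, 95), seed = 8)
  expect_gte(min(x), 18)
  expect_lte(max(x), 95)
  # bounds excluding nearly all mass are refused
  expect_error(sample_age(p, 10, bounds = c(200, 300)), "mass")
})

test_that("full primary sampling is reproducible and hits the tumour mix", {
  spec <- reference_population(n = 2000, seed = 99)
  a <- sample_primaries(spec)
  b <- sample_primaries(spec)
  expect_identical(a, b)

  only_ov <- build_scenario("only_ovarian", n = 200, seed = 1)
  prof <- sample_primaries(only_ov)
  expect_true(all(prof$tumor == "ovarian"))
  expect_true(all(prof$sex == "female"))

  big <- reference_population(n = 100000, seed = 12)
  prof <- sample_primaries(big)
  expect_equal(mean(prof$tumor == "ovarian"), 0.28, tolerance = 0.01 / 0.28)
  expect_true(all(prof$age >= 18 & prof$age <= 95))
})

test_that("moment-matching round trip holds across random targets", {
  set.seed(42)
  for (i in 1:1000) {
    mean <- runif(1, 5, 100)
    cv <- runif(1, 0.05, 0.9)
    sd <- cv * mean
    m <- weibull_moments(weibull_from_moments(mean, sd))
    expect_lt(abs(m["mean"] - mean) / mean, 1e-6)
    expect_lt(abs(m["sd"] - sd) / sd, 1e-6)
  }
})
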