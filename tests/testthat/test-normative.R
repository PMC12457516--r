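test_that("noiseless linear age effect is recovered exactly", {
  regs <- toy_region_set(1)
  coefs <- data.frame(region = regs$name, intercept = 2.5, age_lin = 0.5,
                      age_quad = 0, sex_effect = 0.1, noise_sd = 1e-10)
  cfg <- cohort_config(n_per_site = c(a = 80, b = 80), seed = 31)
  ref <- generate_reference_cohort(cohort_config(n_per_site = c(a = 80, b = 80),
                                                 coefs = coefs, seed = 31), regs)
  fit <- fit_normative(ref, model_spec(basis = "poly", degree = 1))
  # recovered slope = difference in predicted mean over one decade of age
  meta <- data.frame(subject_id = c("p1", "p2"), age = c(60, 70), sex = 0L,
                     site = "a", diagnosis = "CN", severity = NA_real_)
  pred <- normdev:::predict_normative(fit, meta)
  slope <- diff(pred$mu(regs$name[1]))   # per decade
  expect_equal(slope, 0.5, tolerance = 1e-6)
})

test_that("fitted slope agrees with the lm oracle and covers the truth", {
  regs <- toy_region_set(1)
  hits <- 0L
  for (rep in 1:100) {
    coefs <- data.frame(region = regs$name, intercept = 0, age_lin = 0.5,
                        age_quad = 0, sex_effect = 0, noise_sd = 1)
    cfg <- cohort_config(n_per_site = c(a = 500), coefs = coefs, seed = 1000 + rep)
    ref <- generate_reference_cohort(cfg, regs)
    fit <- fit_normative(ref, model_spec(basis = "poly", degree = 1,
                                         variance = "pooled"))
    dec <- (ref$age - 65) / 10
    lmfit <- lm(ref$region_01 ~ dec + ref$sex)
    meta <- data.frame(subject_id = c("p1", "p2"), age = c(60, 70), sex = 0L,
                       site = "a", diagnosis = "CN", severity = NA_real_)
    slope <- diff(normdev:::predict_normative(fit, meta)$mu(regs$name[1]))
    expect_equal(slope, unname(coef(lmfit)["dec"]), tolerance = 1e-8)
    se <- summary(lmfit)$coefficients["dec", "Std. Error"]
    if (abs(slope - 0.5) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("warped fit on Gaussian data recovers a null warp", {
  regs <- toy_region_set(1)
  coefs <- data.frame(region = regs$name, intercept = 2.5, age_lin = -0.04,
                      age_quad = 0, sex_effect = 0.05, noise_sd = 0.2)
  cfg <- cohort_config(n_per_site = c(a = 5000), coefs = coefs, seed = 37)
  ref <- generate_reference_cohort(cfg, regs)
  fit <- fit_normative(ref, model_spec(warp = "sinh-arcsinh"))
  w <- fit$fits$region_01$warp
  expect_lt(abs(w[["eps"]]), 0.1)
  expect_lt(abs(w[["delta"]] - 1), 0.15)
  # likelihood trace is monotone non-decreasing
  expect_true(all(diff(fit$fits$region_01$loglik_trace) > -1e-6))
})

test_that("degenerate designs are rejected with the offending column named", {
  regs <- toy_region_set(1)
  cfg <- cohort_config(n_per_site = c(a = 100), sex_ratio = 0, seed = 2)
  ref <- generate_reference_cohort(cfg, regs)   # sex constant = 0
  expect_error(fit_normative(ref, model_spec()), "sex")
})

test_that("self-adaptation is a no-op and known site effects are recovered", {
  fx <- fixture_fit()
  regs <- fx$regions
  # adaptation drawn from a reference site with no shift: shift ~ 0 and
  # scale ~ 1. At n = 200 the scale estimate has ~5% standard error, so the
  # 0.1 band is a two-sigma statement: check it in aggregate over seeds.
  scales <- shifts <- c()
  for (s in c(41, 141, 241, 341)) {
    self <- generate_reference_cohort(
      cohort_config(n_per_site = c(a = 200), site_offset = c(a = 0.05), seed = s),
      regs, stage = "selfadapt")
    ad <- adapt_to_site(fx$params, self, estimator = "moment")
    scales <- c(scales, vapply(ad$adaptation, `[[`, numeric(1), "scale"))
    shifts <- c(shifts, vapply(ad$adaptation, `[[`, numeric(1), "shift"))
  }
  expect_true(all(abs(shifts) < 0.1))
  expect_gte(mean(abs(scales - 1) < 0.1), 0.85)
  expect_true(all(abs(scales - 1) < 0.2))
  # unseen target site with +3 offset
  tgt <- generate_reference_cohort(
    cohort_config(n_per_site = c(zz = 200), site_offset = c(zz = 3), seed = 43),
    regs, stage = "offsetadapt")
  ad3 <- adapt_to_site(fx$params, tgt)
  for (r in regs$name) expect_lt(abs(ad3$adaptation[[r]]$shift - 3), 0.2)
  expect_error(adapt_to_site(fx$params, new_subject_table(self[1, ], regs)),
               ">= 2")
})

test_that("doubling target-site noise doubles the adaptation scale", {
  fx <- fixture_fit()
  regs <- fx$regions
  mk <- function(sd_mult, seed) {
    coefs <- default_growth_coefs(regs)
    coefs$noise_sd <- coefs$noise_sd * sd_mult
    generate_reference_cohort(
      cohort_config(n_per_site = c(zz = 500), coefs = coefs, seed = seed),
      regs, stage = "scaleadapt")
  }
  s1 <- adapt_to_site(fx$params, mk(1, 47))$adaptation
  s2 <- adapt_to_site(fx$params, mk(2, 47))$adaptation
  for (r in regs$name) {
    expect_lt(abs(s2[[r]]$scale / s1[[r]]$scale - 2), 0.3)   # 15% of 2
  }
})

test_that("z-scores obey the closed-form arithmetic contract", {
  fx <- fixture_fit()
  regs <- fx$regions
  params <- fx$params
  # pin one region to known parameters: mean 2.50 everywhere, total scale 0.50
  params$fits$region_01$beta[] <- 0
  params$fits$region_01$beta[["(Intercept)"]] <- 2.5
  params$fits$region_01$sigma[] <- 0.5
  adaptation <- lapply(params$fits, function(f) list(shift = 0, scale = 1, n = 2))
  adapted <- structure(c(unclass(params),
                         list(adaptation = adaptation, estimator = "moment")),
                       class = c("adapted_params", "normative_params"))
  tab <- generate_reference_cohort(
    cohort_config(n_per_site = c(a = 3), seed = 5), regs, stage = "ztest")
  tab$region_01 <- c(1.52, 2.50, 3.48)
  z <- compute_zscores(adapted, tab)$z[, "region_01"]
  expect_equal(unname(z), c(-1.96, 0, 1.96), tolerance = 1e-12)
})

test_that("warp = none z-scores equal the explicit standardized residual", {
  fx <- fixture_fit()
  regs <- fx$regions
  tgt <- generate_reference_cohort(
    cohort_config(n_per_site = c(zz = 50), site_offset = c(zz = 0.3), seed = 53),
    regs, stage = "warpnone")
  ad <- adapt_to_site(fx$params, tgt)
  test <- generate_reference_cohort(
    cohort_config(n_per_site = c(zz = 40), site_offset = c(zz = 0.3), seed = 59),
    regs, stage = "warpnone2")
  dev <- compute_zscores(ad, test)
  pred <- normdev:::predict_normative(ad, test)
  for (r in regs$name) {
    a <- ad$adaptation[[r]]
    manual <- (feature_matrix(test)[, r] - pred$mu(r) - a$shift) /
      (pred$sigma(r) * a$scale)
    expect_equal(unname(dev$z[, r]), unname(manual), tolerance = 1e-10)
  }
})

test_that("held-out healthy z-scores are calibrated to the standard normal", {
  regs <- toy_region_set(5)
  ref <- generate_reference_cohort(
    cohort_config(n_per_site = c(a = 1500, b = 1500),
                  site_offset = c(a = 0.05, b = -0.05), seed = 61), regs)
  params <- fit_normative(ref, model_spec())
  tgt_cfg <- function(n, stage, seed) generate_reference_cohort(
    cohort_config(n_per_site = c(zz = n), site_offset = c(zz = 0.1), seed = seed),
    regs, stage = stage)
  ad <- adapt_to_site(params, tgt_cfg(1000, "cal-adapt", 67), estimator = "moment")
  dev <- compute_zscores(ad, tgt_cfg(1500, "cal-test", 71))
  expect_lt(abs(mean(dev$z)), 0.05)       # 7,500 draws
  expect_lt(abs(sd(dev$z) - 1), 0.05)
})

test_that("adding a constant to a target site moves the shift and leaves z unchanged", {
  regs <- toy_region_set(2)
  coefs <- data.frame(region = regs$name, intercept = 2.5, age_lin = -0.04,
                      age_quad = 0, sex_effect = 0.05, noise_sd = 1e-9)
  ref <- generate_reference_cohort(
    cohort_config(n_per_site = c(a = 60, b = 60), coefs = coefs, seed = 73), regs)
  params <- fit_normative(ref, model_spec())
  base <- generate_reference_cohort(
    cohort_config(n_per_site = c(zz = 30), coefs = coefs,
                  noise_sd = 0.2, seed = 79), regs, stage = "eq")
  shifted <- base
  for (r in regs$name) shifted[[r]] <- shifted[[r]] + 5
  ad0 <- adapt_to_site(params, base)
  ad5 <- adapt_to_site(params, shifted)
  for (r in regs$name) {
    expect_equal(ad5$adaptation[[r]]$shift, ad0$adaptation[[r]]$shift + 5,
                 tolerance = 1e-6)
  }
  z0 <- compute_zscores(ad0, base)$z
  z5 <- compute_zscores(ad5, shifted)$z
  expect_equal(z0, z5, tolerance = 1e-6)
})

test_that("z-scores increase strictly with the raw value (both warp modes)", {
  fx <- fixture_fit()
  regs <- fx$regions
  tgt <- generate_reference_cohort(
    cohort_config(n_per_site = c(zz = 100), seed = 83), regs, stage = "mono")
  ad <- adapt_to_site(fx$params, tgt)
  probe <- new_subject_table(tgt[rep(1, 9), ], regs)
  probe$subject_id <- paste0("p", 1:9)
  probe$region_01 <- seq(1.5, 3.5, length.out = 9)
  expect_true(all(diff(compute_zscores(ad, probe)$z[, "region_01"]) > 0))

  # warped path: monotone too
  ref <- generate_reference_cohort(
    cohort_config(n_per_site = c(a = 800), skew = 0.3, seed = 89),
    toy_region_set(1))
  wfit <- fit_normative(ref, model_spec(warp = "sinh-arcsinh"))
  adw <- adapt_to_site(wfit, new_subject_table(ref[1:50, ], toy_region_set(1)))
  probe2 <- new_subject_table(ref[rep(1, 9), ], toy_region_set(1))
  probe2$subject_id <- paste0("q", 1:9)
  probe2$region_01 <- seq(1.5, 3.5, length.out = 9)
  expect_true(all(diff(compute_zscores(adw, probe2)$z[, "region_01"]) > 0))
})

test_that("missing regions and covariates are reported by name", {
  fx <- fixture_fit()
  regs6 <- toy_region_set(6)
  tab <- generate_reference_cohort(cohort_config(n_per_site = c(a = 10), seed = 3),
                                   regs6, stage = "missing")
  expect_error(adapt_to_site(fx$params, tab), "region_06")
  tgt <- generate_reference_cohort(cohort_config(n_per_site = c(a = 10), seed = 3),
                                   fx$regions, stage = "cov")
  ad <- adapt_to_site(fx$params, tgt)
  broken <- tgt
  broken$age <- NULL
  expect_error(compute_zscores(ad, broken), "age")
})
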