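test_that("the profiled fitter agrees with lme4 on ML and REML fits", {
  skip_if_not_installed("lme4")
  set.seed(51)
  d <- simulate_lmm_data(24, b_psi = -0.3, b_caregiver = -0.4, b_time = 0.1,
                         seed = 51)
  fit <- synchrony_lmm(d, "lam_det", standardize = FALSE)
  psi_std <- (d$psi_total - mean(d$psi_total)) / sd(d$psi_total)
  lf <- lme4::lmer(lam_det ~ psi_std + I(caregiver == "father") +
                     I(timepoint == "T2") + (1 | subject_id),
                   data = d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(fit$varcomp["subject"]), vc$vcov[1], tolerance = 1e-4)
  expect_equal(unname(fit$varcomp["residual"]), vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$coefficients$se),
               unname(summary(lf)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)

  fr <- synchrony_lmm(d, "lam_det", standardize = FALSE, reml = TRUE)
  lr <- lme4::lmer(lam_det ~ psi_std + I(caregiver == "father") +
                     I(timepoint == "T2") + (1 | subject_id),
                   data = d, REML = TRUE)
  vcr <- as.data.frame(lme4::VarCorr(lr))
  expect_equal(unname(fr$varcomp["subject"]), vcr$vcov[1], tolerance = 1e-4)
  expect_equal(unname(coef(fr)), unname(lme4::fixef(lr)), tolerance = 1e-5)
})

test_that("adding a constant to the response shifts only the intercept", {
  d <- simulate_lmm_data(12, b_psi = 0.2, seed = 52)
  f1 <- synchrony_lmm(d, "lam_det", standardize = FALSE)
  d2 <- d
  d2$lam_det <- d2$lam_det + 10
  f2 <- synchrony_lmm(d2, "lam_det", standardize = FALSE)
  expect_equal(coef(f2)[["(Intercept)"]], coef(f1)[["(Intercept)"]] + 10,
               tolerance = 1e-6)
  expect_equal(coef(f2)[-1], coef(f1)[-1], tolerance = 1e-6)
  expect_equal(f2$varcomp, f1$varcomp, tolerance = 1e-6)
})

test_that("likelihood-ratio comparison follows the chi-squared reference", {
  d <- simulate_lmm_data(15, seed = 53)
  full <- synchrony_lmm(d, "lam_det")
  base <- synchrony_lmm(d, "lam_det", include_stress = FALSE)
  cmp <- lrt_compare(full, base)
  expect_gte(cmp$chi2, 0)
  expect_equal(cmp$df_diff, 1)
  expect_equal(cmp$p_lrt, pchisq(cmp$chi2, 1, lower.tail = FALSE))
  # identical models give a null comparison
  same <- lrt_compare(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_lrt, 1)
  # the observed statistic of the selected model maps to its printed p
  expect_equal(round(pchisq(7.034, 1, lower.tail = FALSE), 3), 0.008)
  expect_error(lrt_compare(base, full), "not nested")
  expect_error(lrt_compare(synchrony_lmm(d, "lam_det", reml = TRUE), base),
               "requires ML")
})

test_that("LRT is invariant to affine rescaling of the response", {
  d <- simulate_lmm_data(14, b_psi = -0.4, seed = 54)
  chi2_of <- function(dd) {
    f <- synchrony_lmm(dd, "lam_det", standardize = FALSE)
    b <- synchrony_lmm(dd, "lam_det", include_stress = FALSE,
                       standardize = FALSE)
    lrt_compare(f, b)$chi2
  }
  d2 <- d
  d2$lam_det <- 3 * d2$lam_det - 7
  expect_equal(chi2_of(d), chi2_of(d2), tolerance = 1e-5)
})

test_that("null LRT p-values are approximately uniform", {
  set.seed(55)
  pvals <- vapply(1:150, function(i) {
    d <- simulate_lmm_data(20, seed = 60000 + i)
    de <- dyadsync:::build_design(d, "lam_det")
    ff <- dyadsync:::lmm_fit_core(de$y, de$Xf, de$cluster)
    fb <- dyadsync:::lmm_fit_core(de$y, de$Xb, de$cluster)
    pchisq(max(0, 2 * (ff$loglik - fb$loglik)), 1, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a planted stress coefficient is recovered without bias", {
  set.seed(56)
  est <- vapply(1:200, function(i) {
    d <- simulate_lmm_data(26, b_psi = -0.2, seed = 70000 + i)
    de <- dyadsync:::build_design(d, "lam_det")
    # truth is on the raw dv scale; undo the internal z-scoring
    dyadsync:::lmm_fit_core(de$y, de$Xf, de$cluster)$beta[["psi_std"]] *
      sd(d$lam_det)
  }, numeric(1))
  expect_lt(abs(mean(est) + 0.2), 0.05)
})

test_that("marginal R2 covers the degenerate and exact cases", {
  d <- simulate_lmm_data(15, seed = 57)
  # no fixed effects beyond noise: R2m near 0
  f0 <- synchrony_lmm(d, "lam_det")
  expect_lt(marginal_r2(f0), 0.15)
  # noiseless response equal to the fixed predictor: R2m -> 1
  d$lam_det <- 2 * (d$caregiver == "father") - (d$timepoint == "T2")
  f1 <- suppressWarnings(synchrony_lmm(d, "lam_det", standardize = FALSE))
  expect_gt(marginal_r2(f1), 0.99)
  # Nakagawa-Schielzeth identity on a generic fit
  f2 <- synchrony_lmm(simulate_lmm_data(20, b_psi = 0.5, seed = 58),
                      "lam_det")
  expect_equal(marginal_r2(f2),
               var(f2$fitted) / (var(f2$fitted) + sum(f2$varcomp)))
})

test_that("CR2 robust inference matches model-based inference when well specified", {
  set.seed(59)
  ratio <- vapply(1:100, function(i) {
    d <- simulate_lmm_data(20, b_psi = 0.2, seed = 80000 + i)
    f <- synchrony_lmm(d, "lam_det")
    cr <- cr2_inference(f)
    cr$se[2] / f$coefficients$se[2]
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.15)

  d1 <- simulate_lmm_data(3, seed = 60)
  f1 <- suppressWarnings(synchrony_lmm(d1, "lam_det"))
  expect_error(cr2_inference(f1), "at least 4 clusters")
})

test_that("CR2 keeps nominal size under cluster-correlated heteroskedastic noise", {
  set.seed(61)
  n <- 250
  rej_cr2 <- logical(n)
  for (i in 1:n) {
    d <- simulate_lmm_data(20, seed = 90000 + i)
    # heteroskedastic, cluster-correlated contamination unrelated to psi
    cl_scale <- rep(exp(rnorm(20, 0, 0.7)), each = 4)
    d$lam_det <- d$lam_det * cl_scale
    f <- suppressWarnings(synchrony_lmm(d, "lam_det"))
    rej_cr2[i] <- cr2_inference(f)$p[2] < 0.05
  }
  expect_gte(mean(rej_cr2), 0.01)
  expect_lte(mean(rej_cr2), 0.09)
})

test_that("assumption checks are deterministic and detect heavy tails", {
  d <- simulate_lmm_data(26, seed = 62)
  f <- synchrony_lmm(d, "lam_det")
  expect_identical(check_assumptions(f), check_assumptions(f))
  a <- check_assumptions(f)
  expect_type(a$residual_normality, "logical")

  set.seed(63)
  hits <- vapply(1:60, function(i) {
    dd <- simulate_lmm_data(26, residual_sd = 1e-6, seed = 95000 + i)
    dd$lam_det <- dd$lam_det + rt(nrow(dd), df = 2)
    fh <- suppressWarnings(synchrony_lmm(dd, "lam_det"))
    !check_assumptions(fh)$residual_normality
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("simulate() reproduces the fitted variance structure", {
  d <- simulate_lmm_data(30, b_psi = -0.3, intercept_sd = 0.8, seed = 64)
  f <- synchrony_lmm(d, "lam_det")
  sims <- simulate(f, nsim = 200, seed = 1)
  expect_equal(dim(sims), c(120, 200))
  # total variance of simulated responses matches the model-implied total
  tot <- var(as.vector(sims))
  expect_equal(tot, var(f$fitted) + sum(f$varcomp), tolerance = 0.15)
  expect_identical(simulate(f, nsim = 2, seed = 9),
                   simulate(f, nsim = 2, seed = 9))
})
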