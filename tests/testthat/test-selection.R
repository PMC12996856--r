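test_that("Bonferroni threshold reporting", {
  b <- bonferroni_threshold(0.05, 32)
  expect_equal(b$raw, 0.0015625)
  expect_equal(b$reported, 0.002)
  expect_equal(bonferroni_threshold(0.05, 1)$raw, 0.05)
  expect_equal(bonferroni_threshold(0.05, 10)$raw, 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "n_models")
})

test_that("FWE simulation matches the independence closed form", {
  configs <- list(list(n = 32, a = c(0.05, 0.05)),
                  list(n = 10, a = c(0.1, 0.5)),
                  list(n = 32, a = c(0.05, 0.05, 0.05, 0.05)))
  for (cf in configs) {
    f <- fwe_simulation(cf$n, cf$a, n_iter = 20000, seed = 2)
    expect_true(all(abs(f$prob - f$analytic) <= 3 * pmax(f$mc_se, 1e-4) +
                      1e-9))
    # survival probability non-increasing in gate depth
    expect_true(all(diff(f$prob) <= 0))
  }
  # an impossible first gate kills every depth
  z <- fwe_simulation(5, c(0, 0.5), n_iter = 2000, seed = 3)
  expect_true(all(z$prob == 0))
  # determinism
  expect_identical(fwe_simulation(8, c(0.1, 0.1), 5000, seed = 7)$prob,
                   fwe_simulation(8, c(0.1, 0.1), 5000, seed = 7)$prob)
})

make_summaries <- function(rows) {
  sens <- do.call(rbind, lapply(rows, function(r)
    data.frame(feature = r$feature, ratio = r$ratio, p_anova = r$p_anova,
               p_dist = r$p_dist, p_stress = r$p_stress,
               p_stress_dist = r$p_stress_dist, stringsAsFactors = FALSE)))
  spec <- do.call(rbind, lapply(rows, function(r)
    data.frame(feature = r$feature, ratio = r$ratio, p_rand = r$p_rand,
               p_spec_model = r$p_spec_model,
               p_spec_stress = r$p_spec_stress, stringsAsFactors = FALSE)))
  list(sens = sens, spec = spec)
}

test_that("sequential gates reproduce the canonical pass/fail patterns", {
  rows <- list(
    # fully selected model: overall significant, specific, stress
    # significant and stress-specific (the third-MFCC pattern)
    list(feature = "mfcc3", ratio = "det_rec", p_anova = 0.010,
         p_dist = 0.0005, p_stress = 0.011, p_stress_dist = 0.0005,
         p_rand = 0.142, p_spec_model = 0.02, p_spec_stress = 0.03),
    # significant overall but significance persists under permutation:
    # fails the specificity gate
    list(feature = "logRelF0-H1-H2", ratio = "lam_det", p_anova = 0.036,
         p_dist = 0.0005, p_stress = 0.087, p_stress_dist = 0.3,
         p_rand = 0.012, p_spec_model = 0.3, p_spec_stress = 0.5),
    # nothing significant anywhere
    list(feature = "dull", ratio = "lam_det", p_anova = 1, p_dist = 1,
         p_stress = 1, p_stress_dist = 1, p_rand = 1, p_spec_model = 1,
         p_spec_stress = 1))
  ss <- make_summaries(rows)
  out <- sequential_gates(ss$sens, ss$spec)
  tab <- out$table[match(c("mfcc3", "logRelF0-H1-H2", "dull"),
                         out$table$feature), ]
  expect_equal(tab$gate1, c(TRUE, TRUE, FALSE))
  expect_equal(tab$gate2, c(TRUE, FALSE, FALSE))
  expect_equal(tab$gate3, c(TRUE, FALSE, FALSE))
  expect_equal(tab$gate4, c(TRUE, FALSE, FALSE))
  expect_equal(out$survivors, c(gate1 = 2L, gate2 = 1L, gate3 = 1L,
                                gate4 = 1L))
  expect_equal(out$selected$feature, "mfcc3")
})

test_that("gates are monotone and missing summaries are reported", {
  set.seed(71)
  rows <- lapply(1:30, function(i)
    list(feature = paste0("f", i), ratio = "lam_det",
         p_anova = runif(1), p_dist = runif(1), p_stress = runif(1),
         p_stress_dist = runif(1), p_rand = runif(1),
         p_spec_model = runif(1), p_spec_stress = runif(1)))
  ss <- make_summaries(rows)
  out <- sequential_gates(ss$sens, ss$spec)
  with(out$table, {
    expect_true(all(gate1 | !gate2))
    expect_true(all(gate2 | !gate3))
    expect_true(all(gate3 | !gate4))
  })
  expect_true(all(diff(out$survivors) <= 0))
  expect_error(sequential_gates(ss$sens, ss$spec[-1, ]), "missing.*f1")
})

test_that("power simulation is calibrated under the null and monotone in effect size", {
  p0 <- power_simulation(b_psi = 0, b_caregiver = 0, b_time = 0,
                         n_subjects = 26, n_sim = 400, seed = 11)
  for (nm in names(p0$power)) {
    expect_gte(p0$power[[nm]], 0.02)
    expect_lte(p0$power[[nm]], 0.09)
  }
  grid <- vapply(c(0.1, 0.25, 0.5), function(b)
    power_simulation(b_psi = b, b_caregiver = 0, b_time = 0,
                     n_subjects = 26, n_sim = 300,
                     seed = 12)$power[["stress"]], numeric(1))
  expect_true(all(diff(grid) > 0))
  # at the conventional medium effect the design has usable power
  expect_gt(grid[2], 0.4)
  expect_lt(grid[2], 0.95)
})
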