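test_that("identical seeds give bit-identical studies", {
  a <- simulate_study(tiny_config(seed = 7))
  b <- simulate_study(tiny_config(seed = 7))
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_study(tiny_config(seed = 8))
  expect_false(identical(a$sessions[[1]]$frames, c_$sessions[[1]]$frames))

  n <- simulate_null_study(tiny_config(seed = 7))
  n2 <- simulate_null_study(tiny_config(seed = 7))
  expect_identical(n$sessions, n2$sessions)
})

test_that("study structure: four sessions per subject, valid schemas", {
  st <- simulate_study(tiny_config(seed = 1))
  expect_equal(length(st$sessions), 24)
  per_subj <- table(st$truth$subject_id)
  expect_true(all(per_subj == 4))
  expect_setequal(unique(st$truth$caregiver), c("mother", "father"))
  expect_setequal(unique(st$truth$timepoint), c("T1", "T2"))
  s <- st$sessions[[1]]
  expect_setequal(names(s$segments),
                  c("session_id", "t_start_s", "t_end_s", "label"))
  expect_true(all(s$segments$label %in% c("CHI", "ADU", "SIL", "BOTH")))
  expect_true(all(s$frames$t_s >= 0 & s$frames$t_s < 60))
  expect_true(all(st$truth$psi_total >= 0))
})

test_that("the null generator forces all planted effects to zero", {
  st <- simulate_null_study(tiny_config(seed = 3, coupling_strength = 2,
                                        stress_effect = 1,
                                        caregiver_effect = 1))
  expect_true(all(st$truth$coupling_strength == 0))
  expect_equal(st$config$stress_effect, 0)
  expect_equal(st$config$caregiver_effect, 0)
  # switch rates vary only through the subject intercept
  expect_true(all(tapply(st$truth$switch_rate, st$truth$subject_id,
                         function(x) diff(range(x))) < 1e-12))
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_subjects = 1), "n_subjects")
  expect_error(sim_config(session_seconds = 30), "session_seconds")
  expect_error(sim_config(residual_sd = 0), "residual_sd")
  expect_error(sim_config(coupling_strength = -1), "coupling_strength")
  expect_error(sim_config(n_features = 2, n_coupled = 3), "n_coupled")
  expect_error(sim_config(ar_rho = 1), "ar_rho")
})

# one session's observed CRQA for the first feature, caregiver on the rows
session_crqa <- function(st, i, params = crqa_params()) {
  s <- st$sessions[[i]]
  ds <- remove_long_silence(robust_scale(build_series(s$segments, s$frames)))
  crqa(ds$adult[, 1], ds$child[, 1], params)
}

test_that("recurrence and determinism are non-decreasing in coupling strength", {
  mets <- sapply(c(0, 1, 2), function(k) {
    rec <- det <- numeric(50)
    for (i in 1:50) {
      st <- simulate_study(sim_config(
        n_subjects = 2, n_features = 1, session_seconds = 60, frame_rate = 4,
        coupling_strength = k, stress_effect = 0, caregiver_effect = 0,
        random_intercept_sd = 0, seed = 3000 + i))
      r <- session_crqa(st, 1)
      rec[i] <- r$rec; det[i] <- r$det
    }
    c(rec = mean(rec), det = mean(det, na.rm = TRUE))
  })
  expect_true(all(diff(mets["rec", ]) >= 0))
  expect_true(all(diff(mets["det", ]) >= 0))
  # and the kappa = 2 vs 0 recurrence gap is real, not a tie
  expect_gt(mets["rec", 3], mets["rec", 1] + 0.005)
})

test_that("without coupling, true and permuted pairings are indistinguishable", {
  p <- crqa_params()
  true_rec <- perm_rec <- numeric(50)
  for (i in 1:50) {
    st <- simulate_study(sim_config(
      n_subjects = 2, n_features = 1, session_seconds = 60, frame_rate = 4,
      coupling_strength = 0, stress_effect = 0, caregiver_effect = 0,
      random_intercept_sd = 0, seed = 4000 + i))
    s <- st$sessions[[1]]
    ds <- remove_long_silence(robust_scale(build_series(s$segments,
                                                        s$frames)))
    true_rec[i] <- crqa(ds$adult[, 1], ds$child[, 1], p)$rec
    perm <- permute_alignment(ds, seed = i)
    perm_rec[i] <- crqa(perm$adult[, 1], perm$child[, 1], p)$rec
  }
  expect_gt(t.test(true_rec, perm_rec)$p.value, 0.01)
})

test_that("higher simulated stress lowers LAM/DET across dyads", {
  # direction invariant of the generator: positive stress_effect with a
  # spread of PSI values must induce a negative PSI ~ LAM/DET association
  st <- simulate_study(sim_config(
    n_subjects = 10, n_features = 1, session_seconds = 600, frame_rate = 4,
    stress_effect = 1.5, caregiver_effect = 0, random_intercept_sd = 0.2,
    seed = 77))
  tab <- crqa_study(prepare_study(st))
  ct <- cor.test(tab$psi_total, tab$lam_det, method = "spearman",
                 alternative = "less", exact = FALSE)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("the similarity generator has marginal structure but no coupling channel", {
  st <- simulate_similarity_study(tiny_config(seed = 12, n_features = 1,
                                              session_seconds = 240))
  expect_equal(st$mode, "similarity")
  s <- st$sessions[[1]]
  # no concurrent vocalization: identical shared frames would themselves be
  # a moment-level coordination channel
  expect_false(any(s$segments$label == "BOTH"))
  ds <- build_series(s$segments, s$frames)
  adult_voc <- ds$adult[ds$speaking_adult, 1]
  # the adult's windows are exchangeable: no serial structure in the values
  expect_lt(abs(cor(adult_voc[-1], adult_voc[-length(adult_voc)])), 0.25)
  # and no lagged cross-coupling: child values do not predict the adult's
  # next-window values
  w <- which(ds$speaking_child[-nrow(ds$child)] & ds$speaking_adult[-1])
  expect_gt(length(w), 20)
  expect_lt(abs(cor(ds$child[w, 1], ds$adult[w + 1, 1])), 0.3)
})
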