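test_that("delay embedding follows the definition", {
  expect_equal(nrow(embed_series(rnorm(20), 3, 3)), 14)
  x <- rnorm(9)
  expect_equal(embed_series(x, 1, 1), matrix(x, ncol = 1))
  e <- embed_series(1:7, 2, 2)
  expect_equal(e, cbind(1:5, 3:7))
  expect_error(embed_series(1:6, 3, 3), "insufficient data.*7")
})

test_that("cross-recurrence matrix matches brute force and is symmetric in transpose", {
  A <- c(0, 0, 0, 1, 1, 1, 0, 0, 0)
  M <- cross_recurrence(embed_series(A, 1, 1), embed_series(A, 1, 1), 0.5)
  expect_equal(sum(M), 45)  # 6*6 zero-pairs + 3*3 one-pairs
  expect_equal(M, oracle_crp(A, A, 0.5))

  cst <- rep(2, 6)
  expect_true(all(cross_recurrence(cst, cst, 0.1) == 1))
  expect_true(all(cross_recurrence(rep(0, 5), rep(10, 5), 1) == 0))

  set.seed(3)
  a <- embed_series(rnorm(25), 2, 2)
  b <- embed_series(rnorm(30), 2, 2)
  expect_equal(cross_recurrence(a, b, 1.2),
               t(cross_recurrence(b, a, 1.2)))
  expect_error(cross_recurrence(a, cbind(b, 1), 1), "dimension mismatch")
})

test_that("recurrence rate is monotone in the radius", {
  set.seed(4)
  a <- embed_series(rnorm(40), 3, 3)
  b <- embed_series(rnorm(40), 3, 3)
  recs <- vapply(c(0.2, 0.5, 1, 1.5, 2.5, 4),
                 function(e) mean(cross_recurrence(a, b, e)), numeric(1))
  expect_true(all(diff(recs) >= 0))
  # auto-recurrence with a huge radius saturates
  expect_equal(crqa(rnorm(30), rnorm(30), crqa_params(radius = 100))$rec, 1)
})

test_that("crqa_metrics matches the closed-form corner cases", {
  m <- crqa_metrics(matrix(1L, 10, 10))
  expect_equal(m$rec, 1)
  # the two corner diagonals have length 1 < lmin, so det = 98/100 under the
  # standard run-length definition; every vertical line has length 10
  expect_equal(m$det, 0.98)
  expect_equal(m$lam, 1)
  expect_equal(m$l_max, 10)
  expect_equal(m$tt, 10)
  expect_equal(m$v_entr, 0)           # every vertical line has length 10
  expect_equal(m$l_mean, 98 / 17)     # diagonal lengths 2,2,3,3,...,9,9,10

  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  s <- crqa_metrics(single)
  expect_equal(s$rec, 1 / 25)
  expect_equal(s$det, 0)
  expect_equal(s$lam, 0)
  expect_true(is.na(s$lam_det))
  expect_true(s$unstable)

  z <- crqa_metrics(matrix(0L, 4, 6))
  expect_equal(z$rec, 0)
  expect_true(z$unstable)
})

test_that("metrics equal the brute-force oracle on random matrices", {
  set.seed(7)
  for (i in 1:40) {
    nr <- sample(3:25, 1); nc <- sample(3:25, 1)
    M <- matrix(rbinom(nr * nc, 1, runif(1, 0.1, 0.7)), nr, nc)
    a <- crqa_metrics(M)
    b <- oracle_crqa_metrics(M)
    expect_equal(a[names(b)], b, tolerance = 1e-12)
  }
})

test_that("compiled fast path agrees exactly with the reference implementation", {
  set.seed(8)
  p <- crqa_params()
  for (i in 1:20) {
    x <- rnorm(60); y <- rnorm(60)
    fast <- crqa(x, y, p)
    M <- cross_recurrence(embed_series(x, p$m, p$tau),
                          embed_series(y, p$m, p$tau), p$radius)
    ref <- crqa_metrics(M, p$lmin, p$vmin)
    expect_equal(unclass(fast), unclass(ref), tolerance = 1e-12)
  }
  # zero-variance input flagged unstable, never computed
  expect_true(crqa(rep(1, 30), rnorm(30))$unstable)
})

test_that("stability filter enforces complete data study-wide", {
  grid <- expand.grid(subject_id = c("A", "B", "C"),
                      caregiver = c("mother", "father"),
                      timepoint = c("T1", "T2"),
                      feature = c("f1", "f2"), stringsAsFactors = FALSE)
  grid$unstable <- FALSE
  grid$det_rec <- 1.5
  grid$lam_det <- 1.1
  all_ok <- stability_filter(grid)
  expect_setequal(all_ok$subjects, c("A", "B", "C"))
  expect_setequal(all_ok$features, c("f1", "f2"))

  # one unstable (session, feature) drops that feature everywhere
  one_bad <- grid
  one_bad$unstable[one_bad$subject_id == "B" & one_bad$feature == "f2" &
                     one_bad$caregiver == "father" &
                     one_bad$timepoint == "T2"] <- TRUE
  filt <- stability_filter(one_bad)
  expect_setequal(filt$features, "f1")
  expect_setequal(filt$subjects, c("A", "B", "C"))

  # a subject missing a session is dropped before feature filtering
  missing_sess <- grid[!(grid$subject_id == "C" & grid$caregiver == "father" &
                           grid$timepoint == "T2"), ]
  filt2 <- stability_filter(missing_sess)
  expect_setequal(filt2$subjects, c("A", "B"))
  expect_setequal(filt2$features, c("f1", "f2"))

  all_bad <- grid
  all_bad$unstable <- TRUE
  expect_error(stability_filter(all_bad), "empty retention")
})
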