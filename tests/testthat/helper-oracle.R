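# Independent brute-force oracles, written before (and apart from) the
# engine implementations they check.

# Cross-recurrence matrix by explicit double loop over point pairs.
oracle_crp <- function(a, b, eps) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  M <- matrix(0L, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d <= eps) M[i, j] <- 1L
  }
  M
}

# CRQA metrics by direct run-length scanning with explicit loops.
oracle_crqa_metrics <- function(M, lmin = 2, vmin = 2) {
  nr <- nrow(M); nc <- ncol(M)
  total <- sum(M)
  rec <- total / (nr * nc)
  if (total == 0)
    return(list(rec = 0, det = NA_real_, lam = NA_real_, det_rec = NA_real_,
                lam_det = NA_real_, l_mean = NA_real_, l_max = NA_real_,
                tt = NA_real_, entr = NA_real_, v_entr = NA_real_,
                unstable = TRUE))
  dlens <- integer(0)
  for (d in (-(nr - 1)):(nc - 1)) {
    i <- if (d < 0) -d + 1 else 1
    j <- if (d < 0) 1 else d + 1
    run <- 0L
    while (i <= nr && j <= nc) {
      if (M[i, j] == 1) run <- run + 1L
      else { if (run > 0) dlens <- c(dlens, run); run <- 0L }
      i <- i + 1; j <- j + 1
    }
    if (run > 0) dlens <- c(dlens, run)
  }
  vlens <- integer(0)
  for (j in seq_len(nc)) {
    run <- 0L
    for (i in seq_len(nr)) {
      if (M[i, j] == 1) run <- run + 1L
      else { if (run > 0) vlens <- c(vlens, run); run <- 0L }
    }
    if (run > 0) vlens <- c(vlens, run)
  }
  sumstats <- function(lens, minlen) {
    keep <- lens[lens >= minlen]
    if (!length(keep))
      return(list(pts = 0, mean = NA_real_, max = NA_real_, ent = NA_real_))
    p <- as.numeric(table(keep)) / length(keep)
    list(pts = sum(keep), mean = mean(keep), max = max(keep),
         ent = -sum(p * log(p)))
  }
  ds <- sumstats(dlens, lmin)
  vs <- sumstats(vlens, vmin)
  det <- ds$pts / total
  lam <- vs$pts / total
  list(rec = rec, det = det, lam = lam,
       det_rec = if (rec > 0) det / rec else NA_real_,
       lam_det = if (det > 0) lam / det else NA_real_,
       l_mean = ds$mean, l_max = ds$max, tt = vs$mean,
       entr = ds$ent, v_entr = vs$ent,
       unstable = !(rec > 0) || !(det > 0))
}

# Fine-grid trapezoid quadrature for the JZS correlation Bayes factor,
# independent of the adaptive-quadrature route in the package.
oracle_jzs_bf <- function(r, n, prior_scale = 1 / 3, n_rho = 2001,
                          n_w = 4000, w_max = 30) {
  w <- seq(0, w_max, length.out = n_w)
  lik <- function(rho) {
    f <- exp(-(n - 1) * log(cosh(w) - rho * r))
    inner <- sum((f[-1] + f[-n_w]) / 2) * (w[2] - w[1])
    exp((n - 1) / 2 * log1p(-rho^2)) * inner
  }
  a <- 1 / prior_scale
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_rho)
  prior <- exp((a - 1) * log1p(-rho^2) - (2 * a - 1) * log(2) - lbeta(a, a))
  vals <- vapply(rho, lik, numeric(1)) * prior
  num <- sum((vals[-1] + vals[-n_rho]) / 2) * (rho[2] - rho[1])
  num / lik(0)
}

# Construct paired vectors with an exact sample Pearson correlation.
make_correlated <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  z <- rnorm(n)
  z <- scale(resid(lm(z ~ x)))[, 1]
  y <- r * x + sqrt(1 - r^2) * z
  list(x = x, y = y)
}
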