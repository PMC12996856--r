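# Random-intercept linear mixed models for dyad-level synchrony metrics.
#
# The model is deliberately narrow: a single random intercept per subject with
# fixed effects for standardized parenting stress, caregiver role and
# timepoint.  For this model the profiled log-likelihood has a closed form
# given the variance ratio theta = sigma_b^2 / sigma_e^2, so estimation
# reduces to a one-dimensional optimization over theta with exact GLS solves
# at each evaluation.  This makes a single fit ~1 ms, which the resampling
# layers (LOSO parametric bootstrap, permutation specificity, power and
# calibration simulations) rely on: they refit the model 10^5-10^6 times.
# Agreement with lme4 is verified in the test suite.

# ---- internal fast fitter ---------------------------------------------------

# Precompute the sufficient statistics needed to evaluate the profiled
# likelihood at any theta.  Clusters are grouped by size so each evaluation is
# a handful of p x p matrix operations.
lmm_precompute <- function(y, X, cluster) {
  cluster <- as.integer(factor(cluster))
  N <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  S <- rowsum(X, cluster)                 # J x p cluster sums of X
  t_ <- rowsum(y, cluster)[, 1L]          # J cluster sums of y
  sizes <- tabulate(cluster)
  J <- length(sizes)
  by_size <- split(seq_len(J), sizes)
  groups <- lapply(names(by_size), function(k) {
    idx <- by_size[[k]]
    Sk <- S[idx, , drop = FALSE]
    list(k = as.numeric(k), m = length(idx),
         A = crossprod(Sk),
         b = crossprod(Sk, t_[idx]),
         cc = sum(t_[idx]^2))
  })
  list(y = y, X = X, cluster = cluster, N = N, p = p, J = J,
       XtX = XtX, Xty = Xty, yty = yty, S = S, t = t_,
       sizes = sizes, groups = groups)
}

# Profiled deviance pieces at a given theta.
lmm_profile <- function(pre, theta) {
  XtVX <- pre$XtX
  XtVy <- pre$Xty
  yVy <- pre$yty
  logdet <- 0
  for (g in pre$groups) {
    w <- theta / (1 + g$k * theta)
    XtVX <- XtVX - w * g$A
    XtVy <- XtVy - w * g$b
    yVy <- yVy - w * g$cc
    logdet <- logdet + g$m * log1p(g$k * theta)
  }
  beta <- solve(XtVX, XtVy)
  rss <- max(yVy - sum(beta * XtVy), 1e-12)
  list(beta = beta, rss = rss, logdet = logdet, XtVX = XtVX)
}

lmm_deviance <- function(pre, theta, reml = FALSE) {
  pr <- lmm_profile(pre, theta)
  N <- pre$N
  p <- pre$p
  if (reml) {
    s2 <- pr$rss / (N - p)
    (N - p) * log(2 * pi * s2) + pr$logdet +
      determinant(pr$XtVX, logarithm = TRUE)$modulus[1] + (N - p)
  } else {
    s2 <- pr$rss / N
    N * log(2 * pi * s2) + pr$logdet + N
  }
}

# Fit by 1-D minimization of the profiled deviance over theta >= 0.
lmm_fit_core <- function(y, X, cluster, reml = FALSE) {
  pre <- lmm_precompute(y, X, cluster)
  f <- function(u) lmm_deviance(pre, exp(u), reml = reml)
  opt <- stats::optimize(f, interval = c(-14, 14), tol = 1e-7)
  dev0 <- lmm_deviance(pre, 0, reml = reml)
  if (dev0 <= opt$objective) {
    theta <- 0
    dev <- dev0
  } else {
    theta <- exp(opt$minimum)
    dev <- opt$objective
  }
  pr <- lmm_profile(pre, theta)
  N <- pre$N
  p <- pre$p
  s2 <- pr$rss / (if (reml) N - p else N)
  vcov_beta <- solve(pr$XtVX) * s2
  beta <- drop(pr$beta)
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  list(beta = beta, vcov = vcov_beta, sigma2_e = s2, sigma2_b = theta * s2,
       theta = theta, loglik = -dev / 2, reml = reml,
       fitted = fitted, resid = y - fitted,
       N = N, p = p, J = pre$J, cluster = pre$cluster, sizes = pre$sizes,
       singular = theta < 1e-8)
}

# ---- user-facing fit --------------------------------------------------------

#' Fit the synchrony linear mixed model
#'
#' Fits the repeated-measures random-intercept model used throughout the
#' pipeline: a dyad-level synchrony metric (one CRQA composite ratio for one
#' acoustic feature) regressed on standardized parenting stress, caregiver
#' role and timepoint, with a random intercept per subject,
#' \deqn{y_{ij} = \beta_0 + \beta_1\,\mathrm{psi\_std} + \beta_2\,\mathrm{father}
#'   + \beta_3\,\mathrm{T2} + b_i + e_{ij}.}
#'
#' Estimation is exact maximum likelihood (default) or REML via the profiled
#' likelihood.  ML is required whenever fits are compared by likelihood-ratio
#' test ([lrt_compare()]); REML is available for final coefficient reporting.
#'
#' Coding: caregiver mother = 0 / father = 1; timepoint T1 = 0 / T2 = 1;
#' \code{psi_std} is the caregiver-specific PSI total score z-scored within
#' the data passed to this call (so every resample standardizes on its own
#' subset, as the sensitivity analysis requires).  With
#' \code{standardize = TRUE} (default) the dependent variable is z-scored the
#' same way, putting coefficients on the standardized-response scale.
#'
#' @param data data frame with columns \code{subject_id}, \code{caregiver}
#'   (\code{"mother"}/\code{"father"}), \code{timepoint} (\code{"T1"}/
#'   \code{"T2"}), \code{psi_total}, and the column named by \code{dv}.
#' @param dv name of the dependent-variable column, e.g. \code{"lam_det"} or
#'   \code{"det_rec"}.
#' @param include_stress if \code{FALSE}, fit the baseline model without the
#'   stress term (the null for the likelihood-ratio comparison).
#' @param reml use REML instead of ML.
#' @param standardize z-score the dependent variable within \code{data}.
#' @return an object of class \code{"synchrony_lmm"}: coefficient table
#'   (estimate, se, t, df, p), variance components, log-likelihood, AIC/BIC,
#'   fitted values and residuals.  Term p-values use a between-within residual
#'   degrees-of-freedom approximation, \eqn{df = N - J - (p - 1)}.
#' @seealso [lrt_compare()], [marginal_r2()], [cr2_inference()],
#'   [check_assumptions()]
#' @examples
#' d <- simulate_lmm_data(n_subjects = 20, b_psi = -0.3, seed = 1)
#' fit <- synchrony_lmm(d, dv = "lam_det")
#' summary(fit)
#' @export
synchrony_lmm <- function(data, dv, include_stress = TRUE, reml = FALSE,
                          standardize = TRUE) {
  req <- c("subject_id", "caregiver", "timepoint", "psi_total", dv)
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- data[[dv]]
  if (anyNA(y)) stop("dependent variable '", dv, "' contains missing values",
                     call. = FALSE)
  if (standardize) {
    s <- stats::sd(y)
    if (s < 1e-12) stop("dependent variable '", dv, "' has zero variance",
                        call. = FALSE)
    y <- (y - mean(y)) / s
  }
  psi <- data$psi_total
  psi_std <- (psi - mean(psi)) / stats::sd(psi)
  father <- as.numeric(data$caregiver == "father")
  t2 <- as.numeric(data$timepoint == "T2")
  X <- if (include_stress) {
    cbind(`(Intercept)` = 1, psi_std = psi_std, caregiver = father, time = t2)
  } else {
    cbind(`(Intercept)` = 1, caregiver = father, time = t2)
  }
  fit <- lmm_fit_core(y, X, data$subject_id, reml = reml)
  if (fit$singular)
    warning("random-intercept variance estimated at the boundary (0); ",
            "fit flagged singular", call. = FALSE)
  se <- sqrt(diag(fit$vcov))
  df_resid <- fit$N - fit$J - (fit$p - 1)
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df = df_resid, lower.tail = FALSE)
  k_par <- fit$p + 2  # fixed effects + 2 variance components
  out <- list(
    coefficients = data.frame(
      term = names(fit$beta), estimate = unname(fit$beta), se = unname(se),
      t = unname(tval), df = df_resid, p = unname(pval),
      stringsAsFactors = FALSE),
    varcomp = c(subject = fit$sigma2_b, residual = fit$sigma2_e),
    loglik = fit$loglik, aic = -2 * fit$loglik + 2 * k_par,
    bic = -2 * fit$loglik + log(fit$N) * k_par,
    n_obs = fit$N, n_subjects = fit$J, n_par = k_par,
    reml = fit$reml, singular = fit$singular,
    fitted = fit$fitted, residuals = drop(fit$resid),
    y = y, X = X, cluster = fit$cluster, theta = fit$theta,
    dv = dv, include_stress = include_stress,
    call = match.call()
  )
  class(out) <- "synchrony_lmm"
  out
}

#' @export
print.synchrony_lmm <- function(x, ...) {
  cat("Synchrony random-intercept LMM (", if (x$reml) "REML" else "ML",
      "), dv = ", x$dv, "\n", sep = "")
  cat(x$n_obs, "sessions,", x$n_subjects, "subjects\n")
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  cat("Variance components: subject =", signif(x$varcomp["subject"], 3),
      ", residual =", signif(x$varcomp["residual"], 3), "\n")
  invisible(x)
}

#' @export
summary.synchrony_lmm <- function(object, ...) {
  object$marginal_r2 <- marginal_r2(object)
  class(object) <- c("summary.synchrony_lmm", class(object))
  object
}

#' @export
print.summary.synchrony_lmm <- function(x, ...) {
  NextMethod()
  cat("logLik =", signif(x$loglik, 6), " AIC =", signif(x$aic, 6),
      " BIC =", signif(x$bic, 6), "\n")
  cat("Marginal R2 (fixed effects) =", signif(x$marginal_r2, 3), "\n")
  invisible(x)
}

#' @export
coef.synchrony_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.synchrony_lmm <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' @export
residuals.synchrony_lmm <- function(object, ...) object$residuals

#' @export
fitted.synchrony_lmm <- function(object, ...) object$fitted

#' @export
predict.synchrony_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  psi_std <- (newdata$psi_total - mean(newdata$psi_total)) /
    stats::sd(newdata$psi_total)
  father <- as.numeric(newdata$caregiver == "father")
  t2 <- as.numeric(newdata$timepoint == "T2")
  X <- if (object$include_stress)
    cbind(1, psi_std, father, t2) else cbind(1, father, t2)
  drop(X %*% coef(object))
}

#' Simulate responses from a fitted synchrony model
#'
#' Parametric simulation from the fitted model: new subject intercepts drawn
#' from \eqn{N(0, \hat\sigma_b^2)} and residuals from
#' \eqn{N(0, \hat\sigma_e^2)} are added to the fixed-effect predictions.  This
#' is the generator behind the parametric-bootstrap likelihood-ratio
#' calibration in [loso_bootstrap()].
#'
#' @param object a fitted \code{synchrony_lmm}.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed (RNG state is restored afterwards).
#' @param ... unused.
#' @return a matrix with \code{nsim} columns, one simulated response each.
#' @export
simulate.synchrony_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    J <- object$n_subjects
    N <- object$n_obs
    sims <- matrix(NA_real_, N, nsim)
    for (s in seq_len(nsim)) {
      b <- stats::rnorm(J, 0, sqrt(object$varcomp["subject"]))
      e <- stats::rnorm(N, 0, sqrt(object$varcomp["residual"]))
      sims[, s] <- object$fitted + b[object$cluster] + e
    }
    sims
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
plot.synchrony_lmm <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals, xlab = "fitted", ylab = "residual",
                 main = paste("Residuals vs fitted:", x$dv), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# ---- model comparison -------------------------------------------------------

#' Likelihood-ratio comparison of nested synchrony models
#'
#' Compares the full model (with the stress term) against the nested baseline
#' without it: \eqn{X^2 = 2(\ell_{full} - \ell_{base})} (clipped at 0), with a
#' \eqn{\chi^2_{df}} p-value and AIC/BIC differences.  Both fits must be ML on
#' identical rows.
#'
#' @param full,baseline fitted \code{synchrony_lmm} objects (ML), baseline
#'   nested in full.
#' @return a list of class \code{"lmm_comparison"}: \code{chi2},
#'   \code{df_diff}, \code{p_lrt}, \code{delta_aic} (full - baseline),
#'   \code{delta_bic}.
#' @export
lrt_compare <- function(full, baseline) {
  if (!inherits(full, "synchrony_lmm") || !inherits(baseline, "synchrony_lmm"))
    stop("both arguments must be synchrony_lmm fits", call. = FALSE)
  if (full$reml || baseline$reml)
    stop("likelihood-ratio comparison requires ML fits (reml = FALSE)",
         call. = FALSE)
  if (full$n_obs != baseline$n_obs)
    stop("models were fitted on different numbers of rows", call. = FALSE)
  if (!all(baseline$coefficients$term %in% full$coefficients$term))
    stop("baseline model is not nested in the full model", call. = FALSE)
  df_diff <- full$n_par - baseline$n_par
  if (df_diff < 0) stop("baseline model is not nested in the full model",
                        call. = FALSE)
  chi2 <- max(0, 2 * (full$loglik - baseline$loglik))
  structure(list(
    chi2 = chi2, df_diff = df_diff,
    p_lrt = if (df_diff == 0) 1 else
      stats::pchisq(chi2, df = df_diff, lower.tail = FALSE),
    delta_aic = full$aic - baseline$aic,
    delta_bic = full$bic - baseline$bic
  ), class = "lmm_comparison")
}

#' @export
print.lmm_comparison <- function(x, ...) {
  cat(sprintf("LRT: X2 = %.3f, df = %d, p = %.4g; dAIC = %.2f, dBIC = %.2f\n",
              x$chi2, x$df_diff, x$p_lrt, x$delta_aic, x$delta_bic))
  invisible(x)
}

#' Marginal R-squared of a synchrony model
#'
#' Proportion of total variance explained by the fixed effects alone
#' (Nakagawa-Schielzeth): variance of the fixed-effect predictions divided by
#' that variance plus the random-intercept and residual variances.
#'
#' @param fit a fitted \code{synchrony_lmm}.
#' @return a number in \eqn{[0, 1]}, or \code{NA} if the total variance is
#'   degenerate.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "synchrony_lmm"))
  var_f <- stats::var(fit$fitted)
  tot <- var_f + sum(fit$varcomp)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  var_f / tot
}

# ---- robust (CR2) inference -------------------------------------------------

#' Cluster-robust coefficient table (CR2 bias-reduced linearization)
#'
#' Recomputes coefficient standard errors with the CR2 bias-reduced
#' linearization cluster-robust variance estimator (clusters = subjects),
#' with Satterthwaite degrees of freedom, as the robust fallback when the
#' model's distributional assumptions are flagged.  The adjustment is applied
#' to the marginal (OLS) regression of the response on the fixed-effect
#' design, so its validity does not depend on the modelled covariance
#' structure being correct.
#'
#' @param fit a fitted \code{synchrony_lmm} with at least 4 subjects.
#' @return a data frame like \code{fit$coefficients} but with CR2 standard
#'   errors, Satterthwaite df, and the corresponding t and p values.
#' @references Bell & McCaffrey (2002); Pustejovsky & Tipton (2018).
#' @export
cr2_inference <- function(fit) {
  stopifnot(inherits(fit, "synchrony_lmm"))
  J <- fit$n_subjects
  if (J < 4) stop("CR2 inference requires at least 4 clusters (subjects), got ",
                  J, call. = FALSE)
  X <- fit$X
  y <- fit$y
  cl <- fit$cluster
  p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  beta_ols <- drop(XtXinv %*% crossprod(X, y))
  e <- y - drop(X %*% beta_ols)
  idx <- split(seq_along(y), cl)
  # A_j = (I - H_jj)^{-1/2}; meat = sum_j X_j' A_j e_j e_j' A_j X_j
  meat <- matrix(0, p, p)
  Aj_list <- vector("list", J)
  for (j in seq_len(J)) {
    ii <- idx[[j]]
    Xj <- X[ii, , drop = FALSE]
    Hjj <- Xj %*% XtXinv %*% t(Xj)
    eg <- eigen(diag(length(ii)) - Hjj, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-12)
    Aj <- eg$vectors %*% (t(eg$vectors) / sqrt(vals))
    Aj_list[[j]] <- Aj
    u <- drop(Aj %*% e[ii])
    meat <- meat + crossprod(Xj, u) %*% t(crossprod(Xj, u))
  }
  Vcr2 <- XtXinv %*% meat %*% XtXinv
  se <- sqrt(diag(Vcr2))
  # Satterthwaite df per coefficient (Bell-McCaffrey / Imbens-Kolesar):
  # G columns g_j = (I - H)[, S_j] A_j X_j XtXinv ell; df = tr(G'G)^2/tr((G'G)^2)
  H <- X %*% XtXinv %*% t(X)
  ImH <- diag(fit$n_obs) - H
  df_sat <- numeric(p)
  for (k in seq_len(p)) {
    ell <- numeric(p); ell[k] <- 1
    G <- matrix(0, fit$n_obs, J)
    for (j in seq_len(J)) {
      ii <- idx[[j]]
      uj <- drop(Aj_list[[j]] %*% (X[ii, , drop = FALSE] %*% (XtXinv %*% ell)))
      G[, j] <- ImH[, ii, drop = FALSE] %*% uj
    }
    M <- crossprod(G)
    df_sat[k] <- sum(diag(M))^2 / sum(M * M)
  }
  tval <- beta_ols / se
  pval <- 2 * stats::pt(abs(tval), df = df_sat, lower.tail = FALSE)
  data.frame(term = colnames(X), estimate = beta_ols, se = se, t = tval,
             df = df_sat, p = pval, stringsAsFactors = FALSE)
}

# ---- assumption checks ------------------------------------------------------

#' Diagnostic checks on a fitted synchrony model
#'
#' Pure functions of the fit: Shapiro-Wilk on the within-subject residuals,
#' Shapiro-Wilk on the empirical-Bayes subject intercepts, and a
#' Breusch-Pagan-style score test of heteroskedasticity of squared residuals
#' against fitted values.  A flag is \code{TRUE} when the assumption passes at
#' \eqn{\alpha = 0.05}.
#'
#' @param fit a fitted \code{synchrony_lmm}.
#' @param alpha significance level for the flags.
#' @return list with \code{residual_normality}, \code{intercept_normality},
#'   \code{homoskedasticity} (logical flags), the underlying p-values, and
#'   \code{any_violation}.
#' @export
check_assumptions <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "synchrony_lmm"))
  marg_resid <- fit$y - fit$fitted
  shrink <- fit$varcomp["subject"] /
    (fit$varcomp["subject"] * tabulate(fit$cluster) + fit$varcomp["residual"])
  blup <- shrink * rowsum(marg_resid, fit$cluster)[, 1L]
  cond_resid <- marg_resid - blup[fit$cluster]
  p_res <- stats::shapiro.test(cond_resid)$p.value
  p_int <- if (stats::sd(blup) > 1e-10 && length(blup) >= 3)
    stats::shapiro.test(blup)$p.value else NA_real_
  # Breusch-Pagan score test: N * R2 of e^2 on fitted ~ chi2(1)
  e2 <- cond_resid^2
  r2 <- summary(stats::lm(e2 ~ fit$fitted))$r.squared
  p_bp <- stats::pchisq(length(e2) * r2, df = 1, lower.tail = FALSE)
  flags <- list(
    residual_normality = p_res >= alpha,
    intercept_normality = is.na(p_int) || p_int >= alpha,
    homoskedasticity = p_bp >= alpha,
    p_residual = p_res, p_intercept = p_int, p_heteroskedasticity = p_bp
  )
  flags$any_violation <- !(flags$residual_normality &&
                             flags$intercept_normality &&
                             flags$homoskedasticity)
  flags
}

# ---- LMM-level simulator ----------------------------------------------------

#' Simulate dyad-level data directly from the mixed model
#'
#' Generates a balanced dyad-level table (2 caregivers x 2 timepoints per
#' subject) straight from the random-intercept model, with known
#' coefficients on the standardized-response scale.  This is the generator
#' used for parameter-recovery, power and calibration studies of the modeling
#' stage itself (the time-series generator [simulate_study()] exercises the
#' whole pipeline instead).
#'
#' PSI totals are drawn per caregiver from a truncated Normal(80, 20) and held
#' correlated 0.75 across timepoints, mirroring the scale and test-retest
#' reliability of the instrument.
#'
#' @param n_subjects number of subjects.
#' @param b_psi,b_caregiver,b_time fixed-effect coefficients (standardized
#'   response scale; caregiver father vs mother, time T2 vs T1).
#' @param intercept_sd,residual_sd random-intercept and residual SDs.
#' @param dv_name name for the response column (default \code{"lam_det"}).
#' @param seed optional seed.
#' @return a data frame with columns \code{subject_id}, \code{caregiver},
#'   \code{timepoint}, \code{psi_total} and the response column; attribute
#'   \code{"truth"} records the generating coefficients.
#' @export
simulate_lmm_data <- function(n_subjects, b_psi = 0, b_caregiver = 0,
                              b_time = 0, intercept_sd = 0.5,
                              residual_sd = 1, dv_name = "lam_det",
                              seed = NULL) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  run <- function() {
    d <- expand.grid(caregiver = c("mother", "father"),
                     timepoint = c("T1", "T2"),
                     subject_id = sprintf("S%03d", seq_len(n_subjects)),
                     stringsAsFactors = FALSE)
    d <- d[order(d$subject_id, d$caregiver, d$timepoint), ]
    psi <- draw_psi(n_subjects)
    d$psi_total <- psi[paste(d$subject_id, d$caregiver, d$timepoint)]
    psi_std <- (d$psi_total - mean(d$psi_total)) / stats::sd(d$psi_total)
    b <- stats::rnorm(n_subjects, 0, intercept_sd)
    names(b) <- sprintf("S%03d", seq_len(n_subjects))
    d[[dv_name]] <- b_psi * psi_std +
      b_caregiver * (d$caregiver == "father") +
      b_time * (d$timepoint == "T2") +
      b[d$subject_id] + stats::rnorm(nrow(d), 0, residual_sd)
    rownames(d) <- NULL
    attr(d, "truth") <- c(b_psi = b_psi, b_caregiver = b_caregiver,
                          b_time = b_time, intercept_sd = intercept_sd,
                          residual_sd = residual_sd)
    d
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Draw caregiver-specific PSI totals, Normal(80, 20) truncated at 0, with
# test-retest correlation 0.75 between T1 and T2.  Returns a named vector
# keyed "subject caregiver timepoint".
draw_psi <- function(n_subjects, mean = 80, sd = 20, retest_r = 0.75) {
  ids <- sprintf("S%03d", seq_len(n_subjects))
  out <- numeric(0)
  for (cg in c("mother", "father")) {
    z1 <- stats::rnorm(n_subjects)
    z2 <- retest_r * z1 + sqrt(1 - retest_r^2) * stats::rnorm(n_subjects)
    p1 <- pmax(mean + sd * z1, 0)
    p2 <- pmax(mean + sd * z2, 0)
    out[paste(ids, cg, "T1")] <- p1
    out[paste(ids, cg, "T2")] <- p2
  }
  out
}
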