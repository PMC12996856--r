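# The two resampling layers of the inferential procedure.
#
# Sensitivity (internal robustness): leave-one-subject-out refitting with a
# parametric bootstrap of the likelihood-ratio statistic, yielding
# empirically calibrated model and term p-values averaged over folds.
#
# Specificity (temporal coordination vs general similarity): permuting the
# adult's window order destroys dyadic temporal alignment while preserving
# every marginal property of each speaker's speech; rebuilding the CRQA
# metrics and models on permuted data yields a null distribution for the
# model chi-squared and the stress-term t statistic.

# Standardized design matrices for one dyad-level table (psi and dv z-scored
# within the table, as each resampling step requires).
build_design <- function(data, dv) {
  y <- data[[dv]]
  s <- stats::sd(y)
  if (!is.finite(s) || s < 1e-12) stop("zero-variance response", call. = FALSE)
  y <- (y - mean(y)) / s
  psi_std <- (data$psi_total - mean(data$psi_total)) /
    stats::sd(data$psi_total)
  father <- as.numeric(data$caregiver == "father")
  t2 <- as.numeric(data$timepoint == "T2")
  Xf <- cbind(`(Intercept)` = 1, psi_std = psi_std, caregiver = father,
              time = t2)
  list(y = y, Xf = Xf, Xb = Xf[, -2, drop = FALSE],
       cluster = as.integer(factor(data$subject_id)))
}

# Term p-values from a core fit (between-within residual df).
term_pvals <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  df <- fit$N - fit$J - (fit$p - 1)
  2 * stats::pt(abs(fit$beta / se), df = df, lower.tail = FALSE)
}

# One-sided percentile-bootstrap p-value for H0: mean(p) >= 0.05 (small
# values = evidence that the average p is below 0.05); add-one convention.
dist_pvalue <- function(p, n_resample = 10000) {
  if (length(p) < 2) return(NA_real_)
  idx <- matrix(sample.int(length(p), length(p) * n_resample, replace = TRUE),
                ncol = n_resample)
  means <- colMeans(matrix(p[idx], ncol = n_resample))
  (1 + sum(means >= 0.05)) / (n_resample + 1)
}

#' Leave-one-subject-out parametric-bootstrap sensitivity analysis
#'
#' For each left-out subject, the full and baseline (no-stress) models are
#' refit on the remaining subjects (re-standardizing the response and PSI
#' within the subset), the observed likelihood-ratio statistic is calibrated
#' by a parametric bootstrap under the fitted baseline (responses simulated
#' from its estimated fixed effects and variance components, both models
#' refit per draw), and the resulting empirical p-values and term p-values
#' are averaged over folds.  The bootstrap budget \code{n_boot} is divided
#' evenly across folds.  Empirical p-values use the add-one convention and
#' are never exactly 0.
#'
#' The distribution-level p-values (\code{p_dist}, \code{p_*_dist}) test the
#' null hypothesis that the mean fold-level p-value is at least 0.05, by
#' percentile bootstrap over folds.
#'
#' @param data dyad-level table (columns \code{subject_id}, \code{caregiver},
#'   \code{timepoint}, \code{psi_total} and the response \code{dv}); at least
#'   5 subjects.
#' @param dv response column name (e.g. \code{"lam_det"}).
#' @param n_boot total parametric-bootstrap simulations across folds.
#' @param seed master seed for the bootstrap draws.
#' @param dist_resamples resamples for the distribution-level p-values.
#' @return a list of class \code{"sensitivity_summary"}: \code{chi2_mean},
#'   \code{p_anova}, \code{p_dist}, \code{p_stress}, \code{p_caregiver},
#'   \code{p_time} and their \code{_dist} companions, \code{n_boot}, and the
#'   per-fold table \code{folds}.
#' @export
loso_bootstrap <- function(data, dv, n_boot = 1000, seed = 1,
                           dist_resamples = 10000) {
  subjects <- unique(data$subject_id)
  J <- length(subjects)
  if (J < 5) stop("LOSO sensitivity needs at least 5 subjects", call. = FALSE)
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  share <- max(1L, as.integer(round(n_boot / J)))
  folds <- vector("list", J)
  skipped <- 0L
  for (j in seq_len(J)) {
    res <- tryCatch({
      sub <- data[data$subject_id != subjects[j], , drop = FALSE]
      d <- build_design(sub, dv)
      ff <- lmm_fit_core(d$y, d$Xf, d$cluster)
      fb <- lmm_fit_core(d$y, d$Xb, d$cluster)
      obs_chi2 <- max(0, 2 * (ff$loglik - fb$loglik))
      pv <- term_pvals(ff)
      null_chi2 <- with_seed(derive_seed(seed, "loso", j), {
        sd_b <- sqrt(fb$sigma2_b)
        sd_e <- sqrt(fb$sigma2_e)
        Jb <- fb$J
        vapply(seq_len(share), function(b) {
          ystar <- fb$fitted + stats::rnorm(Jb, 0, sd_b)[fb$cluster] +
            stats::rnorm(fb$N, 0, sd_e)
          ystar <- (ystar - mean(ystar)) / stats::sd(ystar)
          f1 <- lmm_fit_core(ystar, d$Xf, d$cluster)
          f0 <- lmm_fit_core(ystar, d$Xb, d$cluster)
          max(0, 2 * (f1$loglik - f0$loglik))
        }, numeric(1))
      })
      data.frame(subject_left_out = subjects[j], chi2 = obs_chi2,
                 p = (1 + sum(null_chi2 >= obs_chi2)) / (share + 1),
                 p_stress = pv[["psi_std"]], p_caregiver = pv[["caregiver"]],
                 p_time = pv[["time"]], stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- skipped + 1L else folds[[j]] <- res
  }
  if (skipped > 0.2 * J)
    stop("more than 20% of LOSO folds failed (", skipped, "/", J, ")",
         call. = FALSE)
  folds <- do.call(rbind, folds)
  out <- list(
    chi2_mean = mean(folds$chi2),
    p_anova = mean(folds$p),
    p_dist = with_seed(derive_seed(seed, "loso_dist", 1),
                       dist_pvalue(folds$p, dist_resamples)),
    p_stress = mean(folds$p_stress),
    p_stress_dist = with_seed(derive_seed(seed, "loso_dist", 2),
                              dist_pvalue(folds$p_stress, dist_resamples)),
    p_caregiver = mean(folds$p_caregiver),
    p_caregiver_dist = with_seed(derive_seed(seed, "loso_dist", 3),
                                 dist_pvalue(folds$p_caregiver,
                                             dist_resamples)),
    p_time = mean(folds$p_time),
    p_time_dist = with_seed(derive_seed(seed, "loso_dist", 4),
                            dist_pvalue(folds$p_time, dist_resamples)),
    n_boot = share * J, n_folds = nrow(folds), n_skipped = skipped,
    folds = folds)
  class(out) <- "sensitivity_summary"
  out
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat(sprintf(
    "LOSO sensitivity (%d folds, %d bootstrap draws):\n", x$n_folds,
    x$n_boot))
  cat(sprintf("  X2 = %.3f  p-ANOVA = %.3f (p-dist = %.3g)\n", x$chi2_mean,
              x$p_anova, x$p_dist))
  cat(sprintf("  p-stress = %.3f (%.3g)  p-caregiver = %.3f (%.3g)  p-time = %.3f (%.3g)\n",
              x$p_stress, x$p_stress_dist, x$p_caregiver, x$p_caregiver_dist,
              x$p_time, x$p_time_dist))
  invisible(x)
}

#' Permute temporal alignment of a dyad series
#'
#' Uniformly permutes the adult's window order (the child series is left
#' untouched), destroying dyadic temporal alignment while exactly preserving
#' the marginal distribution of every adult feature -- each speaker's
#' individual characteristics are intact, only the moment-to-moment
#' correspondence is broken.  With \code{both = TRUE} the child series is
#' permuted as well (independently).
#'
#' @param series a \code{dyad_series} with at least 4 windows.
#' @param seed optional seed.
#' @param both also permute the child series.
#' @return the permuted \code{dyad_series}.
#' @export
permute_alignment <- function(series, seed = NULL, both = FALSE) {
  stopifnot(inherits(series, "dyad_series"))
  n <- nrow(series$adult)
  if (n < 4) stop("series too short to permute (< 4 windows)", call. = FALSE)
  run <- function() {
    perm <- sample.int(n)
    series$adult <- series$adult[perm, , drop = FALSE]
    series$speaking_adult <- series$speaking_adult[perm]
    if (both) {
      perm2 <- sample.int(n)
      series$child <- series$child[perm2, , drop = FALSE]
      series$speaking_child <- series$speaking_child[perm2]
    }
    series
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Fast CRQA ratio for one feature of one (adult, child) pair of vectors.
crqa_ratio_fast <- function(x, y, params, ratio) {
  rx <- range(x)
  ry <- range(y)
  if (rx[2] - rx[1] < 1e-12 || ry[2] - ry[1] < 1e-12) return(NA_real_)
  v <- .crqa_core(x, y, params$m, params$tau, params$radius, params$lmin,
                  params$vmin)
  v[[ratio]]
}

#' Temporal-alignment permutation specificity analysis
#'
#' Tests whether a model's significance reflects moment-to-moment
#' coordination rather than general acoustic similarity.  For each of
#' \code{n_perm} permutation replicates, the adult window order of every
#' session is independently permuted ([permute_alignment()]), the CRQA
#' composite ratio for the target feature is recomputed, and the full and
#' baseline models are refit; the permuted likelihood-ratio statistics and
#' stress-term t values form the null distributions.
#'
#' Outputs: \code{p_spec_model} and \code{p_spec_stress} are the add-one
#' empirical tail probabilities of the observed \eqn{X^2} and \eqn{|t|}
#' against the permutation nulls; \code{p_rand} is the mean LRT p-value over
#' permuted datasets (a model significant only through true temporal
#' coordination loses significance under permutation, so \code{p_rand} above
#' \eqn{\alpha} supports specificity); \code{p_rand_dist} is the
#' distribution-level test of \code{p_rand} as in [loso_bootstrap()].
#'
#' @param prepared a \code{prepared_study} (see [prepare_study()]).
#' @param feature feature name to analyze.
#' @param ratio which composite ratio to model: \code{"lam_det"} or
#'   \code{"det_rec"}.
#' @param n_perm number of permutation replicates.
#' @param seed master seed.
#' @param params a [crqa_params()].
#' @param dist_resamples resamples for \code{p_rand_dist}.
#' @return a list of class \code{"specificity_summary"}: the p-values above,
#'   the null vectors \code{null_chi2} and \code{null_t_stress}, observed
#'   statistics, \code{n_perm} (effective, after dropping unstable
#'   replicates) and \code{n_dropped}.
#' @export
permutation_specificity <- function(prepared, feature,
                                    ratio = c("lam_det", "det_rec"),
                                    n_perm = 100, seed = 1,
                                    params = NULL, dist_resamples = 10000) {
  stopifnot(inherits(prepared, "prepared_study"))
  ratio <- match.arg(ratio)
  n_perm <- check_count(n_perm, "n_perm", min = 2L)
  params <- params %||% prepared$params
  k <- match(feature, prepared$series[[1]]$feature_names)
  if (is.na(k)) stop("unknown feature: ", feature, call. = FALSE)
  cvec <- lapply(prepared$series, function(s) s$child[, k])
  avec <- lapply(prepared$series, function(s) s$adult[, k])
  n_sess <- length(cvec)

  y_obs <- vapply(seq_len(n_sess), function(i)
    crqa_ratio_fast(avec[[i]], cvec[[i]], params, ratio), numeric(1))
  if (anyNA(y_obs))
    stop("unstable CRQA for feature '", feature,
         "' in the observed data; run stability_filter first", call. = FALSE)
  meta <- prepared$meta
  meta$.y <- y_obs
  d <- build_design(meta, ".y")
  ff <- lmm_fit_core(d$y, d$Xf, d$cluster)
  fb <- lmm_fit_core(d$y, d$Xb, d$cluster)
  obs_chi2 <- max(0, 2 * (ff$loglik - fb$loglik))
  obs_t <- ff$beta[["psi_std"]] / sqrt(diag(ff$vcov)[2])

  null_chi2 <- numeric(0)
  null_t <- numeric(0)
  null_p <- numeric(0)
  dropped <- 0L
  for (r in seq_len(n_perm)) {
    yr <- with_seed(derive_seed(seed, "perm", r), {
      vapply(seq_len(n_sess), function(i) {
        # an individual permuted session can lose all diagonal structure
        # (undefined ratio); retry with fresh permutations before giving up
        for (try in 1:3) {
          perm <- sample.int(length(avec[[i]]))
          v <- crqa_ratio_fast(avec[[i]][perm], cvec[[i]], params, ratio)
          if (!is.na(v)) return(v)
        }
        NA_real_
      }, numeric(1))
    })
    # sessions still unstable after retries are dropped listwise from this
    # replicate's refit; the replicate itself is dropped only if too few
    # sessions survive
    keep <- !is.na(yr)
    if (sum(keep) < 0.8 * n_sess ||
        stats::sd(yr[keep]) < 1e-12) { dropped <- dropped + 1L; next }
    if (all(keep)) {
      dr <- d
      yk <- yr
    } else {
      mk <- meta[keep, , drop = FALSE]
      mk$.y <- yr[keep]
      dr <- build_design(mk, ".y")
      yk <- yr[keep]
    }
    yk <- (yk - mean(yk)) / stats::sd(yk)
    f1 <- lmm_fit_core(yk, dr$Xf, dr$cluster)
    f0 <- lmm_fit_core(yk, dr$Xb, dr$cluster)
    chi2 <- max(0, 2 * (f1$loglik - f0$loglik))
    null_chi2 <- c(null_chi2, chi2)
    null_t <- c(null_t, f1$beta[["psi_std"]] / sqrt(diag(f1$vcov)[2]))
    null_p <- c(null_p, stats::pchisq(chi2, 1, lower.tail = FALSE))
  }
  if (dropped > 0.3 * n_perm)
    stop("more than 30% of permutation replicates were unstable (",
         dropped, "/", n_perm, ")", call. = FALSE)
  n_eff <- length(null_chi2)
  out <- list(
    feature = feature, ratio = ratio,
    p_rand = mean(null_p),
    p_rand_dist = with_seed(derive_seed(seed, "perm_dist", 1),
                            dist_pvalue(null_p, dist_resamples)),
    p_spec_model = (1 + sum(null_chi2 >= obs_chi2)) / (n_eff + 1),
    p_spec_stress = (1 + sum(abs(null_t) >= abs(obs_t))) / (n_eff + 1),
    obs_chi2 = obs_chi2, obs_t_stress = unname(obs_t),
    obs_p = stats::pchisq(obs_chi2, 1, lower.tail = FALSE),
    null_chi2 = null_chi2, null_t_stress = null_t,
    n_perm = n_eff, n_dropped = dropped)
  class(out) <- "specificity_summary"
  out
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat(sprintf(
    "Permutation specificity for %s (%s), %d replicates:\n", x$feature,
    x$ratio, x$n_perm))
  cat(sprintf("  observed X2 = %.3f (p = %.3f); p-spec-model = %.3f, p-spec-stress = %.3f\n",
              x$obs_chi2, x$obs_p, x$p_spec_model, x$p_spec_stress))
  cat(sprintf("  p-rand = %.3f (p-rand-dist = %.3g)\n", x$p_rand,
              x$p_rand_dist))
  invisible(x)
}
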