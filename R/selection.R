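# Sequential model prioritization and family-wise error control.
#
# Candidate models (one per acoustic feature x composite ratio) pass through
# four gates in order: (1) overall significance of the stress model in the
# LOSO sensitivity analysis; (2) specificity to true temporal coordination
# (significance vanishes under temporal permutation AND the observed
# statistic is extreme against the permutation null); (3) a significant
# parenting-stress term; (4) specificity of the stress effect itself.
# Family-wise type-I error of the whole procedure is quantified by Monte
# Carlo simulation over independent null models.

#' Gate configuration for sequential model selection
#'
#' @param alpha_overall level for gate 1 (overall model significance).
#' @param alpha_specificity level for gate 2 (temporal specificity).
#' @param alpha_stress level for gate 3 (stress-term significance).
#' @param alpha_stress_spec level for gate 4 (stress-term specificity).
#' @param alpha_dist level at which a distribution-level p-value
#'   (\code{p_dist}, \code{p_stress_dist}) counts as significant.
#' @param bonferroni_family number of models in the family (16 features x 2
#'   ratios = 32 in the target design).
#' @return a list of class \code{"gate_config"}.
#' @export
gate_config <- function(alpha_overall = 0.05, alpha_specificity = 0.05,
                        alpha_stress = 0.05, alpha_stress_spec = 0.05,
                        alpha_dist = 0.05, bonferroni_family = 32) {
  for (nm in c("alpha_overall", "alpha_specificity", "alpha_stress",
               "alpha_stress_spec", "alpha_dist")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      stop_config(nm, "must be in (0, 1)")
  }
  bonferroni_family <- check_count(bonferroni_family, "bonferroni_family")
  structure(list(alpha_overall = alpha_overall,
                 alpha_specificity = alpha_specificity,
                 alpha_stress = alpha_stress,
                 alpha_stress_spec = alpha_stress_spec,
                 alpha_dist = alpha_dist,
                 bonferroni_family = bonferroni_family),
            class = "gate_config")
}

#' Sequential four-gate model selection
#'
#' Applies the sequential prioritization to per-model sensitivity and
#' specificity summaries:
#' \enumerate{
#'   \item overall significance: \code{p_anova < alpha_overall} and
#'     \code{p_dist} significant;
#'   \item temporal specificity: significance vanishes under permutation
#'     (\code{p_rand > alpha_specificity}) and the observed model statistic
#'     is extreme against the permutation null
#'     (\code{p_spec_model < alpha_specificity});
#'   \item stress effect: \code{p_stress < alpha_stress} and
#'     \code{p_stress_dist} significant;
#'   \item stress specificity: \code{p_spec_stress < alpha_stress_spec}.
#' }
#' Gates are monotone: a model is evaluated at gate k+1 only if it passed
#' gate k.
#'
#' @param sens data frame of sensitivity summaries, one row per model, with
#'   columns \code{feature}, \code{ratio}, \code{p_anova}, \code{p_dist},
#'   \code{p_stress}, \code{p_stress_dist} (see [loso_bootstrap()]).
#' @param spec data frame of specificity summaries with columns
#'   \code{feature}, \code{ratio}, \code{p_rand}, \code{p_spec_model},
#'   \code{p_spec_stress} (see [permutation_specificity()]).
#' @param cfg a [gate_config()].
#' @return a list of class \code{"selection_outcome"}: \code{table} (the
#'   audit trail: one row per model with the consumed p-values and the four
#'   gate booleans), \code{survivors} (counts per gate) and \code{selected}
#'   (models passing all four gates).
#' @export
sequential_gates <- function(sens, spec, cfg = gate_config()) {
  stopifnot(inherits(cfg, "gate_config"))
  key <- function(d) paste(d$feature, d$ratio, sep = ":")
  absent <- setdiff(key(sens), key(spec))
  if (length(absent))
    stop("missing specificity summaries for model(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  m <- merge(sens, spec, by = c("feature", "ratio"), suffixes = c("", ".spec"))
  if (!nrow(m)) stop("no models to select over", call. = FALSE)
  g1 <- m$p_anova < cfg$alpha_overall & m$p_dist < cfg$alpha_dist
  g2 <- g1 & m$p_rand > cfg$alpha_specificity &
    m$p_spec_model < cfg$alpha_specificity
  g3 <- g2 & m$p_stress < cfg$alpha_stress &
    m$p_stress_dist < cfg$alpha_dist
  g4 <- g3 & m$p_spec_stress < cfg$alpha_stress_spec
  tab <- data.frame(feature = m$feature, ratio = m$ratio,
                    p_anova = m$p_anova, p_dist = m$p_dist,
                    p_rand = m$p_rand, p_spec_model = m$p_spec_model,
                    p_stress = m$p_stress, p_stress_dist = m$p_stress_dist,
                    p_spec_stress = m$p_spec_stress,
                    gate1 = g1, gate2 = g2, gate3 = g3, gate4 = g4,
                    stringsAsFactors = FALSE)
  out <- list(table = tab,
              survivors = c(gate1 = sum(g1), gate2 = sum(g2),
                            gate3 = sum(g3), gate4 = sum(g4)),
              selected = tab[g4, c("feature", "ratio")],
              cfg = cfg)
  class(out) <- "selection_outcome"
  out
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat("Sequential selection over", nrow(x$table), "models; survivors:",
      paste(sprintf("gate%d=%d", 1:4, x$survivors), collapse = ", "), "\n")
  if (nrow(x$selected)) {
    cat("Selected:\n")
    print(x$selected, row.names = FALSE)
  } else cat("No model passed the full selection.\n")
  invisible(x)
}

#' Bonferroni threshold for a model family
#'
#' @param alpha family-wise level.
#' @param n_models number of models tested.
#' @return list with \code{raw} (\eqn{\alpha / n}) and \code{reported}
#'   (rounded to 3 decimals).
#' @examples
#' bonferroni_threshold(0.05, 32)  # raw 0.0015625, reported 0.002
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_models) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha", "must be in (0, 1)")
  n_models <- check_count(n_models, "n_models")
  raw <- alpha / n_models
  list(raw = raw, reported = round(raw, 3))
}

#' Monte Carlo family-wise error of the sequential gates
#'
#' Simulates the probability that at least one of \code{n_models} truly null
#' models survives the first k selection gates, for k up to the number of
#' gates: each null model draws an independent Uniform(0,1) p-value per gate
#' and survives depth k iff its first k p-values each fall below the
#' corresponding alpha.  Under this independence model the closed form is
#' \eqn{1 - (1 - \prod_{j \le k}\alpha_j)^{n}}, which the simulation must
#' reproduce within Monte Carlo error (a test-suite invariant).
#'
#' @param n_models number of null models in the family.
#' @param gate_alphas vector of per-gate levels (length = gate depth).
#' @param n_iter Monte Carlo iterations (>= 1000).
#' @param seed seed.
#' @return a list of class \code{"fwe_simulation"}: \code{prob} (named
#'   vector, P(>= 1 survivor of depth k)), \code{mc_se} (Monte Carlo
#'   standard errors), \code{analytic} (independence closed form),
#'   \code{n_iter}.
#' @export
fwe_simulation <- function(n_models, gate_alphas, n_iter = 50000, seed = 1) {
  n_models <- check_count(n_models, "n_models")
  if (!is.numeric(gate_alphas) || !length(gate_alphas) ||
      any(gate_alphas < 0 | gate_alphas > 1))
    stop_config("gate_alphas", "must be probabilities in [0, 1]")
  n_iter <- check_count(n_iter, "n_iter", min = 1000L)
  depth <- length(gate_alphas)
  with_seed(seed, {
    alive <- matrix(TRUE, n_iter, n_models)
    prob <- numeric(depth)
    for (k in seq_len(depth)) {
      alive <- alive & matrix(stats::runif(n_iter * n_models) < gate_alphas[k],
                              n_iter, n_models)
      prob[k] <- mean(rowSums(alive) > 0)
    }
    analytic <- 1 - (1 - cumprod(gate_alphas))^n_models
    nms <- paste0("depth", seq_len(depth))
    out <- list(prob = stats::setNames(prob, nms),
                mc_se = stats::setNames(sqrt(prob * (1 - prob) / n_iter),
                                        nms),
                analytic = stats::setNames(analytic,
                                           paste0("depth", seq_len(depth))),
                n_iter = n_iter, n_models = n_models,
                gate_alphas = gate_alphas)
    class(out) <- "fwe_simulation"
    out
  })
}

#' @export
print.fwe_simulation <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo FWE over %d null models, %d iterations:\n", x$n_models,
    x$n_iter))
  for (k in seq_along(x$prob))
    cat(sprintf("  depth %d: P = %.4f (MC SE %.4f; analytic %.4f)\n", k,
                x$prob[k], x$mc_se[k], x$analytic[k]))
  invisible(x)
}

#' Simulation-based power analysis for the mixed-model stage
#'
#' Simulates dyad-level data from the random-intercept model at the study
#' design (2 caregivers x 2 timepoints per subject) with the given
#' standardized coefficients, refits the full and baseline models per draw,
#' and reports rejection rates at \code{alpha} for the stress / caregiver /
#' time terms and for the likelihood-ratio model comparison, with binomial
#' 95\% confidence intervals.
#'
#' @param b_psi,b_caregiver,b_time true coefficients (standardized-response
#'   scale).
#' @param n_subjects subjects per simulated study.
#' @param intercept_sd,residual_sd variance components (SDs).
#' @param n_sim number of simulated studies (>= 100).
#' @param alpha test level.
#' @param seed seed.
#' @return a list of class \code{"power_estimate"}: \code{power} (named
#'   rates for \code{lrt}, \code{stress}, \code{caregiver}, \code{time}),
#'   \code{ci95} (matrix of binomial CIs), \code{n_sim},
#'   \code{prop_nonconverged}.
#' @export
power_simulation <- function(b_psi = 0.25, b_caregiver = 0.35, b_time = 0.35,
                             n_subjects = 26, intercept_sd = 0.5,
                             residual_sd = 1, n_sim = 5000, alpha = 0.05,
                             seed = 1) {
  n_sim <- check_count(n_sim, "n_sim", min = 100L)
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  with_seed(seed, {
    cl <- rep(seq_len(n_subjects), each = 4L)
    father <- rep(c(0, 0, 1, 1), n_subjects)
    t2 <- rep(c(0, 1, 0, 1), n_subjects)
    N <- length(cl)
    rej <- matrix(FALSE, n_sim, 4,
                  dimnames = list(NULL, c("lrt", "stress", "caregiver",
                                          "time")))
    failed <- 0L
    for (s in seq_len(n_sim)) {
      psi <- draw_psi(n_subjects)
      # caregiver-specific PSI attached to the dyad rows
      ids <- sprintf("S%03d", cl)
      cg <- ifelse(father == 1, "father", "mother")
      tp <- ifelse(t2 == 1, "T2", "T1")
      p_tot <- psi[paste(ids, cg, tp)]
      psi_std <- (p_tot - mean(p_tot)) / stats::sd(p_tot)
      y <- b_psi * psi_std + b_caregiver * father + b_time * t2 +
        stats::rnorm(n_subjects, 0, intercept_sd)[cl] +
        stats::rnorm(N, 0, residual_sd)
      y <- (y - mean(y)) / stats::sd(y)
      Xf <- cbind(1, psi_std, father, t2)
      ok <- tryCatch({
        ff <- lmm_fit_core(y, Xf, cl)
        fb <- lmm_fit_core(y, Xf[, -2, drop = FALSE], cl)
        chi2 <- max(0, 2 * (ff$loglik - fb$loglik))
        pv <- term_pvals(ff)
        rej[s, ] <- c(stats::pchisq(chi2, 1, lower.tail = FALSE) < alpha,
                      pv[2] < alpha, pv[3] < alpha, pv[4] < alpha)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) failed <- failed + 1L
    }
    used <- n_sim - failed
    if (failed > 0.05 * n_sim)
      warning("more than 5% of power simulations failed to converge",
              call. = FALSE)
    pow <- colSums(rej) / used
    ci <- t(vapply(pow, function(p) {
      se <- sqrt(p * (1 - p) / used)
      c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
    }, numeric(2)))
    colnames(ci) <- c("lo", "hi")
    out <- list(power = pow, ci95 = ci, n_sim = used,
                prop_nonconverged = failed / n_sim,
                truth = c(b_psi = b_psi, b_caregiver = b_caregiver,
                          b_time = b_time))
    class(out) <- "power_estimate"
    out
  })
}

#' @export
print.power_estimate <- function(x, ...) {
  cat("Simulation-based power (", x$n_sim, " simulations):\n", sep = "")
  for (nm in names(x$power))
    cat(sprintf("  %-9s %.3f  [%.3f, %.3f]\n", nm, x$power[nm],
                x$ci95[nm, "lo"], x$ci95[nm, "hi"]))
  invisible(x)
}
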