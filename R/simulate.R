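# Synthetic dyadic studies with known ground truth.
#
# Each simulated study mirrors the design of the target data: every subject
# (child) contributes four sessions, one per caregiver (mother, father) at
# each of two timepoints (T1, T2).  A session consists of (a) a
# second-by-second diarization produced by a four-state Markov turn-taking
# chain over {CHI, ADU, SIL, BOTH}, and (b) per-frame acoustic feature
# streams for each speaker.
#
# Generative model of the coupled features (see the methods vignette for the
# full account and the calibration experiments behind it):
#  - the child's prosody moves through piecewise-constant, heavy-tailed
#    "register" levels (dwell of a few seconds) plus window-level noise;
#  - a responsive caregiver alternates between engagement stretches -- during
#    which the adult tracks the child's last vocalized value and holds the
#    child's current register -- and disengaged stretches following an
#    independent fast-mixing process; the engaged fraction is
#    kappa / (1 + kappa), so coupling_strength = 0 removes every
#    moment-to-moment dependence;
#  - parenting stress, caregiver role and a subject-level intercept act on
#    the dyad's register turnover rate, rate = base * exp(-eta) with
#    eta = stress_effect * psi_std + caregiver_effect * I(father) + b_i.
#    Slower turnover ("stuck" interactions) raises recurrence and
#    determinism and lowers the laminarity-to-determinism balance, so a
#    positive stress_effect lowers LAM/DET, the direction of effect the
#    inferential pipeline must recover.

#' Simulation configuration
#'
#' Parameters of the synthetic dyad generator.  Defaults describe a study of
#' the target scale: 26 subjects (the analyzable sample after completeness
#' filtering), 10-minute free-play sessions, moderate coupling, and
#' stress/caregiver effects calibrated so that the planted stress effect on
#' the standardized LAM/DET scale is approximately -0.2 and the caregiver
#' effect approximately -0.35 (see the methods vignette).
#'
#' @param n_subjects number of children (>= 2); each contributes 4 sessions.
#' @param n_features number of acoustic features simulated.
#' @param n_coupled number of features carrying the planted coupling (the
#'   first \code{n_coupled}); the rest evolve independently of the partner.
#' @param session_seconds session duration in seconds (>= 60).
#' @param frame_rate acoustic frames per second (>= 2; aggregation to 500 ms
#'   windows makes the analysis insensitive to this rate).
#' @param coupling_strength kappa >= 0: the caregiver's engaged fraction of
#'   the session is kappa/(1+kappa); 0 removes moment-to-moment coupling.
#' @param stress_effect effect of standardized PSI on the dyad's
#'   log register-turnover rate (positive = slower turnover under stress,
#'   lowering LAM/DET).
#' @param caregiver_effect father-vs-mother shift on the same log-rate scale.
#' @param random_intercept_sd SD of the subject-level intercept on the log
#'   turnover rate.
#' @param residual_sd scale of the within-register window noise (> 0).
#' @param base_switch_rate baseline register switches per 500 ms window.
#' @param ar_rho lag-1 autocorrelation of the disengaged adult process.
#' @param frame_noise_sd SD of frame-level noise around the window latent.
#' @param seed integer master seed; identical seeds give bit-identical
#'   studies.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 26, n_features = 5, n_coupled = n_features,
                       session_seconds = 600, frame_rate = 10,
                       coupling_strength = 1, stress_effect = 0.8,
                       caregiver_effect = 1.2, random_intercept_sd = 0.5,
                       residual_sd = 1, base_switch_rate = 0.08,
                       ar_rho = 0.4, frame_noise_sd = 0.1, seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  n_features <- check_count(n_features, "n_features", min = 1L)
  n_coupled <- check_count(n_coupled, "n_coupled", min = 0L)
  if (n_coupled > n_features)
    stop_config("n_coupled", "cannot exceed n_features")
  session_seconds <- check_number(session_seconds, "session_seconds")
  if (session_seconds < 60)
    stop_config("session_seconds", "must be at least 60")
  frame_rate <- check_count(frame_rate, "frame_rate", min = 2L)
  coupling_strength <- check_number(coupling_strength, "coupling_strength")
  if (coupling_strength < 0)
    stop_config("coupling_strength", "must be >= 0")
  stress_effect <- check_number(stress_effect, "stress_effect")
  caregiver_effect <- check_number(caregiver_effect, "caregiver_effect")
  random_intercept_sd <- check_number(random_intercept_sd,
                                      "random_intercept_sd")
  if (random_intercept_sd < 0)
    stop_config("random_intercept_sd", "must be >= 0")
  residual_sd <- check_positive(residual_sd, "residual_sd")
  base_switch_rate <- check_positive(base_switch_rate, "base_switch_rate")
  ar_rho <- check_number(ar_rho, "ar_rho")
  if (abs(ar_rho) >= 1) stop_config("ar_rho", "must be in (-1, 1)")
  frame_noise_sd <- check_positive(frame_noise_sd, "frame_noise_sd")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    n_subjects = n_subjects, n_features = n_features, n_coupled = n_coupled,
    session_seconds = session_seconds, frame_rate = frame_rate,
    coupling_strength = coupling_strength, stress_effect = stress_effect,
    caregiver_effect = caregiver_effect,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
    base_switch_rate = base_switch_rate, ar_rho = ar_rho,
    frame_noise_sd = frame_noise_sd, seed = seed), class = "sim_config")
}

# Internal scales of the generative model (fixed; see vignette).
GEN <- list(level_sd = 3,       # spread of register levels (sinh-normal)
            window_noise = 2.6, # child window noise per residual_sd unit
            echo_noise = 0.15,  # adult tracking noise per residual_sd unit
            engage_mean_w = 12, # mean engagement-stretch length (windows)
            own_sd = 1)         # disengaged-process AR innovation scale

# Default turn-taking transition matrix (rows: from, cols: to), 1 s steps.
# A lively play interaction: frequent concurrent vocalization, short
# silences; per-speaker voiced fraction ~0.55 (child) / ~0.8 (adult).
turn_taking_matrix <- function() {
  rbind(
    CHI  = c(CHI = 0.45, ADU = 0.15, SIL = 0.03, BOTH = 0.37),
    ADU  = c(CHI = 0.06, ADU = 0.55, SIL = 0.04, BOTH = 0.35),
    SIL  = c(CHI = 0.25, ADU = 0.45, SIL = 0.08, BOTH = 0.22),
    BOTH = c(CHI = 0.12, ADU = 0.25, SIL = 0.03, BOTH = 0.60))
}

# Labeling used by the general-similarity generator.  Two deliberate
# differences from the coupled world's chain: no BOTH state (concurrent
# vocalization assigns identical frames to both speakers, which is itself a
# moment-level coordination channel), and no memory (iid labels per second),
# so the adult's voicing mask carries no run structure beyond the 1 s
# diarization granularity.  Multi-second dwells would otherwise interact
# with the adult's marginal and leak a temporal signature into a world
# meant to contain none.
similarity_turn_matrix <- function() {
  p <- c(CHI = 0.35, ADU = 0.55, SIL = 0.10)
  rbind(CHI = p, ADU = p, SIL = p)
}

markov_labels <- function(n_seconds, P = turn_taking_matrix()) {
  states <- colnames(P)
  lab <- character(n_seconds)
  cur <- "SIL"
  u <- stats::runif(n_seconds)
  cum <- t(apply(P, 1, cumsum))
  for (t in seq_len(n_seconds)) {
    cur <- states[which(u[t] <= cum[cur, ])[1]]
    lab[t] <- cur
  }
  lab
}

ar1 <- function(n, rho, sd_marginal = 1) {
  innov <- stats::rnorm(n, 0, sd_marginal * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sd_marginal)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# piecewise-constant heavy-tailed register levels
register_levels <- function(W, switch_rate, level_sd = GEN$level_sd) {
  flips <- stats::runif(W) < min(switch_rate, 0.7)
  flips[1] <- TRUE
  id <- cumsum(flips)
  lev <- level_sd * sinh(stats::rnorm(max(id)))
  lev[id]
}

# One session's latent window series, labels, and frame table.
simulate_session <- function(cfg, session_id, switch_rate, mode = "coupled",
                             burst_prob_adult = 0.1) {
  S <- as.integer(cfg$session_seconds)
  W <- as.integer(ceiling(S / 0.5))
  K <- cfg$n_features
  lab <- if (mode == "similarity") markov_labels(S, similarity_turn_matrix())
         else markov_labels(S)
  lab_w <- rep(lab, each = 2L)[seq_len(W)]
  adult_speaks <- lab_w %in% c("ADU", "BOTH")
  child_speaks <- lab_w %in% c("CHI", "BOTH")
  wn <- GEN$window_noise * cfg$residual_sd
  en <- GEN$echo_noise * cfg$residual_sd

  child <- matrix(0, W, K)
  adult <- matrix(0, W, K)
  if (mode == "similarity") {
    # general acoustic similarity without coordination: the child carries a
    # slow sinusoidal drift; the adult's windows are drawn iid from the
    # *marginal* of the same drift process (the sinusoid evaluated at iid
    # phases), so the two speakers' distributions match while the adult is
    # window-exchangeable -- there is no dyadic alignment and no
    # within-speaker temporal structure for a window permutation to
    # destroy.  Stress modulates a purely marginal property of the adult's
    # prosody: the rate of iid heavy excursions (vocal-effort outbursts).
    period_w <- 120
    for (k in seq_len(K)) {
      tw <- 2 * pi * seq_len(W) / period_w
      child[, k] <- 0.8 * GEN$level_sd *
        sin(tw + stats::runif(1, 0, 2 * pi)) + ar1(W, 0.6, wn / 2)
      burst <- (stats::runif(W) < burst_prob_adult) *
        sample(c(-1, 1), W, replace = TRUE) * 2 * GEN$level_sd
      adult[, k] <- 0.8 * GEN$level_sd *
        sin(stats::runif(W, 0, 2 * pi)) +
        stats::rnorm(W, 0, wn / 2) + burst
    }
  } else {
    g <- cfg$coupling_strength / (1 + cfg$coupling_strength)
    for (k in seq_len(K)) {
      clev <- register_levels(W, switch_rate)
      ck <- clev + stats::rnorm(W, 0, wn)
      own <- GEN$level_sd * sinh(ar1(W, cfg$ar_rho, GEN$own_sd)) +
        stats::rnorm(W, 0, 1)
      if (k <= cfg$n_coupled && g > 0) {
        ef <- stats::runif(W) < 1 / GEN$engage_mean_w
        ef[1] <- TRUE
        eid <- cumsum(ef)
        engaged <- (stats::runif(max(eid)) < g)[eid]
        # track the child's last vocalized value; hold the register during
        # child pauses
        echo <- ifelse(c(FALSE, child_speaks[-W]), c(0, ck[-W]), clev)
        adult[, k] <- ifelse(adult_speaks & engaged,
                             echo + stats::rnorm(W, 0, en), own)
      } else {
        adult[, k] <- own
      }
      child[, k] <- ck
    }
  }

  segments <- data.frame(session_id = session_id,
                         t_start_s = seq_len(S) - 1,
                         t_end_s = seq_len(S), label = lab,
                         stringsAsFactors = FALSE)
  # frames for vocalized seconds; BOTH seconds mix the two latents and are
  # assigned to both speakers downstream
  voc <- which(lab != "SIL")
  fr <- cfg$frame_rate
  if (length(voc)) {
    t_s <- rep(voc - 1, each = fr) + rep(seq_len(fr) - 1, length(voc)) / fr
    win <- floor(t_s / 0.5) + 1L
    spk <- rep(lab[voc], each = fr)
    vals <- matrix(NA_real_, length(t_s), K)
    is_chi <- spk == "CHI"
    is_adu <- spk == "ADU"
    is_both <- spk == "BOTH"
    vals[is_chi, ] <- child[win[is_chi], , drop = FALSE]
    vals[is_adu, ] <- adult[win[is_adu], , drop = FALSE]
    vals[is_both, ] <- (child[win[is_both], , drop = FALSE] +
                          adult[win[is_both], , drop = FALSE]) / 2
    vals <- vals + stats::rnorm(length(vals), 0, cfg$frame_noise_sd)
    colnames(vals) <- sprintf("f%d", seq_len(K))
    frames <- data.frame(session_id = session_id, t_s = t_s, speaker = spk,
                         stringsAsFactors = FALSE)
    frames <- cbind(frames, as.data.frame(vals))
  } else {
    frames <- data.frame(session_id = character(0), t_s = numeric(0),
                         speaker = character(0))
    for (k in seq_len(K)) frames[[sprintf("f%d", k)]] <- numeric(0)
  }
  list(segments = segments, frames = frames)
}

simulate_study_impl <- function(cfg, mode) {
  ids <- sprintf("S%03d", seq_len(cfg$n_subjects))
  psi <- with_seed(derive_seed(cfg$seed, "psi"), draw_psi(cfg$n_subjects))
  b <- with_seed(derive_seed(cfg$seed, "intercepts"),
                 stats::rnorm(cfg$n_subjects, 0, cfg$random_intercept_sd))
  names(b) <- ids
  grid <- expand.grid(timepoint = c("T1", "T2"),
                      caregiver = c("mother", "father"),
                      subject_id = ids, stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject_id, grid$caregiver, grid$timepoint),
               c("subject_id", "caregiver", "timepoint")]
  rownames(grid) <- NULL
  grid$session_id <- sprintf("%s_%s_%s", grid$subject_id,
                             substr(grid$caregiver, 1, 1), grid$timepoint)
  grid$psi_total <- psi[paste(grid$subject_id, grid$caregiver,
                              grid$timepoint)]
  psi_std <- (grid$psi_total - 80) / 20  # population standardization
  father <- as.numeric(grid$caregiver == "father")
  eta <- cfg$stress_effect * psi_std + cfg$caregiver_effect * father +
    b[grid$subject_id]
  grid$eta <- eta
  # stress slows register turnover (lowering LAM/DET); clamped for sanity
  grid$switch_rate <- pmin(pmax(cfg$base_switch_rate * exp(-eta), 0.005), 0.5)
  # similarity mode: probability of an iid heavy-excursion window in the
  # adult's prosody (a marginal property), on a logistic scale in eta
  grid$burst_prob <- stats::plogis(-1.5 + eta)
  grid$coupling_strength <- cfg$coupling_strength
  sessions <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- with_seed(derive_seed(cfg$seed, "session", i),
                   simulate_session(cfg, grid$session_id[i],
                                    grid$switch_rate[i], mode = mode,
                                    burst_prob_adult = grid$burst_prob[i]))
    s$meta <- list(session_id = grid$session_id[i],
                   subject_id = grid$subject_id[i],
                   caregiver = grid$caregiver[i],
                   timepoint = grid$timepoint[i],
                   psi_total = grid$psi_total[i])
    sessions[[i]] <- s
  }
  structure(list(sessions = sessions, truth = grid, config = cfg,
                 mode = mode), class = "synthetic_study")
}

#' Simulate a synthetic dyadic study
#'
#' Generates a complete study (diarized segments, per-frame feature streams
#' and metadata for 4 sessions per subject) with known coupling, stress,
#' caregiver-role and subject effects.  See the package vignette for the
#' generative model and the calibration of its defaults.
#'
#' @param config a [sim_config()].
#' @return an object of class \code{"synthetic_study"}: \code{sessions} (a
#'   list of \code{segments} / \code{frames} / \code{meta} per session),
#'   \code{truth} (the per-dyad generating parameters) and \code{config}.
#' @examples
#' study <- simulate_study(sim_config(n_subjects = 2, session_seconds = 60,
#'                                    n_features = 1, frame_rate = 4))
#' study$truth[, c("session_id", "psi_total", "switch_rate")]
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  simulate_study_impl(config, mode = "coupled")
}

#' Simulate a null study (no coupling, no stress or caregiver effects)
#'
#' As [simulate_study()] but with \code{coupling_strength},
#' \code{stress_effect} and \code{caregiver_effect} forced to 0; the
#' \code{truth} record reflects the forcing.  Used for type-I-error
#' calibration of the inferential pipeline.
#'
#' @param config a [sim_config()].
#' @return a \code{"synthetic_study"}.
#' @export
simulate_null_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$coupling_strength <- 0
  config$stress_effect <- 0
  config$caregiver_effect <- 0
  simulate_study_impl(config, mode = "coupled")
}

#' Simulate a general-similarity study (no moment-to-moment coupling)
#'
#' Generates dyads whose speakers share a slow session-level drift (general
#' acoustic similarity) but have no window-level temporal coupling; parenting
#' stress and caregiver role modulate the adult's drift share, a marginal
#' property that survives temporal permutation.  Any stress association
#' detected in such a study therefore reflects general similarity, not
#' moment-to-moment coordination -- the temporal-specificity permutation test
#' must \emph{not} attribute it to coordination.  Used for
#' discriminant-validity checks of the specificity gate.
#'
#' @param config a [sim_config()]; \code{coupling_strength} is ignored.
#' @return a \code{"synthetic_study"}.
#' @export
simulate_similarity_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  simulate_study_impl(config, mode = "similarity")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic dyadic study (", x$mode, "): ",
      x$config$n_subjects, " subjects x 4 sessions, ",
      x$config$n_features, " features, ",
      x$config$session_seconds, " s/session\n", sep = "")
  invisible(x)
}
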