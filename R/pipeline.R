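# End-to-end orchestration: series construction -> CRQA -> stability filter
# -> screening -> mixed models -> sensitivity -> specificity -> selection.

#' Prepare a study for CRQA: build, prune and scale every session
#'
#' Applies [build_series()], [remove_long_silence()] and [robust_scale()] to
#' each session of a study and collects the session metadata.
#'
#' @param study a \code{"synthetic_study"} ([simulate_study()]), or a list
#'   with elements \code{sessions} (each a list of \code{segments},
#'   \code{frames}, \code{meta}) assembled from files.
#' @param params a [crqa_params()] carried along for downstream stages.
#' @param silence_threshold_s joint-silence removal threshold (seconds).
#' @return a list of class \code{"prepared_study"}: \code{series} (scaled
#'   \code{dyad_series} per session), \code{meta} (data frame of session
#'   metadata: \code{session_id}, \code{subject_id}, \code{caregiver},
#'   \code{timepoint}, \code{psi_total}), \code{params}.
#' @export
prepare_study <- function(study, params = crqa_params(),
                          silence_threshold_s = 25) {
  sessions <- study$sessions
  series <- vector("list", length(sessions))
  meta <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    ds <- build_series(s$segments, s$frames, meta = s$meta)
    ds <- robust_scale(ds)
    ds <- remove_long_silence(ds, silence_threshold_s)
    series[[i]] <- ds
    meta[[i]] <- as.data.frame(s$meta[c("session_id", "subject_id",
                                        "caregiver", "timepoint",
                                        "psi_total")],
                               stringsAsFactors = FALSE)
  }
  structure(list(series = series, meta = do.call(rbind, meta),
                 params = params), class = "prepared_study")
}

#' CRQA metric table for a whole prepared study
#'
#' Runs [crqa_session()] over every session and stacks the per-feature rows;
#' one row per (session, feature).
#'
#' @param prepared a \code{prepared_study}.
#' @return data frame with metadata columns, \code{feature}, the CRQA
#'   metrics and \code{unstable}.
#' @export
crqa_study <- function(prepared) {
  stopifnot(inherits(prepared, "prepared_study"))
  do.call(rbind, lapply(prepared$series, crqa_session,
                        params = prepared$params))
}

#' Pipeline configuration
#'
#' @param simulate a [sim_config()] to generate the study, or \code{NULL} to
#'   read it from \code{segments_path} / \code{frames_path} /
#'   \code{metadata_path}.
#' @param segments_path,frames_path,metadata_path input CSVs (ignored when
#'   simulating).
#' @param output_dir directory for result CSVs and the manifest.
#' @param crqa a [crqa_params()].
#' @param gates a [gate_config()].
#' @param ratios composite ratios to model.
#' @param n_boot,n_perm,n_fwe resampling counts (LOSO bootstrap, temporal
#'   permutations, FWE Monte Carlo iterations).
#' @param silence_threshold_s joint-silence removal threshold.
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(simulate = NULL, segments_path = NULL,
                            frames_path = NULL, metadata_path = NULL,
                            output_dir = tempfile("dyadsync_run_"),
                            crqa = crqa_params(), gates = gate_config(),
                            ratios = c("det_rec", "lam_det"),
                            n_boot = 1000, n_perm = 100, n_fwe = 50000,
                            silence_threshold_s = 25, seed = 1) {
  if (is.null(simulate)) {
    if (is.null(segments_path) || is.null(frames_path) ||
        is.null(metadata_path))
      stop_config("paths",
        "segments_path, frames_path and metadata_path are required unless simulating")
  } else stopifnot(inherits(simulate, "sim_config"))
  structure(list(simulate = simulate, segments_path = segments_path,
                 frames_path = frames_path, metadata_path = metadata_path,
                 output_dir = output_dir, crqa = crqa, gates = gates,
                 ratios = match.arg(ratios, c("det_rec", "lam_det"),
                                    several.ok = TRUE),
                 n_boot = check_count(n_boot, "n_boot"),
                 n_perm = check_count(n_perm, "n_perm"),
                 n_fwe = check_count(n_fwe, "n_fwe", min = 1000L),
                 silence_threshold_s = silence_threshold_s,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

read_study <- function(cfg) {
  seg <- read_segments(cfg$segments_path)
  frm <- read_frames(cfg$frames_path)
  met <- read_metadata(cfg$metadata_path)
  sessions <- lapply(seq_len(nrow(met)), function(i) {
    sid <- met$session_id[i]
    list(segments = seg[seg$session_id == sid, , drop = FALSE],
         frames = frm[frm$session_id == sid, , drop = FALSE],
         meta = as.list(met[i, , drop = FALSE]))
  })
  list(sessions = sessions, truth = NULL)
}

#' Run the full synchrony analysis pipeline
#'
#' Executes, in order: study acquisition (simulate or read), series
#' construction and scaling, CRQA, stability filtering, correlation
#' screening, mixed-model fitting with likelihood-ratio comparison, LOSO
#' parametric-bootstrap sensitivity, temporal-permutation specificity,
#' sequential gate selection, and the family-wise error Monte Carlo.  All
#' result tables are written as CSVs under \code{cfg$output_dir} and a run
#' manifest records the configuration hash, seed and per-stage row counts.
#' Reruns with the same configuration and seed are byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest (invisibly contains all stage outputs under
#'   \code{$results}).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)
  # a failing stage still leaves a manifest recording how far the run got
  on.exit(writeLines(
    c(sprintf("dyadsync pipeline run (seed %d): INCOMPLETE", cfg$seed),
      paste("stages completed:", paste(stages, collapse = " -> "))),
    file.path(cfg$output_dir, "manifest.txt")))

  study <- if (is.null(cfg$simulate)) read_study(cfg) else
    simulate_study(cfg$simulate)
  done("study")

  prepared <- prepare_study(study, cfg$crqa, cfg$silence_threshold_s)
  done("series")

  metrics <- crqa_study(prepared)
  write_table_csv(metrics, file.path(cfg$output_dir, "metrics.csv"))
  done("crqa")

  filt <- stability_filter(metrics)
  done("stability_filter")

  scr <- screen_correlations(
    filt$data, metrics = c("rec", "det", "lam", "det_rec", "lam_det"),
    outcomes = "psi_total", all = FALSE)
  write_table_csv(scr, file.path(cfg$output_dir, "screening.csv"))
  done("screening")

  # keep only sessions of retained subjects for the resampling stages
  keep <- prepared$meta$subject_id %in% filt$subjects
  prepared$series <- prepared$series[keep]
  prepared$meta <- prepared$meta[keep, , drop = FALSE]

  models <- list(); sens <- list(); spec <- list()
  for (feat in filt$features) for (ratio in cfg$ratios) {
    d <- filt$data[filt$data$feature == feat, , drop = FALSE]
    full <- synchrony_lmm(d, dv = ratio)
    base <- synchrony_lmm(d, dv = ratio, include_stress = FALSE)
    cmp <- lrt_compare(full, base)
    # robust (CR2) stress inference replaces the model-based one when the
    # distributional assumptions are flagged
    flags <- check_assumptions(full)
    rob_se <- rob_p <- NA_real_
    if (flags$any_violation && full$n_subjects >= 4) {
      rob <- cr2_inference(full)
      rob_se <- rob$se[rob$term == "psi_std"]
      rob_p <- rob$p[rob$term == "psi_std"]
    }
    models[[length(models) + 1L]] <- data.frame(
      feature = feat, ratio = ratio, chi2 = cmp$chi2, p_lrt = cmp$p_lrt,
      delta_aic = cmp$delta_aic, delta_bic = cmp$delta_bic,
      marginal_r2 = marginal_r2(full),
      b_psi = coef(full)[["psi_std"]],
      se_psi = full$coefficients$se[full$coefficients$term == "psi_std"],
      assumptions_ok = !flags$any_violation,
      cr2_se_psi = rob_se, cr2_p_psi = rob_p, stringsAsFactors = FALSE)
    sb <- loso_bootstrap(d, dv = ratio, n_boot = cfg$n_boot,
                         seed = derive_seed(cfg$seed, paste0("loso_", feat),
                                            match(ratio, cfg$ratios)))
    sens[[length(sens) + 1L]] <- data.frame(
      feature = feat, ratio = ratio, chi2_mean = sb$chi2_mean,
      p_anova = sb$p_anova, p_dist = sb$p_dist, p_stress = sb$p_stress,
      p_stress_dist = sb$p_stress_dist, p_caregiver = sb$p_caregiver,
      p_caregiver_dist = sb$p_caregiver_dist, p_time = sb$p_time,
      p_time_dist = sb$p_time_dist, stringsAsFactors = FALSE)
    sp <- permutation_specificity(
      prepared, feat, ratio, n_perm = cfg$n_perm,
      seed = derive_seed(cfg$seed, paste0("spec_", feat),
                         match(ratio, cfg$ratios)))
    spec[[length(spec) + 1L]] <- data.frame(
      feature = feat, ratio = ratio, p_rand = sp$p_rand,
      p_rand_dist = sp$p_rand_dist, p_spec_model = sp$p_spec_model,
      p_spec_stress = sp$p_spec_stress, stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, models)
  sens_df <- do.call(rbind, sens)
  spec_df <- do.call(rbind, spec)
  write_table_csv(models, file.path(cfg$output_dir, "models.csv"))
  done("models")
  write_table_csv(sens_df, file.path(cfg$output_dir, "sensitivity.csv"))
  done("sensitivity")
  write_table_csv(spec_df, file.path(cfg$output_dir, "specificity.csv"))
  done("specificity")

  sel <- sequential_gates(sens_df, spec_df, cfg$gates)
  write_table_csv(sel$table, file.path(cfg$output_dir, "selection.csv"))
  fwe <- fwe_simulation(nrow(models),
                        c(cfg$gates$alpha_overall,
                          cfg$gates$alpha_specificity,
                          cfg$gates$alpha_stress,
                          cfg$gates$alpha_stress_spec),
                        n_iter = cfg$n_fwe,
                        seed = derive_seed(cfg$seed, "fwe"))
  done("selection")

  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadsync")),
    seed = cfg$seed,
    config_hash = sum(utf8ToInt(paste(deparse(
      cfg[setdiff(names(cfg), "output_dir")]), collapse = ""))),
    stages_complete = stages,
    rows = c(sessions = length(prepared$series), metrics = nrow(metrics),
             retained_subjects = filt$n_subjects,
             retained_features = filt$n_features, models = nrow(models)),
    selected = sel$selected,
    fwe = fwe$prob,
    output_dir = cfg$output_dir)
  manifest$results <- list(metrics = metrics, filter = filt,
                           screening = scr, models = models,
                           sensitivity = sens_df, specificity = spec_df,
                           selection = sel, fwe = fwe)
  class(manifest) <- "pipeline_manifest"
  on.exit()  # completed: replace the partial-run manifest
  writeLines(utils::capture.output(utils::str(
    manifest[setdiff(names(manifest), "results")])),
    file.path(cfg$output_dir, "manifest.txt"))
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Pipeline run complete:", length(x$stages_complete), "stages (",
      paste(x$stages_complete, collapse = " -> "), ")\n")
  cat("Retained:", x$rows["retained_subjects"], "subjects,",
      x$rows["retained_features"], "features;", x$rows["models"],
      "candidate models\n")
  if (nrow(x$selected)) {
    cat("Selected models:\n"); print(x$selected, row.names = FALSE)
  } else cat("No model passed the full selection.\n")
  invisible(x)
}
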