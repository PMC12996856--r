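# Small programmatic fixtures shared across test files.

# A hand-written two-speaker session: seconds 0-4 child, 5-9 adult.
toy_segments <- function(session_id = "T1") {
  data.frame(session_id = session_id, t_start_s = 0:9, t_end_s = 1:10,
             label = c(rep("CHI", 5), rep("ADU", 5)),
             stringsAsFactors = FALSE)
}

# Frames at a given rate with a single feature equal to `value_fun(t)`.
toy_frames <- function(segments, frame_rate = 4,
                       value_fun = function(t) sin(t)) {
  voc <- segments[segments$label != "SIL", , drop = FALSE]
  t_s <- as.vector(vapply(voc$t_start_s, function(s)
    s + (seq_len(frame_rate) - 1) / frame_rate, numeric(frame_rate)))
  data.frame(session_id = segments$session_id[1], t_s = t_s,
             speaker = rep(voc$label, each = frame_rate),
             f1 = value_fun(t_s), stringsAsFactors = FALSE)
}

# Tiny fast simulation config for pipeline-level tests.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 6, n_features = 2,
                                 session_seconds = 60, frame_rate = 4),
                            list(...))
  do.call(sim_config, args)
}

# Dyad-level CRQA table for one simulated study (single call point so the
# heavier tests share the code path).
study_table <- function(study, params = crqa_params()) {
  prep <- prepare_study(study, params)
  list(prep = prep, table = crqa_study(prep))
}
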