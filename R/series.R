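# Construction of paired per-speaker prosodic time series from diarized
# segments and frame-level acoustic features.
#
# Segments are second-by-second speaker labels (CHI / ADU / SIL / BOTH);
# frames are per-timestamp acoustic descriptor vectors.  Both are turned into
# two aligned matrices (child, adult) of 500 ms windows: a speaker's window
# is the mean of that speaker's frames in the window while vocalizing, and a
# silence placeholder otherwise.  Concurrent vocalization (BOTH) assigns the
# same frames to both speakers.

SEGMENT_LABELS <- c("CHI", "ADU", "SIL", "BOTH")

new_dyad_series <- function(child, adult, speaking_child, speaking_adult,
                            feature_names, session_id = NA_character_,
                            meta = list(), window_s = 0.5, scaled = FALSE,
                            unstable_features = character(0),
                            degenerate = FALSE) {
  stopifnot(identical(dim(child), dim(adult)))
  structure(list(session_id = session_id, window_s = window_s,
                 child = child, adult = adult,
                 speaking_child = speaking_child,
                 speaking_adult = speaking_adult,
                 feature_names = feature_names, meta = meta,
                 scaled = scaled, unstable_features = unstable_features,
                 degenerate = degenerate),
            class = "dyad_series")
}

#' @export
print.dyad_series <- function(x, ...) {
  cat("Dyad series", if (!is.na(x$session_id)) paste0("'", x$session_id, "'"),
      ":", nrow(x$child), "windows x", length(x$feature_names), "features",
      if (x$scaled) "(scaled)" else "(raw)", "\n")
  if (x$degenerate) cat("(degenerate: no windows remain)\n")
  invisible(x)
}

validate_segments <- function(segments) {
  req <- c("session_id", "t_start_s", "t_end_s", "label")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols))
    stop("segment table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !segments$label %in% SEGMENT_LABELS
  if (any(bad))
    stop("unknown segment label(s) ",
         paste(unique(segments$label[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "),
         "; labels must be one of ", paste(SEGMENT_LABELS, collapse = "/"),
         call. = FALSE)
  segments <- segments[order(segments$t_start_s), , drop = FALSE]
  if (any(abs(segments$t_end_s - segments$t_start_s - 1) > 1e-9))
    stop("segments must be contiguous 1 s rows", call. = FALSE)
  gaps <- which(diff(segments$t_start_s) != 1)
  if (length(gaps) || segments$t_start_s[1] != 0)
    stop("gap in segment coverage around t = ",
         if (length(gaps)) segments$t_end_s[gaps[1]] else 0, " s",
         call. = FALSE)
  segments
}

#' Build aligned per-speaker window series for one session
#'
#' Aggregates frame-level features into 500 ms windows separately for the
#' child and the adult.  For each window and speaker: the arithmetic mean of
#' that speaker's frames when the diarization says the speaker vocalizes in
#' that second; the \code{silence_profile} vector otherwise.  Seconds labeled
#' \code{BOTH} contribute the same frames to both speakers' series.  Time
#' windows are half-open \eqn{[t, t + 0.5)}.
#'
#' @param segments one session's segment table: columns \code{session_id},
#'   \code{t_start_s}, \code{t_end_s}, \code{label} (contiguous 1 s rows,
#'   labels in CHI/ADU/SIL/BOTH).
#' @param frames one session's frame table: columns \code{session_id},
#'   \code{t_s}, \code{speaker}, then one column per feature.
#' @param silence_profile numeric vector (one value per feature) substituted
#'   for silent windows, interpreted on the robustly scaled scale (silent
#'   windows pass through [robust_scale()] unchanged).  The default of -4
#'   places silence in the far tail of the scaled speech distribution,
#'   reflecting that a silent segment's low-level descriptors (near-zero
#'   loudness, undefined pitch) are extreme relative to speech; a
#'   centre-of-distribution placeholder would make speech and silence
#'   spuriously recurrent.
#' @param meta optional named list of dyad metadata (\code{subject_id},
#'   \code{caregiver}, \code{timepoint}, \code{psi_total}, ...), carried
#'   through to downstream stages.
#' @param window_s window length in seconds (fixed at 0.5 in the analysis).
#' @return a \code{dyad_series} object: matrices \code{child} and
#'   \code{adult} of identical shape (windows x features), per-speaker
#'   speaking masks, feature names and metadata.  The number of windows is
#'   \code{ceiling(session_seconds / window_s)}.
#' @export
build_series <- function(segments, frames, silence_profile = NULL,
                         meta = list(), window_s = 0.5) {
  window_s <- check_positive(window_s, "window_s")
  segments <- validate_segments(segments)
  feat_cols <- setdiff(names(frames), c("session_id", "t_s", "speaker"))
  if (!length(feat_cols)) stop("frame table has no feature columns",
                               call. = FALSE)
  K <- length(feat_cols)
  if (is.null(silence_profile)) silence_profile <- rep(-4, K)
  if (length(silence_profile) != K)
    stop("silence_profile must have one value per feature (", K, ")",
         call. = FALSE)
  session_seconds <- max(segments$t_end_s)
  n_win <- as.integer(ceiling(session_seconds / window_s))

  # speaking masks per window, from the label of the containing second
  sec_of_win <- floor((seq_len(n_win) - 1) * window_s)
  lab <- segments$label[match(sec_of_win, segments$t_start_s)]
  speaking_child <- lab %in% c("CHI", "BOTH")
  speaking_adult <- lab %in% c("ADU", "BOTH")

  child <- matrix(rep(silence_profile, each = n_win), n_win, K)
  adult <- matrix(rep(silence_profile, each = n_win), n_win, K)
  colnames(child) <- colnames(adult) <- feat_cols

  if (nrow(frames)) {
    win <- floor(frames$t_s / window_s) + 1L
    ok <- win >= 1L & win <= n_win
    fm <- as.matrix(frames[ok, feat_cols, drop = FALSE])
    win <- win[ok]
    spk <- frames$speaker[ok]
    fill <- function(target, use) {
      if (!any(use)) return(target)
      sums <- rowsum(fm[use, , drop = FALSE], win[use])
      cnts <- as.vector(table(win[use]))
      idx <- as.integer(rownames(sums))
      target[idx, ] <- sums / cnts
      target
    }
    child <- fill(child, spk %in% c("CHI", "BOTH"))
    adult <- fill(adult, spk %in% c("ADU", "BOTH"))
    # frames never override the diarization: windows the segment table calls
    # silent keep the placeholder
    child[!speaking_child, ] <- matrix(rep(silence_profile, each =
      sum(!speaking_child)), ncol = K)
    adult[!speaking_adult, ] <- matrix(rep(silence_profile, each =
      sum(!speaking_adult)), ncol = K)
  }

  new_dyad_series(child, adult, speaking_child, speaking_adult, feat_cols,
                  session_id = segments$session_id[1], meta = meta,
                  window_s = window_s)
}

#' Remove prolonged joint silences from a dyad series
#'
#' Deletes every maximal run of windows in which both speakers are silent
#' whose duration is at least \code{threshold_s} (default 25 s), from both
#' series simultaneously, preserving the order and pairing of the remaining
#' windows.  A series left with no windows is flagged \code{degenerate}.
#'
#' @param series a \code{dyad_series}.
#' @param threshold_s minimum joint-silence duration to remove, seconds.
#' @return the pruned \code{dyad_series}.
#' @export
remove_long_silence <- function(series, threshold_s = 25) {
  stopifnot(inherits(series, "dyad_series"))
  threshold_s <- check_positive(threshold_s, "threshold_s")
  both_silent <- !series$speaking_child & !series$speaking_adult
  r <- rle(both_silent)
  min_run <- ceiling(threshold_s / series$window_s)
  drop_run <- r$values & r$lengths >= min_run
  keep <- rep(!drop_run, r$lengths)
  series$child <- series$child[keep, , drop = FALSE]
  series$adult <- series$adult[keep, , drop = FALSE]
  series$speaking_child <- series$speaking_child[keep]
  series$speaking_adult <- series$speaking_adult[keep]
  series$degenerate <- nrow(series$child) == 0
  series
}

#' Robust scaling (median / IQR)
#'
#' Robustly scales values to \eqn{(x - \mathrm{median}) / \mathrm{IQR}},
#' with the IQR computed from linear-interpolation (type 7) quantiles.  For a
#' \code{dyad_series}, scaling is applied per speaker and per feature,
#' independently, using only that speaker's vocalized windows; silent windows
#' keep the silence placeholder, which therefore lives on the scaled scale
#' (default -4, the far tail of the speech distribution).
#' A speaker-feature vector with zero IQR cannot be scaled: the feature is
#' recorded in \code{unstable_features} (and will be flagged by the CRQA
#' stability filter), never silently zeroed.
#'
#' @param x a numeric vector, or a \code{dyad_series}.
#' @param ... unused.
#' @return an object of the same type, scaled.
#' @examples
#' robust_scale(c(1, 2, 3, 4, 5))  # -1 -0.5 0 0.5 1
#' @export
robust_scale <- function(x, ...) UseMethod("robust_scale")

#' @rdname robust_scale
#' @export
robust_scale.default <- function(x, ...) {
  if (length(x) < 4) stop("robust scaling needs at least 4 values",
                          call. = FALSE)
  iqr <- stats::IQR(x, type = 7)
  if (iqr < 1e-12)
    stop("zero IQR: vector cannot be robustly scaled", call. = FALSE)
  (x - stats::median(x)) / iqr
}

#' @rdname robust_scale
#' @export
robust_scale.dyad_series <- function(x, ...) {
  if (x$scaled) return(x)
  unstable <- character(0)
  scale_one <- function(mat, mask) {
    for (k in seq_len(ncol(mat))) {
      v <- mat[mask, k]
      if (length(v) < 4) { unstable <<- c(unstable, colnames(mat)[k]); next }
      iqr <- stats::IQR(v, type = 7)
      if (iqr < 1e-12) { unstable <<- c(unstable, colnames(mat)[k]); next }
      mat[mask, k] <- (v - stats::median(v)) / iqr
    }
    mat
  }
  x$child <- scale_one(x$child, x$speaking_child)
  x$adult <- scale_one(x$adult, x$speaking_adult)
  x$unstable_features <- unique(unstable)
  # features that cannot be scaled carry no usable signal for this session:
  # freeze them at the placeholder so CRQA flags them unstable downstream
  for (f in x$unstable_features) {
    x$child[, f] <- 0
    x$adult[, f] <- 0
  }
  x$scaled <- TRUE
  x
}
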