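# Reading and writing of the pipeline's delimited-text formats.

check_schema <- function(df, required, what, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(what, " file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

#' Read / write segment, frame and metadata tables
#'
#' CSV schemas: segments \code{session_id, t_start_s, t_end_s, label}
#' (labels CHI/ADU/SIL/BOTH); frames \code{session_id, t_s, speaker,
#' <feature columns>}; metadata \code{session_id, subject_id, caregiver,
#' timepoint, psi_total} plus optional outcome columns.  Writing then
#' reading a table is the identity.
#'
#' @param path file path.
#' @return a data frame.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segments file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, c("session_id", "t_start_s", "t_end_s", "label"),
                     "segments", path)
  bad <- which(!df$label %in% SEGMENT_LABELS)
  if (length(bad))
    stop("segments file '", path, "': invalid label '", df$label[bad[1]],
         "' at row ", bad[1], call. = FALSE)
  df
}

#' @rdname pipeline_io
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("frames file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("session_id", "t_s", "speaker"), "frames", path)
}

#' @rdname pipeline_io
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("session_id", "subject_id", "caregiver", "timepoint",
                     "psi_total"), "metadata", path)
}

#' @rdname pipeline_io
#' @param df table to write.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dyad series as a wide CSV
#'
#' Columns: \code{speaker} (CHI/ADU), \code{window_index}, \code{speaking},
#' then one column per feature.
#'
#' @param series a \code{dyad_series}.
#' @param path output path.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dyad_series"))
  n <- nrow(series$child)
  df <- rbind(
    data.frame(speaker = "CHI", window_index = seq_len(n),
               speaking = series$speaking_child, series$child,
               check.names = FALSE),
    data.frame(speaker = "ADU", window_index = seq_len(n),
               speaking = series$speaking_adult, series$adult,
               check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export / import segments in RTTM format
#'
#' Writes one \code{SPEAKER} line per vocalized second (CHI and ADU; a BOTH
#' second produces one line for each speaker).  Silence is implicit.
#' \code{read_rttm()} reconstructs the segment table given the session
#' duration, mapping concurrent CHI+ADU seconds back to BOTH and uncovered
#' seconds to SIL.
#'
#' @param segments a segment table.
#' @param path file path.
#' @param session_seconds total session duration for reconstruction.
#' @return \code{read_rttm()} returns a segment table.
#' @export
write_rttm <- function(segments, path) {
  segments <- validate_segments(segments)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(segments))) {
    lb <- segments$label[i]
    spk <- switch(lb, CHI = "CHI", ADU = "ADU", BOTH = c("CHI", "ADU"),
                  SIL = character(0))
    for (s in spk)
      writeLines(sprintf("SPEAKER %s 1 %.3f %.3f <NA> <NA> %s <NA> <NA>",
                         segments$session_id[i], segments$t_start_s[i],
                         segments$t_end_s[i] - segments$t_start_s[i], s),
                 con)
  }
  invisible(path)
}

#' @rdname write_rttm
#' @export
read_rttm <- function(path, session_seconds) {
  if (!file.exists(path)) stop("RTTM file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  session_id <- NA_character_
  chi <- logical(session_seconds)
  adu <- logical(session_seconds)
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] != "SPEAKER") next
    session_id <- f[2]
    sec <- as.integer(round(as.numeric(f[4]))) + 1L
    if (f[8] == "CHI") chi[sec] <- TRUE else if (f[8] == "ADU")
      adu[sec] <- TRUE
  }
  label <- ifelse(chi & adu, "BOTH",
                  ifelse(chi, "CHI", ifelse(adu, "ADU", "SIL")))
  data.frame(session_id = session_id,
             t_start_s = seq_len(session_seconds) - 1,
             t_end_s = seq_len(session_seconds), label = label,
             stringsAsFactors = FALSE)
}
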