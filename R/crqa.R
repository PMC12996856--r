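# Cross-recurrence quantification analysis (CRQA).
#
# Two scalar window series (child and adult values of one acoustic feature)
# are delay-embedded into a shared phase space; a cross-recurrence plot marks
# every pair of time points whose embedded states fall within a fixed
# Euclidean radius; and the line structures of that plot yield the synchrony
# metrics: recurrence rate, determinism, laminarity, their composite ratios,
# and the diagonal/vertical line-length summaries.

#' CRQA parameter set
#'
#' Container for the CRQA settings.  Defaults are the standard settings for
#' vocal interaction data: embedding dimension 3, delay 3 windows, fixed
#' Euclidean radius 1.5 on the robustly scaled feature scale.  Minimum line
#' lengths default to the conventional 2 (diagonal and vertical).
#'
#' @param m embedding dimension (>= 1).
#' @param tau embedding delay in windows (>= 1).
#' @param radius fixed Euclidean radius epsilon (> 0), on the scaled scale.
#' @param lmin minimum diagonal line length (>= 2).
#' @param vmin minimum vertical line length (>= 2).
#' @return a list of class \code{"crqa_params"}.
#' @export
crqa_params <- function(m = 3, tau = 3, radius = 1.5, lmin = 2, vmin = 2) {
  m <- check_count(m, "m", min = 1L)
  tau <- check_count(tau, "tau", min = 1L)
  radius <- check_positive(radius, "radius")
  lmin <- check_count(lmin, "lmin", min = 2L)
  vmin <- check_count(vmin, "vmin", min = 2L)
  structure(list(m = m, tau = tau, radius = radius, lmin = lmin, vmin = vmin),
            class = "crqa_params")
}

#' Delay embedding of a scalar series
#'
#' Reconstructs a state-space trajectory from lagged copies of a scalar
#' series: point \eqn{i} is \eqn{(x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau})}.
#'
#' @param x numeric vector.
#' @param m embedding dimension.
#' @param tau delay (in windows).
#' @return a matrix with \code{length(x) - (m-1)*tau} rows and \code{m}
#'   columns.
#' @examples
#' embed_series(1:7, m = 2, tau = 2)
#' @export
embed_series <- function(x, m, tau) {
  m <- check_count(m, "m", min = 1L)
  tau <- check_count(tau, "tau", min = 1L)
  need <- (m - 1L) * tau + 1L
  if (length(x) < need)
    stop(sprintf(
      "insufficient data for embedding: length %d < required minimum %d (m = %d, tau = %d)",
      length(x), need, m, tau), call. = FALSE)
  n <- length(x) - (m - 1L) * tau
  out <- matrix(NA_real_, n, m)
  for (k in seq_len(m)) out[, k] <- x[seq_len(n) + (k - 1L) * tau]
  out
}

#' Cross-recurrence plot of two embedded trajectories
#'
#' Binary matrix \eqn{M[i,j] = 1} iff the Euclidean distance between embedded
#' point \eqn{i} of \code{a} and point \eqn{j} of \code{b} is at most
#' \code{radius}.  The full rectangular matrix is returned; there is no
#' line-of-identity exclusion, since in cross-recurrence the two series are
#' distinct systems.
#'
#' @param a,b embedding matrices (same number of columns, i.e. same m/tau).
#' @param radius recurrence radius epsilon.
#' @return an integer 0/1 matrix with \code{nrow(a)} rows and \code{nrow(b)}
#'   columns.
#' @export
cross_recurrence <- function(a, b, radius) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  if (ncol(a) != ncol(b))
    stop("embedding dimension mismatch: ", ncol(a), " vs ", ncol(b),
         call. = FALSE)
  radius <- check_positive(radius, "radius")
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # guard tiny negatives from floating point
  matrix(as.integer(d2 <= radius^2), nrow(a), nrow(b))
}

# Run-length histogram of 1-runs along all diagonals of a binary matrix.
diag_run_lengths <- function(M) {
  d <- col(M) - row(M)
  unlist(lapply(split(M == 1L, d), function(v) {
    r <- rle(v)
    r$lengths[r$values]
  }), use.names = FALSE)
}

# Run-length histogram of 1-runs within each column (vertical lines).
vert_run_lengths <- function(M) {
  unlist(apply(M == 1L, 2, function(v) {
    r <- rle(v)
    r$lengths[r$values]
  }, simplify = FALSE), use.names = FALSE)
}

line_summary <- function(lens, minlen) {
  keep <- lens[lens >= minlen]
  if (!length(keep))
    return(list(points = 0, l_mean = NA_real_, l_max = NA_real_,
                entr = NA_real_))
  tab <- table(keep)
  p <- as.numeric(tab) / length(keep)
  list(points = sum(keep), l_mean = mean(keep), l_max = max(keep),
       entr = -sum(p * log(p)))
}

#' CRQA metrics from a cross-recurrence matrix
#'
#' Reference implementation of the metric definitions, operating on an
#' explicit binary matrix:
#' \itemize{
#'   \item \code{rec}: proportion of recurrent points,
#'     \eqn{\Sigma M / (rows \cdot cols)};
#'   \item \code{det}: proportion of recurrent points on diagonal lines of
#'     length >= \code{lmin} (sequential predictability);
#'   \item \code{lam}: proportion on vertical lines of length >= \code{vmin}
#'     (persistence in shared states);
#'   \item \code{det_rec} = det/rec, structure relative to raw recurrence
#'     (undefined iff rec = 0);
#'   \item \code{lam_det} = lam/det, stability relative to predictability
#'     (undefined iff det = 0);
#'   \item \code{l_mean} (L), \code{l_max} (Lmax): mean and longest diagonal
#'     line length; \code{tt}: trapping time, mean vertical line length;
#'   \item \code{entr}, \code{v_entr}: Shannon entropy (nats) of the diagonal
#'     resp. vertical line-length distributions.
#' }
#' An all-zero matrix yields \code{rec = 0}, everything else undefined, and
#' \code{unstable = TRUE}; \code{unstable} is also set whenever a composite
#' ratio is undefined.
#'
#' The compiled fast path used by [crqa()] implements the identical
#' definitions; their exact agreement is part of the test suite.
#'
#' @param M binary (0/1) matrix.
#' @param lmin,vmin minimum diagonal/vertical line lengths.
#' @return a list of class \code{"crqa_result"}.
#' @export
crqa_metrics <- function(M, lmin = 2, vmin = 2) {
  if (!is.matrix(M) || !length(M)) stop("M must be a non-empty matrix",
                                        call. = FALSE)
  lmin <- check_count(lmin, "lmin", min = 2L)
  vmin <- check_count(vmin, "vmin", min = 2L)
  storage.mode(M) <- "integer"
  sumM <- sum(M)
  rec <- sumM / length(M)
  if (sumM == 0) {
    res <- list(rec = 0, det = NA_real_, lam = NA_real_, det_rec = NA_real_,
                lam_det = NA_real_, l_mean = NA_real_, l_max = NA_real_,
                tt = NA_real_, entr = NA_real_, v_entr = NA_real_,
                unstable = TRUE)
    class(res) <- "crqa_result"
    return(res)
  }
  ds <- line_summary(diag_run_lengths(M), lmin)
  vs <- line_summary(vert_run_lengths(M), vmin)
  det <- ds$points / sumM
  lam <- vs$points / sumM
  det_rec <- if (rec > 0) det / rec else NA_real_
  lam_det <- if (det > 0) lam / det else NA_real_
  res <- list(rec = rec, det = det, lam = lam, det_rec = det_rec,
              lam_det = lam_det, l_mean = ds$l_mean, l_max = ds$l_max,
              tt = vs$l_mean, entr = ds$entr, v_entr = vs$entr,
              unstable = !(rec > 0) || !(det > 0))
  class(res) <- "crqa_result"
  res
}

#' @export
print.crqa_result <- function(x, digits = 3, ...) {
  v <- unlist(x[c("rec", "det", "lam", "det_rec", "lam_det", "l_mean",
                  "l_max", "tt", "entr", "v_entr")])
  print(round(v, digits))
  if (isTRUE(x$unstable)) cat("(numerically unstable: ratio(s) undefined)\n")
  invisible(x)
}

#' Cross-recurrence quantification of two scalar series
#'
#' End-to-end CRQA for one (session, feature) pair: delay-embeds both window
#' series, thresholds pairwise Euclidean distances at the fixed radius, and
#' extracts the line-structure metrics (see [crqa_metrics()] for the
#' definitions).  Runs in compiled code.
#'
#' A series with zero variance cannot be meaningfully scaled or embedded, so
#' the result is flagged \code{unstable} (composite ratios undefined), as is
#' any plot with no recurrent points or no diagonal structure.
#'
#' @param x,y numeric window series (child and adult), equal length after
#'   series construction.
#' @param params a [crqa_params()] object.
#' @return a \code{"crqa_result"} list.
#' @examples
#' set.seed(1)
#' x <- sin(seq(0, 10, by = 0.1)) + rnorm(101, 0, 0.1)
#' crqa(x, x, crqa_params(radius = 0.5))
#' @export
crqa <- function(x, y, params = crqa_params()) {
  stopifnot(inherits(params, "crqa_params"))
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    res <- list(rec = NA_real_, det = NA_real_, lam = NA_real_,
                det_rec = NA_real_, lam_det = NA_real_, l_mean = NA_real_,
                l_max = NA_real_, tt = NA_real_, entr = NA_real_,
                v_entr = NA_real_, unstable = TRUE)
    class(res) <- "crqa_result"
    return(res)
  }
  v <- .crqa_core(as.numeric(x), as.numeric(y), params$m, params$tau,
                  params$radius, params$lmin, params$vmin)
  res <- as.list(v[setdiff(names(v), "unstable")])
  res$unstable <- v[["unstable"]] > 0
  class(res) <- "crqa_result"
  res
}

#' CRQA over every feature of a dyad series
#'
#' Applies [crqa()] to each (child, adult) feature pair of a constructed
#' [build_series()] object, returning one row per feature in the layout used
#' by the modeling stage.  The recurrence matrix is oriented with the
#' caregiver on the rows and the child on the columns, so vertical lines
#' (LAM, TT) measure the caregiver remaining in the child's state; recurrence
#' rate and diagonal metrics are orientation-symmetric.
#'
#' @param series a \code{dyad_series} object (scaled; see [robust_scale()]).
#' @param params a [crqa_params()] object.
#' @return a data frame with columns \code{feature}, the ten CRQA metrics and
#'   \code{unstable}, plus the session metadata columns \code{session_id},
#'   \code{subject_id}, \code{caregiver}, \code{timepoint}, \code{psi_total}
#'   when present in the series metadata.
#' @export
crqa_session <- function(series, params = crqa_params()) {
  stopifnot(inherits(series, "dyad_series"))
  feats <- series$feature_names
  rows <- lapply(seq_along(feats), function(k) {
    r <- crqa(series$adult[, k], series$child[, k], params)
    as.data.frame(r[c("rec", "det", "lam", "det_rec", "lam_det", "l_mean",
                      "l_max", "tt", "entr", "v_entr", "unstable")])
  })
  out <- do.call(rbind, rows)
  out <- cbind(feature = feats, out, stringsAsFactors = FALSE)
  meta <- series$meta
  for (nm in c("psi_total", "timepoint", "caregiver", "subject_id",
               "session_id")) {
    if (!is.null(meta[[nm]])) out <- cbind(stats::setNames(
      data.frame(meta[[nm]], stringsAsFactors = FALSE), nm), out)
  }
  rownames(out) <- NULL
  out
}

#' Study-wide numerical-stability filter
#'
#' The modeling stage needs complete data: every retained subject must
#' contribute all four sessions (2 caregivers x 2 timepoints) and every
#' retained feature must have defined composite ratios in every one of those
#' sessions.  Subjects missing any session are dropped first; then any
#' feature that is numerically unstable in any remaining session is dropped
#' study-wide.
#'
#' @param metrics data frame of per-(session, feature) CRQA rows as returned
#'   by [crqa_session()] (stacked over sessions), with columns
#'   \code{subject_id}, \code{caregiver}, \code{timepoint}, \code{feature},
#'   \code{unstable}.
#' @return a list with \code{subjects} (retained subject ids), \code{features}
#'   (retained feature names), \code{n_subjects}, \code{n_features}, and
#'   \code{data}, the filtered metric rows.
#' @export
stability_filter <- function(metrics) {
  req <- c("subject_id", "caregiver", "timepoint", "feature", "unstable")
  missing_cols <- setdiff(req, names(metrics))
  if (length(missing_cols))
    stop("metrics table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sess <- unique(metrics[c("subject_id", "caregiver", "timepoint")])
  n_sess <- table(sess$subject_id)
  subjects <- names(n_sess)[n_sess == 4L]
  if (!length(subjects))
    stop("empty retention: no subject has all 4 sessions", call. = FALSE)
  kept <- metrics[metrics$subject_id %in% subjects, , drop = FALSE]
  bad <- kept$unstable | is.na(kept$det_rec) | is.na(kept$lam_det)
  bad_features <- unique(kept$feature[bad])
  features <- setdiff(unique(kept$feature), bad_features)
  if (!length(features))
    stop("empty retention: every feature is unstable in some session",
         call. = FALSE)
  data <- kept[kept$feature %in% features, , drop = FALSE]
  rownames(data) <- NULL
  list(subjects = subjects, features = features,
       n_subjects = length(subjects), n_features = length(features),
       data = data)
}
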