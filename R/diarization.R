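# Reliability metrics for automated speaker diarization, computed from 2x2
# confusion counts obtained by masked manual annotation of sampled segments.

#' Diarization reliability metrics from confusion counts
#'
#' Computes the standard binary-classification reliability metrics used for
#' ongoing quality control of automated child/adult speaker diarization, from
#' the four cells of a 2x2 confusion table.
#'
#' Definitions (all from the counts, full precision kept internally):
#' \itemize{
#'   \item sensitivity (recall) \eqn{= tp/(tp+fn)}
#'   \item specificity \eqn{= tn/(tn+fp)}
#'   \item precision \eqn{= tp/(tp+fp)}
#'   \item balanced accuracy \eqn{= (sensitivity + specificity)/2}
#'   \item F1 = harmonic mean of precision and sensitivity
#'   \item MCC \eqn{= (tp\,tn - fp\,fn)/\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}
#'   \item Cohen's kappa from observed vs chance agreement on the margins
#'   \item \code{roc_auc_point}: the single-operating-point trapezoidal
#'     ROC area, \eqn{(sensitivity + specificity)/2}
#'   \item \code{pr_auc_point}: single-operating-point precision-recall area,
#'     the rectangle up to the observed recall at the observed precision plus
#'     the trapezoid from there to (recall 1, precision = prevalence):
#'     \eqn{rec \cdot prec + (1-rec)(prec + prev)/2} with
#'     \eqn{prev = (tp+fn)/total}.
#' }
#'
#' A metric whose denominator is zero is reported as \code{NA} (undefined),
#' never silently as 0.
#'
#' @param tp,tn,fp,fn non-negative integer confusion counts; their total must
#'   be positive.
#' @return a list of class \code{"diarization_metrics"} with elements
#'   \code{balanced_accuracy}, \code{precision}, \code{sensitivity},
#'   \code{specificity}, \code{f1}, \code{mcc}, \code{cohen_kappa},
#'   \code{roc_auc_point}, \code{pr_auc_point} and the input \code{counts}.
#' @examples
#' confusion_metrics(tp = 71, tn = 65, fp = 2, fn = 13)
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  for (nm in c("tp", "tn", "fp", "fn")) check_count(get(nm), nm, min = 0L)
  total <- tp + tn + fp + fn
  if (total <= 0) stop_config("counts", "must sum to a positive total")

  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  bal <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  prev <- (tp + fn) / total
  pr_auc <- if (is.na(prec) || is.na(sens)) NA_real_ else
    sens * prec + (1 - sens) * (prec + prev) / 2

  structure(list(
    balanced_accuracy = bal, precision = prec, sensitivity = sens,
    specificity = spec, f1 = f1, mcc = mcc, cohen_kappa = kappa,
    roc_auc_point = bal, pr_auc_point = pr_auc,
    counts = c(tp = tp, tn = tn, fp = fp, fn = fn)
  ), class = "diarization_metrics")
}

#' @export
print.diarization_metrics <- function(x, digits = 2, ...) {
  cat("Diarization reliability (tp =", x$counts["tp"], ", tn =", x$counts["tn"],
      ", fp =", x$counts["fp"], ", fn =", x$counts["fn"], ")\n")
  vals <- unlist(x[setdiff(names(x), "counts")])
  print(round(vals, digits))
  invisible(x)
}
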