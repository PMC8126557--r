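#' Threshold classifier for pre-selecting amplifier constructors
#'
#' A graph is predicted to be an amplifier constructor when its maximal
#' remeeting time is at least the smallest `max_tau` observed among true
#' constructors AND its spectral gap is at most the largest `lambda2`
#' among true constructors.  Both comparisons are inclusive, so every true
#' constructor is predicted positive and the false-negative count is zero
#' by construction.  The classifier is descriptive: it is fit and scored on
#' the full census slice, without a train/test split.
#'
#' @param census a census data frame (from [run_census()]) for a single
#'   `(N, k)` slice, with columns `max_tau`, `lambda2`, `is_constructor`.
#' @return object of class `classifier_report`: thresholds, confusion
#'   counts (`tp`, `fp`, `tn`, `fn`), `pre` (precision, percent) and `acc`
#'   (accuracy, percent).
#' @examples
#' \dontrun{
#' fit_and_score(run_census(12, 3))
#' }
#' @export
fit_and_score <- function(census) {
  need <- c("max_tau", "lambda2", "is_constructor")
  if (!all(need %in% names(census)))
    stop("census slice must have columns max_tau, lambda2, is_constructor")
  if (nrow(census) == 0) stop("empty census slice: thresholds undefined")
  cons <- census$is_constructor
  if (!any(cons)) stop("no constructors in slice: thresholds undefined")
  tau_thr <- min(census$max_tau[cons])
  lam_thr <- max(census$lambda2[cons])
  pred <- census$max_tau >= tau_thr & census$lambda2 <= lam_thr
  tp <- sum(pred & cons)
  fp <- sum(pred & !cons)
  tn <- sum(!pred & !cons)
  fn <- sum(!pred & cons)
  structure(
    list(tau_threshold = tau_thr, lambda_threshold = lam_thr,
         tp = tp, fp = fp, tn = tn, fn = fn,
         pre = 100 * tp / (tp + fp),
         acc = 100 * (tp + tn) / nrow(census)),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Amplifier-constructor threshold classifier\n")
  cat(sprintf("  thresholds: max_tau >= %.4f and lambda2 <= %.6f\n",
              x$tau_threshold, x$lambda_threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  PRE = %.4f%%  ACC = %.4f%%\n", x$pre, x$acc))
  invisible(x)
}
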