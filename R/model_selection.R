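#' Corrected Akaike Information Criterion for a least-squares fit
#'
#' \deqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)}
#' with `n` retained data points and `k` fitted parameters (k = 4 for the
#' microstructural model, k = 1 for TID; the noise variance is not counted).
#' Undefined (returns `NA`) when `n <= k + 1`, in which case the caller falls
#' back to the simpler model.
#'
#' @param rss residual sum of squares (> 0; an exact fit yields `-Inf`)
#' @param n_points retained data points
#' @param k_params fitted parameters
#' @return the AICc score, or `NA_real_` when undefined
#' @export
aicc <- function(rss, n_points, k_params) {
  if (is.na(rss) || n_points <= k_params + 1) return(NA_real_)
  n_points * log(rss / n_points) + 2 * k_params +
    2 * k_params * (k_params + 1) / (n_points - k_params - 1)
}

#' Voxel-wise model preference by AICc
#'
#' The microstructural model is preferred iff its AICc is strictly lower than
#' the TID AICc. Ties and voxels where the MM AICc is undefined (too few
#' retained points for the small-sample correction) default to the simpler
#' TID model; voxels where neither model could be evaluated are unfittable.
#' Both fits must have been performed on the identical retained-point set,
#' otherwise the comparison is invalid and an error is raised.
#'
#' @param mm_fit,tid_fit voxel-fit lists from [fit_mm()] / [fit_tid()]
#' @param k_mm,k_tid parameter counts entering AICc
#' @return list with `label` (`"MM"`, `"TID"` or `"unfittable"`), `aicc_mm`,
#'   `aicc_tid`
#' @export
select_model <- function(mm_fit, tid_fit, k_mm = 4L, k_tid = 1L) {
  mm_ok <- !isTRUE(mm_fit$unfittable)
  tid_ok <- !isTRUE(tid_fit$unfittable)
  if (mm_ok && tid_ok && mm_fit$n_used != tid_fit$n_used)
    stop("MM and TID fits used different retained-point sets; ",
         "AICc comparison invalid")
  a_mm <- if (mm_ok) aicc(mm_fit$rss, mm_fit$n_used, k_mm) else NA_real_
  a_tid <- if (tid_ok) aicc(tid_fit$rss, tid_fit$n_used, k_tid) else NA_real_
  label <- if (is.na(a_mm) && is.na(a_tid)) {
    if (tid_ok) "TID" else "unfittable"
  } else if (is.na(a_mm)) "TID"
  else if (is.na(a_tid)) "MM"
  else if (a_mm < a_tid) "MM" else "TID"
  list(label = label, aicc_mm = a_mm, aicc_tid = a_tid)
}

#' Percentage of voxels preferring the microstructural model
#'
#' `100 * #MM / (#MM + #TID)` over a region of interest; unfittable voxels
#' are excluded from numerator and denominator. This is the %MM biomarker.
#'
#' @param preferences character vector of per-voxel labels
#'   (`"MM"`, `"TID"`, `"unfittable"`)
#' @return percentage in `[0, 100]`, or `NA_real_` if no voxel was fittable
#' @export
percent_mm <- function(preferences) {
  n_mm <- sum(preferences == "MM")
  n_tid <- sum(preferences == "TID")
  if (n_mm + n_tid == 0L) return(NA_real_)
  100 * n_mm / (n_mm + n_tid)
}

#' Confusion-matrix summary statistics for MM/TID classification
#'
#' The microstructural model is the positive class:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/total. A rate whose class is absent from the truth is
#' reported as `NA` (undefined), not 0.
#'
#' @param truth,predicted character vectors of `"MM"`/`"TID"` labels
#' @return list with `accuracy`, `sensitivity`, `specificity` and the counts
#'   `tp`, `fn`, `tn`, `fp`
#' @export
confusion_stats <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == "MM" & predicted == "MM")
  fn <- sum(truth == "MM" & predicted != "MM")
  tn <- sum(truth == "TID" & predicted == "TID")
  fp <- sum(truth == "TID" & predicted != "TID")
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fn = fn, tn = tn, fp = fp)
}
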