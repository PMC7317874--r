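#' Percentage of ADC values below a threshold
#'
#' Uses a strict inequality (`ADC < t`); voxels sitting exactly at a fit bound
#' therefore only count once the threshold passes the bound. At the top of the
#' fitted range all values satisfy `ADC <= 3`, so the curve reaches 100% at
#' (or just above) the upper bound.
#'
#' @param adc numeric vector of ADC values, um^2/ms
#' @param threshold scalar threshold, um^2/ms
#' @return percentage in `[0, 100]`
#' @export
fraction_below_threshold <- function(adc, threshold) {
  adc <- adc[!is.na(adc)]
  if (length(adc) == 0L) stop("empty ADC value set")
  100 * sum(adc < threshold) / length(adc)
}

#' Sweep ADC thresholds against an external reference fraction
#'
#' For each threshold, the percentage of voxels below it is computed per
#' dataset and correlated (Pearson) with a per-dataset reference fraction,
#' e.g. histology-derived % necrosis. The threshold attaining the largest
#' absolute correlation is reported as the cut-off (ties go to the lowest
#' threshold). Thresholds where the fraction vector is constant have an
#' undefined correlation and are skipped.
#'
#' @param adc_sets list of ADC vectors, one per dataset/subject
#' @param references numeric vector of reference fractions (%), same length
#'   and order as `adc_sets`
#' @param thresholds strictly increasing grid, um^2/ms (default 0.1-3.0 in
#'   steps of 0.01)
#' @return list of class `threshold_sweep`: `thresholds`, `fraction_below`
#'   (datasets x thresholds matrix), `correlation` (rho per threshold, `NA`
#'   where undefined), `best_threshold`, `best_rho`
#' @export
threshold_sweep <- function(adc_sets, references,
                            thresholds = seq(0.1, 3.0, by = 0.01)) {
  if (length(adc_sets) != length(references))
    stop("adc_sets and references must have the same length")
  if (length(adc_sets) < 3L)
    stop("need at least 3 paired datasets/references")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  frac <- vapply(thresholds, function(t)
    vapply(adc_sets, fraction_below_threshold, numeric(1), threshold = t),
    numeric(length(adc_sets)))
  rho <- apply(frac, 2, function(f)
    if (sd(f) == 0 || sd(references) == 0) NA_real_ else cor(f, references))
  if (all(is.na(rho))) stop("correlation undefined at every threshold")
  best <- which.max(abs(rho))  # first max -> lowest threshold on ties
  structure(list(thresholds = thresholds, fraction_below = frac,
                 correlation = rho, best_threshold = thresholds[best],
                 best_rho = rho[best]),
            class = "threshold_sweep")
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors, length >= 3, non-constant
#' @param conf confidence level (default 0.95)
#' @return list with `rho`, `ci` (length 2), `p` (two-sided), `n`
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  list(rho = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(x))
}
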