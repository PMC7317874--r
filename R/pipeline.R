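#' Fit MM and TID models to a matrix of voxel signals
#'
#' Workhorse behind [fit_dwi_volume()] and the simulation studies. Each row is
#' one voxel's raw signal across the protocol. Per voxel: the noise-floor mask
#' is computed on the raw signals, signals are normalised to the mean of the
#' G = 0 measurements, both models are fitted to the identical retained-point
#' set, and the AICc preference is recorded.
#'
#' @param signals numeric matrix, voxels x measurements
#' @param protocol a [pgse_protocol()] with at least one G = 0 measurement
#' @param config a [fit_config()]
#' @param strategy MM strategy, `"discrete_di"` (default) or `"fit_di"`
#' @param s_noise noise level for the floor; `0` disables the floor
#'   (e.g. noiseless synthetic data)
#' @param voxel_ids integer ids used to seed per-voxel start streams
#'   (default `1:nrow`)
#' @return data frame with one row per voxel: retained count, TID and MM
#'   parameters, RSS, R-squared, extreme/converged flags, AICc values and the
#'   `preference` label
#' @export
fit_signal_matrix <- function(signals, protocol, config = fit_config(),
                              strategy = c("discrete_di", "fit_di"),
                              s_noise = 0, voxel_ids = NULL) {
  strategy <- match.arg(strategy)
  signals <- as.matrix(signals)
  nv <- nrow(signals)
  if (is.null(voxel_ids)) voxel_ids <- seq_len(nv)
  i0 <- b0_indices(protocol)
  if (length(i0) == 0L) stop("protocol has no G = 0 measurement")
  out <- vector("list", nv)
  for (v in seq_len(nv)) {
    raw <- signals[v, ]
    mask <- if (s_noise > 0)
      noise_floor_mask(raw, s_noise, config$noise_floor_multiplier)
    else rep(TRUE, length(raw))
    m0 <- mean(raw[i0])
    row <- list(voxel = voxel_ids[v], n_used = sum(mask))
    if (!is.finite(m0) || m0 <= 0 || !any(mask)) {
      sel <- list(label = "unfittable", aicc_mm = NA_real_,
                  aicc_tid = NA_real_)
      mm <- .unfittable(sum(mask)); tid <- .unfittable(sum(mask))
    } else {
      y <- raw / m0
      tid <- fit_tid(y, protocol, mask, config)
      mm <- fit_mm(y, protocol, mask, config, strategy,
                   voxel_index = voxel_ids[v])
      sel <- select_model(mm, tid)
    }
    out[[v]] <- data.frame(
      voxel = row$voxel, n_used = row$n_used,
      tid_Dprime = if (isTRUE(tid$unfittable)) NA_real_ else tid$params[["Dprime"]],
      tid_rss = tid$rss, tid_r2 = tid$r2,
      tid_extreme = tid$extreme, tid_converged = tid$converged,
      mm_R = if (isTRUE(mm$unfittable)) NA_real_ else mm$params[["R"]],
      mm_Di = if (isTRUE(mm$unfittable)) NA_real_ else mm$params[["Di"]],
      mm_De = if (isTRUE(mm$unfittable)) NA_real_ else mm$params[["De"]],
      mm_fi = if (isTRUE(mm$unfittable)) NA_real_ else mm$params[["fi"]],
      mm_rss = mm$rss, mm_r2 = mm$r2,
      mm_extreme = mm$extreme, mm_converged = mm$converged,
      aicc_mm = sel$aicc_mm, aicc_tid = sel$aicc_tid,
      preference = sel$label)
  }
  do.call(rbind, out)
}

#' Voxel-wise model comparison over a DWI volume
#'
#' Runs the full pipeline on the ROI voxels of a two-diffusion-time volume:
#' noise estimation (from the background mask unless `s_noise` is given),
#' noise-floor exclusion, b = 0 normalisation, TID and MM fits on identical
#' retained points, and AICc model preference.
#'
#' @param dwi a [dwi_volume()]
#' @param config a [fit_config()]
#' @param strategy `"discrete_di"` (default) or `"fit_di"`
#' @param s_noise mean background signal; if `NULL`, estimated from the
#'   volume's background mask via [estimate_snr()]. Use `0` to disable the
#'   noise floor.
#' @return data frame as [fit_signal_matrix()], with voxel grid coordinates
#'   `i`, `j`, `k` prepended; attributes `percent_mm`, `snr`, `config`
#' @export
fit_dwi_volume <- function(dwi, config = fit_config(),
                           strategy = c("discrete_di", "fit_di"),
                           s_noise = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  strategy <- match.arg(strategy)
  snr <- NA_real_
  if (is.null(s_noise)) {
    ne <- estimate_snr(dwi)
    s_noise <- ne$s_noise
    snr <- ne$snr
  }
  idx <- which(dwi$roi_mask)
  dims <- dim(dwi$signals)
  nmeas <- dims[4]
  sig <- matrix(dwi$signals, prod(dims[1:3]), nmeas)[idx, , drop = FALSE]
  tab <- fit_signal_matrix(sig, dwi$protocol, config, strategy,
                           s_noise = s_noise, voxel_ids = idx)
  co <- arrayInd(idx, dims[1:3])
  tab <- cbind(data.frame(i = co[, 1], j = co[, 2], k = co[, 3]), tab)
  attr(tab, "percent_mm") <- percent_mm(tab$preference)
  attr(tab, "snr") <- snr
  attr(tab, "s_noise") <- s_noise
  attr(tab, "config") <- config
  tab
}

#' Assemble parameter and preference maps from a voxel fit table
#'
#' MM parameter maps (R, Di, De, fi) are populated only where MM was the
#' preferred model and the fit was not extreme; the D' map only where TID was
#' preferred; the preference map codes 0 = unfittable, 1 = TID, 2 = MM
#' (`NA` outside the ROI).
#'
#' @param fits data frame from [fit_dwi_volume()] (needs `i`, `j`, `k`)
#' @param dims 3-D grid dimensions
#' @return named list of 3-D arrays: `R`, `Di`, `De`, `fi`, `Dprime`,
#'   `preference`
#' @export
build_maps <- function(fits, dims) {
  blank <- array(NA_real_, dims)
  maps <- list(R = blank, Di = blank, De = blank, fi = blank,
               Dprime = blank, preference = blank)
  if (nrow(fits) == 0L) return(maps)
  idx <- cbind(fits$i, fits$j, fits$k)
  mm_ok <- fits$preference == "MM" & !is.na(fits$mm_extreme) & !fits$mm_extreme
  for (p in c("R", "Di", "De", "fi")) {
    m <- blank
    m[idx[mm_ok, , drop = FALSE]] <- fits[[paste0("mm_", p)]][mm_ok]
    maps[[p]] <- m
  }
  tid_ok <- fits$preference == "TID"
  m <- blank
  m[idx[tid_ok, , drop = FALSE]] <- fits$tid_Dprime[tid_ok]
  maps$Dprime <- m
  pref <- blank
  pref[idx] <- c(unfittable = 0, TID = 1, MM = 2)[fits$preference]
  maps$preference <- pref
  maps
}

#' Summarise model preference and parameters over an ROI
#'
#' @param fits data frame from [fit_dwi_volume()] / [fit_signal_matrix()]
#' @param adc optional vector of conventional ADC values over the same ROI
#' @return one-row data frame: `percent_mm`, voxel counts, and parameter
#'   medians (MM parameters over non-extreme MM-preferred voxels, D' over
#'   TID-preferred voxels, ADC over all supplied voxels)
#' @export
subregion_summary <- function(fits, adc = NULL) {
  mm_ok <- fits$preference == "MM" & !is.na(fits$mm_extreme) & !fits$mm_extreme
  data.frame(
    n_voxels = nrow(fits),
    n_mm = sum(fits$preference == "MM"),
    n_tid = sum(fits$preference == "TID"),
    n_unfittable = sum(fits$preference == "unfittable"),
    n_excluded_extreme = sum(fits$preference == "MM" & !mm_ok),
    percent_mm = percent_mm(fits$preference),
    median_R = median(fits$mm_R[mm_ok]),
    median_Di = median(fits$mm_Di[mm_ok]),
    median_De = median(fits$mm_De[mm_ok]),
    median_fi = median(fits$mm_fi[mm_ok]),
    median_Dprime = median(fits$tid_Dprime[fits$preference == "TID"]),
    median_adc = if (is.null(adc)) NA_real_ else median(adc, na.rm = TRUE))
}

#' Conventional ADC fits for a matrix of voxel signals
#'
#' @param signals matrix, voxels x measurements (raw)
#' @param protocol single-diffusion-time [pgse_protocol()]
#' @param config a [fit_config()]
#' @param s_noise optional noise level for the floor
#' @return data frame with `adc`, `rss`, `r2`, `n_used`, `extreme`
#' @export
fit_adc_matrix <- function(signals, protocol, config = fit_config(),
                           s_noise = NULL) {
  signals <- as.matrix(signals)
  out <- lapply(seq_len(nrow(signals)), function(v) {
    f <- fit_adc(signals[v, ], protocol, config, s_noise)
    data.frame(adc = if (isTRUE(f$unfittable)) NA_real_ else f$params[["adc"]],
               rss = f$rss, r2 = f$r2, n_used = f$n_used,
               extreme = if (isTRUE(f$unfittable)) NA else f$extreme)
  })
  do.call(rbind, out)
}
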