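#' Add Rician noise to a clean magnitude signal
#'
#' Each sample becomes \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with independent
#' zero-mean Gaussians of SD `1/snr`. Signals are assumed normalised so the
#' b = 0 expectation is 1, hence `snr` is the b = 0 signal-to-noise ratio.
#' Uses the current R RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param clean numeric vector or matrix of clean signals
#' @param snr b = 0 signal-to-noise ratio; `Inf` returns the input unchanged
#' @return noisy signals, same shape as `clean`
#' @export
add_rician_noise <- function(clean, snr) {
  if (!is.numeric(snr) || length(snr) != 1L || snr <= 0)
    stop("snr must be a positive scalar (possibly Inf)")
  if (is.infinite(snr)) return(clean)
  sigma <- 1 / snr
  n1 <- rnorm(length(clean), 0, sigma)
  n2 <- rnorm(length(clean), 0, sigma)
  out <- sqrt((clean + n1)^2 + n2^2)
  if (is.matrix(clean)) dim(out) <- dim(clean)
  out
}

# truncated-normal sampler via inverse-CDF (no rejection, deterministic draws)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  stats::qnorm(plo + runif(n) * (phi - plo)) * sd + mean
}

#' Default parameter pools for synthetic tumor datasets
#'
#' Microstructural-model voxels draw R from a truncated normal N(10, 1^2) um,
#' fi from N(0.41, 0.03^2) and De from N(0.6, 0.1^2) um^2/ms (typical
#' day-0 tumor medians for this protocol), and Di uniformly from the discrete
#' lookup set. TID voxels draw D' uniformly on 1.0-2.5 um^2/ms, the upper
#' diffusivity range typical of necrotic/fluid regions. All entries can be
#' overridden.
#'
#' @return nested list with `mm` (R, fi, De as `c(mean, sd)`; `di_values`)
#'   and `tid` (`dprime_range`)
#' @export
default_param_pools <- function() {
  list(mm = list(R = c(mean = 10, sd = 1),
                 fi = c(mean = 0.41, sd = 0.03),
                 De = c(mean = 0.6, sd = 0.1),
                 di_values = c(0.5, 1.0, 1.5, 2.0, 2.5)),
       tid = list(dprime_range = c(1.0, 2.5)))
}

#' Draw microstructural-model parameter sets from a pool
#' @param n number of draws
#' @param pools see [default_param_pools()]
#' @param bounds fit bounds used to truncate the normals
#' @return data frame with columns R, Di, De, fi
#' @export
sample_mm_params <- function(n, pools = default_param_pools(),
                             bounds = fit_config()$bounds) {
  p <- pools$mm
  if (length(p$di_values) == 0L) stop("empty Di pool")
  data.frame(
    R = rtruncnorm(n, p$R["mean"], p$R["sd"], bounds$R[1], bounds$R[2]),
    Di = p$di_values[sample.int(length(p$di_values), n, replace = TRUE)],
    De = rtruncnorm(n, p$De["mean"], p$De["sd"], bounds$De[1], bounds$De[2]),
    fi = rtruncnorm(n, p$fi["mean"], p$fi["sd"], bounds$fi[1], bounds$fi[2]))
}

#' The 96-microstructure simulation grid
#'
#' Cartesian product of R = 5, 10 um; Di, De = 0.2, 1.1, 2.0, 2.9 um^2/ms;
#' fi = 0.25, 0.50, 0.75 — the ground-truth grid of the fitting-accuracy
#' study.
#' @return data frame with 96 rows and columns R, Di, De, fi
#' @export
generate_microstructure_grid <- function() {
  expand.grid(R = c(5, 10), Di = c(0.2, 1.1, 2.0, 2.9),
              De = c(0.2, 1.1, 2.0, 2.9), fi = c(0.25, 0.50, 0.75),
              KEEP.OUT.ATTRS = FALSE)
}

#' Generate a synthetic tumor dataset with known %MM ground truth
#'
#' Mixes voxels whose clean signals come from the microstructural model with
#' voxels from the TID model, in exact proportion to the requested ground
#' truth (MM count = `round(n_voxels * gt / 100)`). Parameters are drawn from
#' the pools; Rician noise is added at the requested SNR.
#'
#' @param gt_percent_mm ground-truth %MM in `[0, 100]`
#' @param n_voxels voxels per dataset (default 200)
#' @param snr b = 0 SNR of the noisy signals (default 54; `Inf` = noiseless)
#' @param pools parameter pools, see [default_param_pools()]
#' @param seed RNG seed for this dataset
#' @param protocol acquisition protocol (default [two_dt_protocol()])
#' @param bounds fit bounds used to truncate pool draws
#' @return object of class `synthetic_tumor`: list with `params` (per-voxel
#'   truth: `model` plus model parameters), `clean` and `noisy` signal
#'   matrices (voxels x measurements), `gt_percent_mm`, `snr`, `seed`,
#'   `protocol`
#' @export
generate_synthetic_tumor <- function(gt_percent_mm, n_voxels = 200L,
                                     snr = 54, pools = default_param_pools(),
                                     seed = 1L,
                                     protocol = two_dt_protocol(),
                                     bounds = fit_config()$bounds) {
  stopifnot(gt_percent_mm >= 0, gt_percent_mm <= 100, n_voxels >= 1L)
  if (length(pools$tid$dprime_range) != 2L) stop("empty D' pool")
  n_mm <- as.integer(round(n_voxels * gt_percent_mm / 100))
  n_tid <- n_voxels - n_mm
  set.seed(derive_seed(seed, 1L))
  mm_par <- sample_mm_params(n_mm, pools, bounds)
  dpr <- runif(n_tid, pools$tid$dprime_range[1], pools$tid$dprime_range[2])
  params <- data.frame(model = rep(c("MM", "TID"), c(n_mm, n_tid)),
                       R = c(mm_par$R, rep(NA_real_, n_tid)),
                       Di = c(mm_par$Di, rep(NA_real_, n_tid)),
                       De = c(mm_par$De, rep(NA_real_, n_tid)),
                       fi = c(mm_par$fi, rep(NA_real_, n_tid)),
                       Dprime = c(rep(NA_real_, n_mm), dpr))
  clean <- matrix(NA_real_, n_voxels, nrow(protocol))
  for (v in seq_len(n_mm))
    clean[v, ] <- mm_signal(mm_par[v, ], protocol)
  if (n_tid > 0)
    clean[n_mm + seq_len(n_tid), ] <- t(vapply(dpr, tid_signal, numeric(nrow(protocol)),
                                               protocol = protocol))
  set.seed(derive_seed(seed, 2L))
  noisy <- add_rician_noise(clean, snr)
  structure(list(params = params, clean = clean, noisy = noisy,
                 gt_percent_mm = gt_percent_mm, snr = snr, seed = seed,
                 protocol = protocol),
            class = "synthetic_tumor")
}

#' Analyse a synthetic tumor dataset with the standard pipeline
#'
#' Runs the same noise-floor/fit/AICc pipeline used for experimental data on
#' the dataset's noisy signals, and scores the classification against the
#' known voxel labels. For noisy data the noise level entering the floor is
#' the analytic Rayleigh background mean `sqrt(pi/2)/snr`.
#'
#' @param dataset a `synthetic_tumor`
#' @param config a [fit_config()]
#' @param strategy MM fitting strategy
#' @return list with `fits` (voxel table), `percent_mm`, and `confusion`
#'   (see [confusion_stats()])
#' @export
analyze_synthetic_tumor <- function(dataset, config = fit_config(),
                                    strategy = "discrete_di") {
  s_noise <- if (is.infinite(dataset$snr)) 0 else sqrt(pi / 2) / dataset$snr
  fits <- fit_signal_matrix(dataset$noisy, dataset$protocol, config, strategy,
                            s_noise = s_noise)
  fittable <- fits$preference != "unfittable"
  list(fits = fits,
       percent_mm = percent_mm(fits$preference),
       confusion = confusion_stats(dataset$params$model[fittable],
                                   fits$preference[fittable]))
}

#' %MM technical-validation study
#'
#' For each ground-truth %MM level, generates replicate synthetic tumor
#' datasets at the given SNR, analyses each with the full pipeline and
#' summarises bias (mean estimated %MM vs truth), precision (SD and
#' coefficient of variation over datasets) and the confusion-matrix accuracy,
#' sensitivity and specificity of the underlying voxel classification.
#'
#' @param gt_levels ground-truth %MM values (default 10, 20, ..., 90)
#' @param n_datasets replicate datasets per ground truth (default 10)
#' @param n_voxels voxels per dataset (default 200)
#' @param snr b = 0 SNR (default 54; `Inf` for the noiseless arm)
#' @param config a [fit_config()]
#' @param strategy MM fitting strategy
#' @param pools parameter pools
#' @param seed global seed; dataset seeds are derived from
#'   (seed, ground truth, dataset)
#' @return object of class `percentmm_validation`: list with `datasets`
#'   (per-dataset table) and `summary` (per-ground-truth means, SDs, CoV and
#'   classification rates)
#' @export
run_percentmm_validation <- function(gt_levels = seq(10, 90, by = 10),
                                     n_datasets = 10L, n_voxels = 200L,
                                     snr = 54, config = fit_config(),
                                     strategy = "discrete_di",
                                     pools = default_param_pools(),
                                     seed = 1L) {
  rows <- list()
  for (gt in gt_levels) {
    for (d in seq_len(n_datasets)) {
      ds <- generate_synthetic_tumor(gt, n_voxels, snr, pools,
                                     seed = derive_seed(seed, gt, d))
      res <- analyze_synthetic_tumor(ds, config, strategy)
      rows[[length(rows) + 1L]] <- data.frame(
        gt_percent_mm = gt, dataset = d, snr = snr,
        percent_mm = res$percent_mm,
        accuracy = res$confusion$accuracy,
        sensitivity = res$confusion$sensitivity,
        specificity = res$confusion$specificity,
        n_unfittable = sum(res$fits$preference == "unfittable"))
    }
  }
  datasets <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(datasets, datasets$gt_percent_mm),
    function(g) data.frame(
      gt_percent_mm = g$gt_percent_mm[1],
      mean_percent_mm = mean(g$percent_mm),
      sd_percent_mm = sd(g$percent_mm),
      cov_percent = 100 * sd(g$percent_mm) / mean(g$percent_mm),
      mean_accuracy = mean(g$accuracy), sd_accuracy = sd(g$accuracy),
      mean_sensitivity = mean(g$sensitivity),
      sd_sensitivity = sd(g$sensitivity),
      mean_specificity = mean(g$specificity),
      sd_specificity = sd(g$specificity))))
  rownames(summary) <- NULL
  structure(list(datasets = datasets, summary = summary, snr = snr,
                 seed = seed, strategy = strategy),
            class = "percentmm_validation")
}

#' Fitting-accuracy simulation over the 96-microstructure grid
#'
#' For each ground-truth microstructure, generates `reps` Rician-noisy signals
#' at the given SNR and fits the microstructural model with the requested
#' strategies. Reports, per microstructure and strategy, the median absolute
#' percentage error of each parameter and the fraction of accepted fits
#' (no parameter within the extreme-fit margin of the constraints).
#'
#' @param reps noisy replicates per microstructure (default 1500)
#' @param snr b = 0 SNR (default 54)
#' @param strategies character vector among `"fit_di"`, `"discrete_di"`
#' @param config a [fit_config()]
#' @param grid ground-truth table (default [generate_microstructure_grid()])
#' @param protocol acquisition protocol
#' @param seed global seed
#' @return data frame: one row per microstructure x strategy with median
#'   absolute percentage errors `err_R`, `err_Di`, `err_De`, `err_fi` and
#'   `accepted_fraction`
#' @export
run_fitting_simulation <- function(reps = 1500L, snr = 54,
                                   strategies = c("fit_di", "discrete_di"),
                                   config = fit_config(),
                                   grid = generate_microstructure_grid(),
                                   protocol = two_dt_protocol(),
                                   seed = 1L) {
  stopifnot(reps >= 1L)
  strategies <- match.arg(strategies, c("fit_di", "discrete_di"),
                          several.ok = TRUE)
  s_noise <- if (is.infinite(snr)) 0 else sqrt(pi / 2) / snr
  i0 <- b0_indices(protocol)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    truth <- grid[g, ]
    clean <- mm_signal(truth, protocol)
    set.seed(derive_seed(seed, g))
    noisy <- add_rician_noise(matrix(clean, reps, length(clean),
                                     byrow = TRUE), snr)
    for (strat in strategies) {
      est <- matrix(NA_real_, reps, 4,
                    dimnames = list(NULL, c("R", "Di", "De", "fi")))
      acc <- logical(reps)
      for (r in seq_len(reps)) {
        raw <- noisy[r, ]
        mask <- if (s_noise > 0)
          noise_floor_mask(raw, s_noise, config$noise_floor_multiplier)
        else rep(TRUE, length(raw))
        m0 <- mean(raw[i0])
        fit <- fit_mm(raw / m0, protocol, mask, config, strat,
                      voxel_index = derive_seed(seed, g, r))
        if (!isTRUE(fit$unfittable)) {
          est[r, ] <- fit$params[c("R", "Di", "De", "fi")]
          acc[r] <- !fit$extreme
        }
      }
      err <- 100 * abs(sweep(est, 2, as.numeric(truth[c("R", "Di", "De", "fi")]),
                             "-")) /
        matrix(as.numeric(truth[c("R", "Di", "De", "fi")]), reps, 4, byrow = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        microstructure = g, strategy = strat,
        R = truth$R, Di = truth$Di, De = truth$De, fi = truth$fi,
        err_R = median(err[, "R"], na.rm = TRUE),
        err_Di = median(err[, "Di"], na.rm = TRUE),
        err_De = median(err[, "De"], na.rm = TRUE),
        err_fi = median(err[, "fi"], na.rm = TRUE),
        accepted_fraction = mean(acc))
    }
  }
  do.call(rbind, rows)
}
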