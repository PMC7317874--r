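#' Fitting configuration
#'
#' Bundles the knobs of the voxel-wise least-squares machinery: number of
#' random start points per fit, parameter bounds, the noise-floor multiplier,
#' the discrete Di lookup set, the extreme-fit margin and the RNG seed.
#'
#' @param n_starts start points per bounded simplex fit (default 100)
#' @param bounds named list of `c(lo, hi)` per parameter; defaults are the
#'   plausibility constraints 0.1 <= R <= 25 um, 0.1 <= Di, De, Dprime,
#'   adc <= 3 um^2/ms, 0.01 <= fi <= 1
#' @param noise_floor_multiplier signals below `multiplier * s_noise` are
#'   discarded before fitting (default 2)
#' @param discrete_di_values fixed Di values for the discrete-Di strategy,
#'   um^2/ms
#' @param seed global RNG seed; per-voxel start streams are derived from it
#' @param extreme_margin fraction of the parameter range (or bound value, see
#'   `extreme_mode`) defining "within 1% of the fit constraints"
#' @param extreme_mode `"range"` (margin times hi - lo, default) or `"value"`
#'   (margin times the bound's absolute value)
#' @param tol relative convergence tolerance on parameters and objective
#' @param maxeval max objective evaluations per simplex start
#' @return a list of class `fit_config`
#' @export
fit_config <- function(n_starts = 100L,
                       bounds = list(R = c(0.1, 25), Di = c(0.1, 3),
                                     De = c(0.1, 3), fi = c(0.01, 1),
                                     Dprime = c(0.1, 3), adc = c(0.1, 3)),
                       noise_floor_multiplier = 2,
                       discrete_di_values = c(0.5, 1.0, 1.5, 2.0, 2.5),
                       seed = 1L,
                       extreme_margin = 0.01,
                       extreme_mode = c("range", "value"),
                       tol = 1e-6, maxeval = 2000L) {
  stopifnot(n_starts >= 1L)
  for (nm in names(bounds))
    if (bounds[[nm]][1] >= bounds[[nm]][2])
      stop("bounds for ", nm, " must satisfy lo < hi")
  di_b <- bounds$Di
  if (any(discrete_di_values < di_b[1] | discrete_di_values > di_b[2]))
    stop("discrete Di values must lie within the Di bounds")
  structure(list(n_starts = as.integer(n_starts), bounds = bounds,
                 noise_floor_multiplier = noise_floor_multiplier,
                 discrete_di_values = discrete_di_values,
                 seed = as.integer(seed), extreme_margin = extreme_margin,
                 extreme_mode = match.arg(extreme_mode),
                 tol = tol, maxeval = as.integer(maxeval)),
            class = "fit_config")
}

# deterministic sub-seed derivation; stays below 2^31 - 1
derive_seed <- function(seed, ...) {
  x <- as.double(seed %% 2147483647L)
  for (k in c(...)) x <- (x * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(x)
}

#' Noise-floor retention mask
#'
#' Magnitude signals at or below the Rician noise floor are biased upward; to
#' mitigate this, measurements with raw signal below
#' `multiplier * s_noise` are discarded from every model fitted to that voxel.
#'
#' @param signals raw (unnormalised) signal vector for one voxel
#' @param s_noise mean background signal (> 0)
#' @param multiplier noise-floor multiplier (default 2)
#' @return logical retention mask, `TRUE` = keep
#' @export
noise_floor_mask <- function(signals, s_noise, multiplier = 2) {
  if (!is.numeric(s_noise) || length(s_noise) != 1L || s_noise <= 0)
    stop("s_noise must be a positive scalar")
  signals >= multiplier * s_noise
}

#' Is a parameter set within the extreme-fit margin of its constraints?
#'
#' A fit is flagged extreme when at least one parameter lies within 1% (by
#' default) of the fit constraints; such fits are excluded from parameter
#' distributions (but still count towards model preference).
#'
#' @param params named numeric vector of fitted parameters
#' @param bounds named list of `c(lo, hi)` covering `names(params)`
#' @param margin fraction (default 0.01)
#' @param mode `"range"`: within `margin * (hi - lo)` of either bound;
#'   `"value"`: within `margin * |bound|` of either bound
#' @return logical scalar
#' @export
is_extreme <- function(params, bounds, margin = 0.01, mode = "range") {
  for (nm in names(params)) {
    bb <- bounds[[nm]]
    if (is.null(bb)) next
    tolv <- if (mode == "range") margin * (bb[2] - bb[1]) else margin * abs(bb)
    tolv <- rep_len(tolv, 2)
    if (params[[nm]] - bb[1] <= tolv[1] || bb[2] - params[[nm]] <= tolv[2])
      return(TRUE)
  }
  FALSE
}

.unfittable <- function(n_used) {
  list(params = NULL, rss = NA_real_, r2 = NA_real_, n_used = n_used,
       extreme = NA, converged = NA, unfittable = TRUE)
}

.r2 <- function(rss, y) {
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(NA_real_)
  1 - rss / tss
}

# start points drawn per voxel; row s uses draws (s-1)*npar+1 .. s*npar of the
# stream, so the first k rows are identical for any n_starts >= k (best-of-
# starts is then monotone in n_starts by construction)
.start_matrix <- function(config, voxel_index, block, npar, lo, hi) {
  set.seed(derive_seed(config$seed, voxel_index, block))
  u <- matrix(runif(config$n_starts * npar), ncol = npar, byrow = TRUE)
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

#' Fit the time-independent diffusion model to one voxel
#'
#' Single diffusivity D' estimated by bounded least squares over the retained
#' measurements of both diffusion times, initialised from the log-linear
#' closed form and refined by a bounded simplex search.
#'
#' @param y normalised signal vector (1 expected at b = 0)
#' @param protocol a [pgse_protocol()]
#' @param mask logical retention mask from [noise_floor_mask()] (default all)
#' @param config a [fit_config()]
#' @return a voxel-fit list: `params` (named), `rss`, `r2`, `n_used`,
#'   `extreme`, `converged`, `unfittable`
#' @export
fit_tid <- function(y, protocol, mask = rep(TRUE, length(y)),
                    config = fit_config()) {
  keep <- which(mask)
  if (length(keep) < 2L) return(.unfittable(length(keep)))
  bb <- config$bounds$Dprime
  bk <- protocol$b[keep] * 1e-3
  yk <- y[keep]
  pos <- yk > 0 & bk > 0
  d0 <- if (any(pos)) sum(bk[pos] * (-log(yk[pos]))) / sum(bk[pos]^2) else mean(bb)
  d0 <- min(max(d0, bb[1] * 1.001), bb[2] * 0.999)
  pc <- .proto_cpp(protocol)
  fit <- cpp_fit_voxel(y, as.integer(keep - 1L), 0L, 0,
                       matrix(d0, 1, 1), bb[1], bb[2],
                       pc$G, pc$b, pc$tid, pc$udelta, pc$uDelta,
                       sphere_gpd_roots(), config$tol, config$maxeval)
  params <- c(Dprime = fit$par[1])
  list(params = params, rss = fit$rss, r2 = .r2(fit$rss, yk),
       n_used = length(keep),
       extreme = is_extreme(params, config$bounds, config$extreme_margin,
                            config$extreme_mode),
       converged = fit$converged, unfittable = FALSE)
}

#' Fit the two-compartment microstructural model to one voxel
#'
#' Bounded multi-start simplex minimisation of the sum of squared residuals
#' over the retained measurements. Two strategies:
#' \describe{
#'   \item{`fit_di`}{all four parameters (R, Di, De, fi) free;
#'     best of `n_starts` random starts.}
#'   \item{`discrete_di`}{Di fixed in turn to each value of the lookup set
#'     (default 0.5, 1.0, 1.5, 2.0, 2.5 um^2/ms) with (R, De, fi) free; the
#'     fixed-Di fit with the highest R-squared wins (ties to the lower Di).
#'     Fixing Di trades Di resolution for fit stability.}
#' }
#'
#' @param y normalised signal vector
#' @param protocol a [pgse_protocol()]
#' @param mask logical retention mask
#' @param config a [fit_config()]
#' @param strategy `"discrete_di"` (default) or `"fit_di"`
#' @param voxel_index integer identifying the voxel; start points are drawn
#'   from a stream seeded by (global seed, voxel index) so that batches are
#'   reproducible and order-independent
#' @return a voxel-fit list as in [fit_tid()]; `params` has entries R, Di,
#'   De, fi
#' @export
fit_mm <- function(y, protocol, mask = rep(TRUE, length(y)),
                   config = fit_config(),
                   strategy = c("discrete_di", "fit_di"),
                   voxel_index = 0L) {
  strategy <- match.arg(strategy)
  keep <- which(mask)
  min_pts <- if (strategy == "fit_di") 5L else 4L
  if (length(keep) < min_pts) return(.unfittable(length(keep)))
  yk <- y[keep]
  pc <- .proto_cpp(protocol)
  roots <- sphere_gpd_roots()
  bnd <- config$bounds
  if (strategy == "fit_di") {
    lo <- c(bnd$R[1], bnd$Di[1], bnd$De[1], bnd$fi[1])
    hi <- c(bnd$R[2], bnd$Di[2], bnd$De[2], bnd$fi[2])
    starts <- .start_matrix(config, voxel_index, 0L, 4L, lo, hi)
    fit <- cpp_fit_voxel(y, as.integer(keep - 1L), 1L, 0, starts, lo, hi,
                         pc$G, pc$b, pc$tid, pc$udelta, pc$uDelta, roots,
                         config$tol, config$maxeval)
    params <- c(R = fit$par[1], Di = fit$par[2], De = fit$par[3],
                fi = fit$par[4])
    rss <- fit$rss; converged <- fit$converged
  } else {
    lo <- c(bnd$R[1], bnd$De[1], bnd$fi[1])
    hi <- c(bnd$R[2], bnd$De[2], bnd$fi[2])
    best <- NULL
    for (di in config$discrete_di_values) {
      # stream keyed by the Di value so a sub-fit is reproducible regardless
      # of which other lookup values are present
      starts <- .start_matrix(config, voxel_index, round(1000 * di), 3L, lo, hi)
      fit <- cpp_fit_voxel(y, as.integer(keep - 1L), 2L, di, starts, lo, hi,
                           pc$G, pc$b, pc$tid, pc$udelta, pc$uDelta, roots,
                           config$tol, config$maxeval)
      # highest R^2 over fixed-Di fits == lowest RSS (same data); strict
      # inequality keeps the lower Di on ties
      if (is.null(best) || fit$rss < best$rss) best <- c(fit, list(di = di))
    }
    params <- c(R = best$par[1], Di = best$di, De = best$par[2],
                fi = best$par[3])
    rss <- best$rss; converged <- best$converged
  }
  free <- if (strategy == "discrete_di") params[c("R", "De", "fi")] else params
  list(params = params, rss = rss, r2 = .r2(rss, yk), n_used = length(keep),
       extreme = is_extreme(free, config$bounds, config$extreme_margin,
                            config$extreme_mode),
       converged = converged, unfittable = FALSE)
}

#' Fit the conventional ADC model to one voxel
#'
#' Signals are normalised to the b = 150 s/mm^2 measurement of a
#' single-diffusion-time protocol and fitted to
#' \eqn{S/S_{b150} = e^{-(b-150)ADC}} by bounded least squares.
#'
#' @param y_raw raw signal vector (unnormalised)
#' @param protocol single-diffusion-time [pgse_protocol()]
#' @param config a [fit_config()]
#' @param s_noise optional noise level; if given, measurements below
#'   `noise_floor_multiplier * s_noise` are discarded. The b = 150 reference
#'   itself must survive the floor, otherwise the voxel is unfittable.
#' @return a voxel-fit list; `params` has entry `adc`
#' @export
fit_adc <- function(y_raw, protocol, config = fit_config(), s_noise = NULL) {
  ref <- adc_reference_index(protocol)
  mask <- if (is.null(s_noise)) rep(TRUE, length(y_raw))
          else noise_floor_mask(y_raw, s_noise, config$noise_floor_multiplier)
  if (!mask[ref]) return(.unfittable(sum(mask)))
  keep <- which(mask)
  if (length(keep) < 2L) return(.unfittable(length(keep)))
  y <- y_raw / y_raw[ref]
  bb <- config$bounds$adc
  db <- (protocol$b[keep] - protocol$b[ref]) * 1e-3
  yk <- y[keep]
  pos <- yk > 0 & db > 0
  a0 <- if (any(pos)) sum(db[pos] * (-log(yk[pos]))) / sum(db[pos]^2) else mean(bb)
  a0 <- min(max(a0, bb[1] * 1.001), bb[2] * 0.999)
  # same bounded-simplex machinery as TID, on the b-offset axis
  shifted <- protocol
  shifted$b <- protocol$b - protocol$b[ref]
  pc <- .proto_cpp(shifted)
  fit <- cpp_fit_voxel(y, as.integer(keep - 1L), 0L, 0, matrix(a0, 1, 1),
                       bb[1], bb[2], pc$G, pc$b, pc$tid, pc$udelta, pc$uDelta,
                       sphere_gpd_roots(), config$tol, config$maxeval)
  params <- c(adc = fit$par[1])
  list(params = params, rss = fit$rss, r2 = .r2(fit$rss, yk),
       n_used = length(keep),
       extreme = is_extreme(params, list(adc = bb), config$extreme_margin,
                            config$extreme_mode),
       converged = fit$converged, unfittable = FALSE)
}
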