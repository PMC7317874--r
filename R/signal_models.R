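.mmtid_env <- new.env(parent = emptyenv())

#' Roots of the sphere GPD boundary condition
#'
#' Returns the first `count` positive roots of \eqn{j_1'(x) = 0}, where
#' \eqn{j_1} is the first-order spherical Bessel function, i.e. solutions of
#' \eqn{(x^2 - 2)\sin x + 2x\cos x = 0}. These are the eigenvalue roots of the
#' Gaussian-phase-distribution series for diffusion restricted in an
#' impermeable sphere (first root 2.08158, spacing approaching pi).
#'
#' @param count number of roots (>= 1)
#' @return strictly increasing numeric vector of length `count`
#' @export
sphere_gpd_roots <- function(count = 30L) {
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  cached <- .mmtid_env$roots
  if (!is.null(cached) && length(cached) >= count) return(cached[seq_len(count)])
  g <- function(x) (x^2 - 2) * sin(x) + 2 * x * cos(x)
  hi <- (count + 2) * pi
  xs <- seq(1.0, hi, by = 0.02)
  sg <- sign(g(xs))
  idx <- which(diff(sg) != 0)
  roots <- vapply(idx, function(i)
    uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-14)$root, numeric(1))
  roots <- roots[roots > 1]
  if (length(roots) < count) stop("root bracketing failed")
  .mmtid_env$roots <- roots
  roots[seq_len(count)]
}

# protocol pieces in the layout the C++ kernels expect (0-based timing ids,
# unique (delta_eff, Delta) pairs)
.proto_cpp <- function(protocol) {
  de <- protocol$delta - protocol$rise
  key <- paste(de, protocol$Delta)
  ukey <- unique(key)
  list(G = protocol$G, b = protocol$b,
       tid = as.integer(match(key, ukey) - 1L),
       udelta = de[match(ukey, key)],
       uDelta = protocol$Delta[match(ukey, key)])
}

#' Echo attenuation for diffusion restricted in an impermeable sphere
#'
#' Gaussian-phase-distribution (Murday-Cotts) series for PGSE. Two waveform
#' handlings are available: `"rectangular"` (default) replaces each trapezoid
#' by a rectangle of effective width `delta - rise`, evaluated from the
#' closed-form series; `"trapezoid"` evaluates the GPD double time-integral of
#' the actual trapezoidal waveform numerically. The two differ by < 0.5%
#' attenuation at a 0.245 ms rise time; the closed form is used in fitting.
#'
#' @param R sphere radius, um
#' @param Di intrasphere diffusivity, um^2/ms
#' @param protocol a [pgse_protocol()] (one attenuation per measurement)
#' @param waveform `"rectangular"` or `"trapezoid"`
#' @param n_roots series length (terms additionally cut once their relative
#'   contribution is below 1e-12)
#' @return attenuation vector in (0, 1]; exactly 1 where G = 0
#' @export
restricted_sphere_attenuation <- function(R, Di, protocol,
                                          waveform = c("rectangular", "trapezoid"),
                                          n_roots = 30L) {
  waveform <- match.arg(waveform)
  stopifnot(R > 0, Di > 0)
  roots <- sphere_gpd_roots(n_roots)
  if (waveform == "rectangular") {
    return(cpp_sphere_attn(R, Di, protocol$G, protocol$delta - protocol$rise,
                           protocol$Delta, roots))
  }
  vapply(seq_len(nrow(protocol)), function(j)
    .trapezoid_gpd_attn(R, Di, protocol$G[j], protocol$delta[j],
                        protocol$Delta[j], protocol$rise[j], roots),
    numeric(1))
}

# GPD attenuation for the true trapezoidal waveform, by direct numerical
# evaluation of ln E = -2 gamma^2 sum_m C_m \int\int g(t) g(t') e^{-lam(t-t')}.
# The inner exponential integral is accumulated recursively on a uniform grid.
.trapezoid_gpd_attn <- function(R, Di, G, delta, Delta, rise, roots,
                                n_steps = 20000L) {
  if (G == 0) return(1)
  R_si <- R * 1e-6; D_si <- Di * 1e-9; G_si <- G * 1e-3
  Ttot <- (Delta + delta) * 1e-3
  dt <- Ttot / n_steps
  t <- (seq_len(n_steps) - 0.5) * dt
  eps <- rise * 1e-3; d <- delta * 1e-3; D <- Delta * 1e-3
  shape <- function(tt) {   # unit-amplitude trapezoid on [0, d]
    ifelse(tt < 0 | tt > d, 0,
           pmin(tt / eps, 1, (d - tt) / eps))
  }
  g <- G_si * (shape(t) - shape(t - D))
  lnE <- 0
  for (mu in roots) {
    lam <- mu^2 * D_si / R_si^2
    C <- R_si^2 / (mu^2 * (mu^2 - 2))
    ex <- exp(-lam * dt)
    q <- 0; J <- 0
    for (i in seq_len(n_steps)) {
      q <- q * ex + g[i] * dt
      J <- J + g[i] * (q - 0.5 * g[i] * dt) * dt
    }
    term <- 2 * GAMMA_1H^2 * C * J
    lnE <- lnE - term
    if (abs(term) < 1e-12 * abs(lnE)) break
  }
  exp(lnE)
}

#' Two-compartment microstructural model (MM) signal
#'
#' Normalised PGSE signal of a voxel containing water restricted in
#' impermeable spheres (fraction `fi`, radius `R`, diffusivity `Di`) plus
#' hindered extracellular water (monoexponential in b with diffusivity `De`):
#' \deqn{S = f_i A_{sphere}(R, D_i) + (1 - f_i) e^{-b D_e}}
#'
#' @param params named list or vector with `R` (um), `Di`, `De` (um^2/ms),
#'   `fi` (signal fraction in (0, 1])
#' @param protocol a [pgse_protocol()]
#' @param waveform passed to [restricted_sphere_attenuation()]
#' @return normalised signal vector (1 at G = 0)
#' @export
mm_signal <- function(params, protocol, waveform = "rectangular") {
  p <- as.list(params)
  attn <- restricted_sphere_attenuation(p$R, p$Di, protocol, waveform = waveform)
  p$fi * attn + (1 - p$fi) * exp(-protocol$b * 1e-3 * p$De)
}

#' Time-independent diffusion (TID) model signal
#'
#' Monoexponential decay with b-value only, \eqn{S = e^{-b D'}}, fitted across
#' all diffusion times; appropriate only where diffusion is time-independent.
#'
#' @param Dprime single diffusivity D', um^2/ms
#' @param protocol a [pgse_protocol()]
#' @return normalised signal vector
#' @export
tid_signal <- function(Dprime, protocol) {
  exp(-protocol$b * 1e-3 * Dprime)
}

#' Conventional ADC model signal (normalised to b = 150 s/mm^2)
#'
#' \eqn{S/S_{b150} = e^{-(b - 150)\,ADC \cdot 10^{-3}}}. The normalisation to
#' the b = 150 s/mm^2 measurement (rather than b = 0) minimises the potential
#' influence of capillary blood flow.
#'
#' @param adc apparent diffusion coefficient, um^2/ms
#' @param protocol a single-diffusion-time [pgse_protocol()] containing a
#'   measurement with nominal b of 150 s/mm^2
#' @return signal vector normalised to the b = 150 measurement
#' @export
adc_signal <- function(adc, protocol) {
  ref <- adc_reference_index(protocol)
  exp(-(protocol$b - protocol$b[ref]) * 1e-3 * adc)
}

# index of the b ~ 150 s/mm^2 reference measurement
adc_reference_index <- function(protocol, nominal = 150, tol = 25) {
  if (length(unique(protocol$Delta)) != 1L)
    stop("ADC model requires a single-diffusion-time protocol")
  d <- abs(protocol$b - nominal)
  if (min(d) > tol)
    stop("protocol has no measurement with b near ", nominal, " s/mm^2")
  which.min(d)
}
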