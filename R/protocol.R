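#' @useDynLib mmtid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optimize quantile rnorm runif sd setNames uniroot cor
#' @importFrom utils write.csv read.csv
NULL

#' Gyromagnetic ratio of the proton
#'
#' 2.6752219e8 rad s^-1 T^-1, used throughout for b-value and
#' Gaussian-phase-distribution computations.
#' @export
GAMMA_1H <- 2.6752219e8

#' Compute the b-value of a trapezoidal PGSE measurement
#'
#' The quoted pulse duration `delta` is the total trapezoid duration including
#' both ramps. The b-value is computed with the rectangular-equivalent width
#' `delta_eff = delta - rise` plus the standard trapezoid correction terms:
#' \deqn{b = \gamma^2 G^2 [\delta_e^2(\Delta - \delta_e/3) + \epsilon^3/30 -
#'       \delta_e \epsilon^2/6]}
#' This convention reproduces nominal preclinical protocol b-values of
#' 150/500/1000 s/mm^2 (delta 4.65 ms, Delta 9.86 ms, rise 0.245 ms,
#' G up to 293 mT/m) to well under 0.5%.
#'
#' @param G gradient amplitude, mT/m (vectorised)
#' @param delta total gradient pulse duration including both ramps, ms
#' @param Delta gradient pulse separation (leading edge to leading edge), ms
#' @param rise ramp time, ms
#' @return b-value(s) in s/mm^2
#' @examples
#' compute_b_value(293, 4.65, 9.86, 0.245)  # ~1000 s/mm^2
#' @export
compute_b_value <- function(G, delta, Delta, rise) {
  if (any(G < 0)) stop("gradient amplitude G must be >= 0")
  if (any(rise <= 0) || any(rise >= delta))
    stop("non-physical timing: require 0 < rise < delta")
  if (any(delta > Delta))
    stop("non-physical timing: require delta <= Delta")
  de  <- (delta - rise) * 1e-3   # s
  eps <- rise * 1e-3
  Dl  <- Delta * 1e-3
  Gsi <- G * 1e-3                # T/m
  b <- GAMMA_1H^2 * Gsi^2 * (de^2 * (Dl - de / 3) + eps^3 / 30 - de * eps^2 / 6)
  b * 1e-6                       # s/m^2 -> s/mm^2
}

#' Construct a PGSE acquisition protocol
#'
#' A protocol is an ordered table of PGSE measurements sharing pulse duration
#' and rise time (gradient amplitude and separation may vary), with derived
#' b-values. Stored as a data frame of class `pgse_protocol` with columns
#' `G`, `delta`, `Delta`, `rise`, `TE`, `TR`, `b`.
#'
#' @param G gradient amplitudes, mT/m (one per measurement)
#' @param delta total pulse duration incl. ramps, ms (scalar or per measurement;
#'   must be constant across the protocol)
#' @param Delta gradient separations, ms (scalar or per measurement)
#' @param rise ramp time, ms (must be constant across the protocol)
#' @param TE,TR echo/repetition time, ms (optional bookkeeping)
#' @param label free-text protocol label
#' @param require_b0 if `TRUE` (default), at least one G = 0 measurement must be
#'   present (needed for b = 0 normalisation). Single-diffusion-time ADC
#'   protocols normalised to the b = 150 s/mm^2 measurement may set this to
#'   `FALSE`.
#' @return a `pgse_protocol` data frame
#' @export
pgse_protocol <- function(G, delta, Delta, rise, TE = NA_real_, TR = NA_real_,
                          label = "", require_b0 = TRUE) {
  n <- length(G)
  if (n < 1L) stop("protocol must contain at least one measurement")
  p <- data.frame(G = as.numeric(G),
                  delta = rep_len(as.numeric(delta), n),
                  Delta = rep_len(as.numeric(Delta), n),
                  rise = rep_len(as.numeric(rise), n),
                  TE = rep_len(as.numeric(TE), n),
                  TR = rep_len(as.numeric(TR), n))
  if (length(unique(p$delta)) != 1L || length(unique(p$rise)) != 1L)
    stop("all measurements in a protocol must share delta and rise")
  if (require_b0 && !any(p$G == 0))
    stop("protocol has no G = 0 measurement; b = 0 normalisation impossible ",
         "(set require_b0 = FALSE for protocols normalised to b = 150)")
  p$b <- compute_b_value(p$G, p$delta, p$Delta, p$rise)
  attr(p, "label") <- label
  class(p) <- c("pgse_protocol", "data.frame")
  p
}

#' @export
print.pgse_protocol <- function(x, ...) {
  cat(sprintf("PGSE protocol '%s': %d measurements, %d diffusion time(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$Delta))))
  print.data.frame(cbind(as.data.frame(x)[c("G", "delta", "Delta", "rise")],
                         b = round(x$b, 1)), row.names = FALSE)
  invisible(x)
}

#' Built-in two-diffusion-time protocol
#'
#' Eight PGSE measurements: G = 0, 113, 207, 293 mT/m at each of
#' Delta = 9.86 and 40.0 ms, with delta = 4.65 ms and rise time 0.245 ms
#' (nominal b = 0, 150, 500, 1000 and 0, 689, 2296, 4592 s/mm^2),
#' TE = 50.1 ms, TR = 2550 ms. This is the acquisition used for
#' microstructural-model/TID comparison.
#' @return a `pgse_protocol`
#' @export
two_dt_protocol <- function() {
  pgse_protocol(G = rep(c(0, 113, 207, 293), 2),
                delta = 4.65,
                Delta = rep(c(9.86, 40.0), each = 4),
                rise = 0.245, TE = 50.1, TR = 2550,
                label = "two diffusion time")
}

#' Built-in single-diffusion-time protocol
#'
#' Three PGSE measurements at Delta = 9.86 ms with G = 113, 207, 293 mT/m
#' (nominal b = 150, 500, 1000 s/mm^2), TE = 20.4 ms, TR = 2550 ms. Used for
#' conventional ADC mapping with signals normalised to the b = 150 s/mm^2
#' measurement to minimise the influence of capillary blood flow.
#' @return a `pgse_protocol`
#' @export
single_dt_protocol <- function() {
  pgse_protocol(G = c(113, 207, 293), delta = 4.65, Delta = 9.86,
                rise = 0.245, TE = 20.4, TR = 2550,
                label = "single diffusion time", require_b0 = FALSE)
}

#' Read a protocol from a JSON sidecar
#'
#' The sidecar is a JSON object with fields `label` (optional) and
#' `measurements`, an array of records each with `G`, `delta`, `Delta`, `rise`
#' and optionally `TE`, `TR`. b-values are always recomputed from the waveform
#' parameters, never read from the file.
#'
#' @param path JSON file path
#' @param require_b0 passed to [pgse_protocol()]
#' @return a `pgse_protocol`
#' @export
read_protocol <- function(path, require_b0 = TRUE) {
  if (!file.exists(path)) stop("protocol sidecar not found: ", path)
  j <- jsonlite::fromJSON(path)
  m <- j$measurements
  if (is.null(m) || NROW(m) == 0L) stop("protocol sidecar has no measurements")
  for (f in c("G", "delta", "Delta", "rise"))
    if (is.null(m[[f]])) stop("protocol sidecar missing field '", f, "'")
  pgse_protocol(G = m$G, delta = m$delta, Delta = m$Delta, rise = m$rise,
                TE = if (is.null(m$TE)) NA_real_ else m$TE,
                TR = if (is.null(m$TR)) NA_real_ else m$TR,
                label = if (is.null(j$label)) "" else j$label,
                require_b0 = require_b0)
}

#' Write a protocol to a JSON sidecar
#'
#' @param protocol a `pgse_protocol`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "pgse_protocol"))
  j <- list(label = attr(protocol, "label"),
            measurements = as.data.frame(protocol)[c("G", "delta", "Delta",
                                                     "rise", "TE", "TR")])
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Export FSL-style .bval / .bvec files
#'
#' Writes the computed b-values as one whitespace-separated row. The model is
#' isotropic so the companion .bvec is all zeros; it is written only for
#' interoperability with tools that expect the pair.
#'
#' @param protocol a `pgse_protocol`
#' @param path output path for the .bval file; the .bvec is written alongside
#'   with extension swapped
#' @return `path`, invisibly
#' @export
write_bval <- function(protocol, path) {
  stopifnot(inherits(protocol, "pgse_protocol"))
  writeLines(paste(formatC(protocol$b, format = "f", digits = 3),
                   collapse = " "), path)
  bvec <- sub("\\.bval$", ".bvec", path)
  if (identical(bvec, path)) bvec <- paste0(path, ".bvec")
  writeLines(rep(paste(rep("0", nrow(protocol)), collapse = " "), 3), bvec)
  invisible(path)
}

#' Indices of b = 0 (G = 0) measurements in a protocol
#' @param protocol a `pgse_protocol`
#' @return integer vector
#' @export
b0_indices <- function(protocol) which(protocol$G == 0)
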