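#' Bind a 4-D signal array to a protocol and masks
#'
#' @param signals 4-D numeric array (x, y, z, measurement), arbitrary units
#' @param protocol a [pgse_protocol()] whose length matches `dim(signals)[4]`
#' @param roi_mask 3-D logical array selecting tissue voxels to analyse
#' @param background_mask optional 3-D logical array of signal-free background
#'   voxels used for noise estimation
#' @return an object of class `dwi_volume`
#' @export
dwi_volume <- function(signals, protocol, roi_mask, background_mask = NULL) {
  signals <- as.array(signals)
  if (length(dim(signals)) != 4L)
    stop("signals must be a 4-D array (x, y, z, measurement)")
  stopifnot(inherits(protocol, "pgse_protocol"))
  if (dim(signals)[4] != nrow(protocol))
    stop("4th dimension (", dim(signals)[4], ") does not match protocol length (",
         nrow(protocol), ")")
  sp <- dim(signals)[1:3]
  roi_mask <- array(as.logical(roi_mask), dim = dim(roi_mask))
  if (!identical(dim(roi_mask), sp))
    stop("roi_mask grid does not match signal grid")
  if (!is.null(background_mask)) {
    background_mask <- array(as.logical(background_mask), dim = dim(background_mask))
    if (!identical(dim(background_mask), sp))
      stop("background_mask grid does not match signal grid")
  }
  structure(list(signals = signals, protocol = protocol, roi_mask = roi_mask,
                 background_mask = background_mask),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("dwi_volume: %dx%dx%d voxels x %d measurements; ROI %d voxels%s\n",
              d[1], d[2], d[3], d[4], sum(x$roi_mask),
              if (is.null(x$background_mask)) ""
              else sprintf("; background %d voxels", sum(x$background_mask))))
  invisible(x)
}

#' Read a 4-D DWI NIfTI with protocol sidecar and masks
#'
#' @param dwi_path 4-D NIfTI (.nii/.nii.gz)
#' @param protocol_path JSON protocol sidecar (see [read_protocol()])
#' @param roi_path 3-D NIfTI mask (nonzero = in ROI)
#' @param background_path optional 3-D NIfTI noise-background mask
#' @param require_b0 passed to [read_protocol()]
#' @return a `dwi_volume`
#' @export
read_dwi_volume <- function(dwi_path, protocol_path, roi_path,
                            background_path = NULL, require_b0 = TRUE) {
  for (p in c(dwi_path, protocol_path, roi_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  sig <- as.array(RNifti::readNifti(dwi_path))
  protocol <- read_protocol(protocol_path, require_b0 = require_b0)
  sp <- dim(sig)[1:3]
  # NIfTI readers may drop trailing singleton dimensions from 3-D masks
  as_mask <- function(path) {
    m <- as.array(RNifti::readNifti(path)) != 0
    if (length(m) != prod(sp))
      stop("mask ", path, " does not match the signal grid")
    array(m, sp)
  }
  roi <- as_mask(roi_path)
  bg <- NULL
  if (!is.null(background_path)) {
    if (!file.exists(background_path))
      stop("input file not found: ", background_path)
    bg <- as_mask(background_path)
  }
  dwi_volume(sig, protocol, roi, bg)
}

#' Write a named list of 3-D maps as NIfTI files
#'
#' @param maps named list of 3-D arrays
#' @param dir output directory (created if needed)
#' @param reference optional NIfTI image or path supplying header geometry
#' @return named character vector of written paths
#' @export
write_maps <- function(maps, dir, reference = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- vapply(names(maps), function(nm) {
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- maps[[nm]]
    if (!is.null(reference)) img <- RNifti::asNifti(img, reference = reference)
    RNifti::writeNifti(img, path)
    path
  }, character(1))
  out
}

#' Estimate Rician noise level and SNR from a background region
#'
#' In a signal-free background of a magnitude image, intensities follow a
#' Rayleigh distribution with mean \eqn{\sigma\sqrt{\pi/2}}. The Rician noise
#' SD is therefore recovered as `mean(background) / sqrt(pi/2)`, and SNR is
#' the ROI-mean b = 0 signal divided by that SD.
#'
#' @param dwi a [dwi_volume()] with a nonempty background mask
#' @return list with `s_noise` (mean background signal), `sigma_rician`
#'   (noise SD) and `snr`
#' @export
estimate_snr <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (is.null(dwi$background_mask) || !any(dwi$background_mask))
    stop("background mask is empty; supply sigma_rician explicitly instead")
  i0 <- b0_indices(dwi$protocol)
  if (length(i0) == 0L) stop("protocol has no G = 0 measurement")
  bg <- apply(dwi$signals, 1:3, mean)[dwi$background_mask]
  s_noise <- mean(bg)
  if (s_noise <= 0)
    stop("background signal is not positive; cannot derive a noise level")
  sigma <- s_noise / sqrt(pi / 2)
  b0 <- dwi$signals[, , , i0, drop = FALSE]
  b0_mean <- mean(apply(b0, 1:3, mean)[dwi$roi_mask])
  list(s_noise = s_noise, sigma_rician = sigma, snr = b0_mean / sigma)
}
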