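#' @import methods
NULL

#' Acquisition metadata for a 2D phase-offset MRE dataset
#'
#' Describes one single-slice gradient-echo MRE acquisition: vibration
#' frequency, number of phase offsets sampled over the vibration cycle,
#' isotropic in-plane pixel spacing, actuator position (vertical, \code{"VAP"},
#' i.e. wave propagation along the principal muscle-fibre direction, or
#' horizontal, \code{"HAP"}, orthogonal to it), body side and subject label.
#' \code{encodingScaleRadPerUm} is the motion-encoding efficiency of the
#' sequence (phase radians per micron of tissue displacement); it is not
#' reported by scanners in a standard way and is a free metadata parameter.
#'
#' The default pixel spacing, 1.40625 mm, corresponds to an 18 cm field of
#' view on a 128 x 128 matrix.
#'
#' @slot frequencyHz vibration frequency in Hz (> 0).
#' @slot nOffsets number of phase offsets (>= 3).
#' @slot pixelSpacingMM isotropic in-plane pixel spacing in mm (> 0).
#' @slot actuatorPosition \code{"VAP"} or \code{"HAP"}.
#' @slot side \code{"left"} or \code{"right"}.
#' @slot subjectId subject identifier.
#' @slot encodingScaleRadPerUm phase radians encoded per micron of
#'   displacement.
#'
#' @export
setClass("AcquisitionMeta",
  representation(
    frequencyHz = "numeric",
    nOffsets = "integer",
    pixelSpacingMM = "numeric",
    actuatorPosition = "character",
    side = "character",
    subjectId = "character",
    encodingScaleRadPerUm = "numeric"
  )
)

setValidity("AcquisitionMeta", function(object) {
  msg <- character(0)
  if (length(object@frequencyHz) != 1L || !is.finite(object@frequencyHz) ||
      object@frequencyHz <= 0)
    msg <- c(msg, "frequencyHz must be a single positive number")
  if (length(object@nOffsets) != 1L || is.na(object@nOffsets) ||
      object@nOffsets < 3L)
    msg <- c(msg, "nOffsets must be >= 3")
  if (length(object@pixelSpacingMM) != 1L ||
      !is.finite(object@pixelSpacingMM) || object@pixelSpacingMM <= 0)
    msg <- c(msg, "pixelSpacingMM must be a single positive number")
  if (!object@actuatorPosition %in% c("VAP", "HAP"))
    msg <- c(msg, "actuatorPosition must be 'VAP' or 'HAP'")
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(object@encodingScaleRadPerUm) != 1L ||
      !is.finite(object@encodingScaleRadPerUm) ||
      object@encodingScaleRadPerUm <= 0)
    msg <- c(msg, "encodingScaleRadPerUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct acquisition metadata
#'
#' @param frequencyHz vibration frequency (Hz).
#' @param nOffsets number of phase offsets acquired over one vibration cycle.
#' @param pixelSpacingMM isotropic in-plane pixel spacing (mm); the default
#'   is an 18 cm FOV on a 128 matrix.
#' @param actuatorPosition \code{"VAP"} or \code{"HAP"}.
#' @param side \code{"left"} or \code{"right"}.
#' @param subjectId subject identifier string.
#' @param encodingScaleRadPerUm motion-encoding efficiency (rad/um).
#' @return An \code{AcquisitionMeta} object.
#' @examples
#' acquisitionMeta(60)
#' @export
acquisitionMeta <- function(frequencyHz, nOffsets = 4L,
                            pixelSpacingMM = 180 / 128,
                            actuatorPosition = "VAP", side = "left",
                            subjectId = "S01",
                            encodingScaleRadPerUm = 0.05) {
  new("AcquisitionMeta", frequencyHz = as.numeric(frequencyHz),
      nOffsets = as.integer(nOffsets),
      pixelSpacingMM = as.numeric(pixelSpacingMM),
      actuatorPosition = actuatorPosition, side = side,
      subjectId = subjectId,
      encodingScaleRadPerUm = as.numeric(encodingScaleRadPerUm))
}

#' A single-slice phase-offset MRE dataset
#'
#' Pairs one magnitude image with the stack of phase images acquired at
#' evenly spaced phase offsets within the vibration cycle, plus acquisition
#' metadata. The phase stack is stored H x W x nOffsets (offset along the
#' third dimension, matching NIfTI volume order); phase is in radians.
#'
#' @slot magnitude 2D real matrix (arbitrary units).
#' @slot phaseStack 3D array, H x W x nOffsets, radians.
#' @slot meta an \code{\link{AcquisitionMeta}}.
#' @export
setClass("MREDataset",
  representation(magnitude = "matrix", phaseStack = "array",
                 meta = "AcquisitionMeta")
)

setValidity("MREDataset", function(object) {
  msg <- character(0)
  d <- dim(object@phaseStack)
  if (length(d) != 3L)
    msg <- c(msg, "phaseStack must be a 3D array (H x W x nOffsets)")
  else {
    if (!identical(dim(object@magnitude), d[1:2]))
      msg <- c(msg, "magnitude and phase slices must share their 2D shape")
    if (d[3L] != object@meta@nOffsets)
      msg <- c(msg, "third dimension of phaseStack must equal meta nOffsets")
  }
  if (!all(is.finite(object@phaseStack)))
    msg <- c(msg, "phase values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an MREDataset
#'
#' @param magnitude 2D numeric matrix.
#' @param phaseStack 3D numeric array, H x W x nOffsets, radians.
#' @param meta an \code{\link{AcquisitionMeta}}.
#' @return An \code{MREDataset}.
#' @export
mreDataset <- function(magnitude, phaseStack, meta) {
  new("MREDataset", magnitude = magnitude, phaseStack = phaseStack,
      meta = meta)
}

#' A labelled binary region of interest aligned to the image grid
#'
#' @slot mask logical matrix, same shape as the images it annotates.
#' @slot label region label, e.g. \code{"UT"} or \code{"background"}.
#' @export
setClass("ROIMask",
  representation(mask = "matrix", label = "character"))

setValidity("ROIMask", function(object) {
  msg <- character(0)
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  else if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one TRUE pixel")
  if (length(msg)) msg else TRUE
})

#' Construct an ROIMask
#' @param mask logical matrix.
#' @param label region label.
#' @return An \code{ROIMask}.
#' @export
roiMask <- function(mask, label = "ROI") {
  new("ROIMask", mask = mask, label = label)
}

#' Complex first-harmonic wave image
#'
#' The complex amplitude of the fundamental temporal frequency of the phase
#' stack at each pixel ("wave image"). Real-valued animation frames are
#' synthesized from it with \code{\link{synthesizeFrames}}.
#'
#' @slot harmonic 2D complex matrix (radians).
#' @slot meta the source dataset's \code{\link{AcquisitionMeta}}.
#' @export
setClass("WaveField",
  representation(harmonic = "matrix", meta = "AcquisitionMeta"))

setValidity("WaveField", function(object) {
  if (!is.complex(object@harmonic))
    return("harmonic must be a complex matrix")
  if (!all(is.finite(Re(object@harmonic)) & is.finite(Im(object@harmonic))))
    return("harmonic values must be finite")
  TRUE
})

#' Eight synthesized wave-animation frames
#'
#' Frame k (k = 0..7) is Re(H * exp(-i 2*pi*k/8)); the frames sum to zero and
#' the per-pixel maximum over frames approximates |H| to within cos(pi/8).
#'
#' @slot frames 3D array H x W x 8 (radians).
#' @slot meta the source \code{\link{AcquisitionMeta}}.
#' @export
setClass("WaveFrames",
  representation(frames = "array", meta = "AcquisitionMeta"))

setValidity("WaveFrames", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L || d[3L] != 8L)
    return("frames must be an H x W x 8 array")
  TRUE
})

#' A 1D caliper profile line in pixel coordinates
#'
#' Continuous 1-based (row, col) endpoints; physical position along the line
#' is measured in mm using the image pixel spacing.
#'
#' @slot start numeric(2), (row, col) of the first endpoint.
#' @slot end numeric(2), (row, col) of the second endpoint.
#' @slot samplingStepMM distance between interpolation stations (mm).
#' @export
setClass("ProfileLine",
  representation(start = "numeric", end = "numeric",
                 samplingStepMM = "numeric"))

setValidity("ProfileLine", function(object) {
  msg <- character(0)
  if (length(object@start) != 2L || length(object@end) != 2L)
    msg <- c(msg, "start and end must be (row, col) pairs")
  if (object@samplingStepMM <= 0)
    msg <- c(msg, "samplingStepMM must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ProfileLine
#' @param start numeric(2) (row, col) endpoint, 1-based pixel coordinates.
#' @param end numeric(2) (row, col) endpoint.
#' @param samplingStepMM interpolation step along the line (mm).
#' @return A \code{ProfileLine}.
#' @export
profileLine <- function(start, end, samplingStepMM) {
  new("ProfileLine", start = as.numeric(start), end = as.numeric(end),
      samplingStepMM = as.numeric(samplingStepMM))
}

#' Interpolated amplitude samples along a caliper line
#'
#' @slot distancesMM strictly increasing, equally spaced sample positions.
#' @slot values wave amplitude at the samples (radians).
#' @export
setClass("ProfileTrace",
  representation(distancesMM = "numeric", values = "numeric"))

setValidity("ProfileTrace", function(object) {
  msg <- character(0)
  if (length(object@distancesMM) != length(object@values))
    msg <- c(msg, "distancesMM and values must have equal length")
  if (length(object@distancesMM) >= 2L) {
    d <- diff(object@distancesMM)
    if (any(d <= 0)) msg <- c(msg, "distances must be strictly increasing")
    if (max(abs(d - d[1L])) > 1e-9 * max(d))
      msg <- c(msg, "distances must be equally spaced")
  }
  if (length(msg)) msg else TRUE
})

#' Per-frame caliper wavelengths and quality scores
#'
#' @slot perFrameLambdaMM wavelength per frame (mm), \code{NA} where absent.
#' @slot perFrameQuality integer quality score 1-5 per frame.
#' @slot extremaPositions list of per-frame extremum positions (mm) along
#'   the profile (peaks then troughs).
#' @export
setClass("WavelengthMeasurement",
  representation(perFrameLambdaMM = "numeric", perFrameQuality = "integer",
                 extremaPositions = "list"))

setValidity("WavelengthMeasurement", function(object) {
  q <- object@perFrameQuality
  if (any(!is.na(q) & (q < 1L | q > 5L)))
    return("quality scores must lie in 1..5")
  TRUE
})

#' Quality-gated stiffness estimate
#'
#' Shear stiffness from the plane-wave relation mu = rho*(lambda*f)^2, with
#' lambda the mean caliper wavelength over the frames whose wave-quality
#' score was at least 3.
#'
#' @slot lambdaMeanM quality-gated mean wavelength (metres).
#' @slot fHz vibration frequency (Hz).
#' @slot rhoKgM3 assumed tissue density (kg/m^3).
#' @slot muPa shear stiffness (Pa).
#' @slot framesUsed indices (1-based) of the frames retained by the gate.
#' @slot measurement the underlying \code{\link{WavelengthMeasurement}}.
#' @slot datasetScore dataset-level wave-quality score (max over frames).
#' @export
setClass("StiffnessResult",
  representation(lambdaMeanM = "numeric", fHz = "numeric",
                 rhoKgM3 = "numeric", muPa = "numeric",
                 framesUsed = "integer",
                 measurement = "WavelengthMeasurement",
                 datasetScore = "integer"))

setValidity("StiffnessResult", function(object) {
  expected <- object@rhoKgM3 * (object@lambdaMeanM * object@fHz)^2
  if (abs(object@muPa - expected) > 1e-6 * max(1, expected))
    return("muPa must equal rho*(lambdaMean*f)^2")
  q <- object@measurement@perFrameQuality[object@framesUsed]
  if (any(is.na(q)) || any(q < 3L))
    return("all frames used must have quality >= 3")
  TRUE
})

#' Rician-corrected magnitude SNR
#'
#' SNR = 0.655 * S_ROI / sigma_bg, where S_ROI is the mean magnitude in the
#' tissue ROI, sigma_bg the sample SD of the magnitude in a signal-free
#' background ROI, and 0.655 corrects for the background magnitude being
#' Rician (Rayleigh) rather than Gaussian distributed.
#'
#' @slot sRoi mean magnitude in the tissue ROI.
#' @slot sigmaBg sample SD of magnitude in the background ROI.
#' @slot snr the corrected signal-to-noise ratio.
#' @export
setClass("SNRResult",
  representation(sRoi = "numeric", sigmaBg = "numeric", snr = "numeric"))

setValidity("SNRResult", function(object) {
  msg <- character(0)
  if (object@sigmaBg <= 0) msg <- c(msg, "sigmaBg must be positive")
  if (object@snr < 0) msg <- c(msg, "snr must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Inter-observer agreement report for one study cell
#'
#' @slot kappa Cohen's kappa for the two observers' quality scores (NA when
#'   undefined, e.g. both observers constant and identical).
#' @slot kappaBand qualitative band for kappa.
#' @slot icc two-way mixed single-rater consistency ICC for stiffness.
#' @slot bias mean inter-observer stiffness difference (kPa).
#' @slot sdDiff sample SD of the differences (kPa).
#' @slot loa limits of agreement, 1.96 * sdDiff (kPa).
#' @slot ub,lb bias +/- loa (kPa).
#' @slot biasCI 95\% confidence interval for the bias (t quantile).
#' @slot cvPercent mean per-pair coefficient of variation (\%).
#' @export
setClass("AgreementReport",
  representation(kappa = "numeric", kappaBand = "character", icc = "numeric",
                 bias = "numeric", sdDiff = "numeric", loa = "numeric",
                 ub = "numeric", lb = "numeric", biasCI = "numeric",
                 cvPercent = "numeric"))

setValidity("AgreementReport", function(object) {
  if (length(object@loa) == 1L && is.finite(object@loa) && object@loa < 0)
    return("loa must be non-negative")
  if (all(is.finite(c(object@lb, object@bias, object@ub))) &&
      !(object@lb <= object@bias && object@bias <= object@ub))
    return("lb <= bias <= ub must hold")
  TRUE
})

#' Friedman factorial analysis result
#'
#' @slot chi2 Friedman chi-squared statistic (tie-corrected mid-ranks).
#' @slot df degrees of freedom, k - 1 for k conditions.
#' @slot p upper-tail chi-squared p-value.
#' @slot pairwise data.frame of pairwise Wilcoxon comparisons with
#'   Bonferroni-adjusted p-values (may have zero rows).
#' @export
setClass("FactorialResult",
  representation(chi2 = "numeric", df = "integer", p = "numeric",
                 pairwise = "data.frame"))

setValidity("FactorialResult", function(object) {
  if (object@df < 1L) return("df must be >= 1")
  if (nrow(object@pairwise) &&
      any(object@pairwise$pAdj <= 0 | object@pairwise$pAdj > 1))
    return("adjusted p-values must lie in (0, 1]")
  TRUE
})
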