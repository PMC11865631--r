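# The measurement core: 1D profile extraction, electronic-caliper
# wavelength, automated 5-point wave-quality rubric, quality-gated
# stiffness via mu = rho*(lambda*f)^2, and Rician-corrected SNR.

# SD of the magnitude of zero-mean complex Gaussian noise, as a fraction of
# the per-channel sigma: sqrt(2 - pi/2) ~= 0.655. Used as the background
# correction in the SNR formula.
.ricianFactor <- 0.655

#' Default thresholds for the automated wave-quality rubric
#'
#' \code{coherenceMin}: minimum ratio of mean |H| in the ROI to the
#' estimated noise floor for the waves to count as coherent (score > 1).
#' \code{circVarMax}: maximum circular variance of the local phase-gradient
#' directions for the waves to count as planar (score > 2).
#'
#' @return A named list.
#' @export
defaultQualityThresholds <- function() list(coherenceMin = 3, circVarMax = 0.3)

#' Extract a 1D interpolated profile along a caliper line
#'
#' Samples the image by bilinear interpolation at equally spaced stations
#' along the line; distances are in mm using the pixel spacing.
#'
#' @param img 2D numeric matrix (a wave frame, or the real or imaginary
#'   part of a harmonic).
#' @param line a \code{\link{profileLine}} in 1-based pixel coordinates.
#' @param pixelSpacingMM isotropic pixel spacing (mm).
#' @return A \code{\link{ProfileTrace}}.
#' @export
extractProfile <- function(img, line, pixelSpacingMM) {
  stopifnot(is.matrix(img), is(line, "ProfileLine"))
  .assertScalarPositive(pixelSpacingMM, "pixelSpacingMM")
  lenMM <- sqrt(sum((line@end - line@start)^2)) * pixelSpacingMM
  if (lenMM <= 0) stop("profile line has zero length")
  tt <- seq(0, lenMM, by = line@samplingStepMM)
  if (length(tt) < 2L) stop("profile line is shorter than one sampling step")
  fr <- tt / lenMM
  r <- line@start[1L] + fr * (line@end[1L] - line@start[1L])
  c <- line@start[2L] + fr * (line@end[2L] - line@start[2L])
  eps <- 1e-9
  if (any(r < 1 - eps | r > nrow(img) + eps | c < 1 - eps |
            c > ncol(img) + eps))
    stop("profile line exits the image")
  vals <- .bilinear(img, pmin(pmax(r, 1), nrow(img)),
                    pmin(pmax(c, 1), ncol(img)))
  if (any(!is.finite(vals))) stop("profile contains non-finite values")
  new("ProfileTrace", distancesMM = tt, values = vals)
}

#' Measure wavelength from a profile trace by the caliper rule
#'
#' Detects local maxima and minima whose topographic prominence is at least
#' \code{minProminenceFrac} times the trace range (with parabolic sub-sample
#' refinement of their positions) and returns the mean of the consecutive
#' peak-to-peak and trough-to-trough spacings, i.e. full wavelengths, as in
#' reading an electronic caliper between like extrema. If fewer than two
#' peaks and fewer than two troughs survive, the measurement is absent.
#'
#' @param trace a \code{\link{ProfileTrace}}.
#' @param minProminenceFrac prominence threshold as a fraction of the trace
#'   range (default 0.1).
#' @return A list with \code{lambdaMM} (numeric or \code{NA}),
#'   \code{reason} (\code{NA} or a string when absent), \code{peaksMM} and
#'   \code{troughsMM} (refined extremum positions).
#' @export
measureWavelength <- function(trace, minProminenceFrac = 0.1) {
  stopifnot(is(trace, "ProfileTrace"))
  v <- trace@values
  if (length(v) == 0L || any(!is.finite(v)))
    stop("trace is empty or contains non-finite values")
  rng <- diff(range(v))
  prom <- minProminenceFrac * rng
  peaks <- .refinedPeaks(v, trace@distancesMM, prom)
  troughs <- .refinedPeaks(-v, trace@distancesMM, prom)
  spac <- c(if (length(peaks) >= 2L) diff(peaks),
            if (length(troughs) >= 2L) diff(troughs))
  if (length(spac) == 0L)
    return(list(lambdaMM = NA_real_, reason = "insufficient extrema",
                peaksMM = peaks, troughsMM = troughs))
  list(lambdaMM = mean(spac), reason = NA_character_,
       peaksMM = peaks, troughsMM = troughs)
}

# Estimate the per-pixel complex noise SD of a harmonic from a signal-free
# background region: |H| there is Rayleigh, so sigma = sqrt(mean(|H|^2)/2).
.harmonicNoiseSigma <- function(H, bgMask) {
  sqrt(mean(Mod(H[bgMask])^2) / 2)
}

# Expected mean |H| under noise alone, predicted from the magnitude images:
# in tissue the per-offset phase noise is sigma_c / S (complex noise SD over
# signal level), the per-channel harmonic noise is sigma_p * sqrt(2/N), and
# the mean Rayleigh magnitude is that times sqrt(pi/2). The background
# magnitude SD is Rayleigh, so sigma_c = sd(bg) / 0.655. This is the right
# floor for phase-derived wave images: the *air* phase is uniform random
# (its harmonic is large), so the background harmonic itself must not be
# used as the tissue noise floor.
.predictedNoiseFloor <- function(magnitudeImg, roiMask, bgMask, nOffsets) {
  sigmaC <- stats::sd(magnitudeImg[bgMask]) / .ricianFactor
  s <- mean(magnitudeImg[roiMask])
  if (!is.finite(sigmaC) || sigmaC <= 0 || s <= 0) return(0)
  sigmaP <- sigmaC / s
  sigmaP * sqrt(2 / nOffsets) * sqrt(pi / 2)
}

# Line through the ROI centroid along `direction`, clipped to the ROI's
# extent along that direction. Returns list(line, extentMM).
.centroidLine <- function(roiMask, direction, spacingMM, stepFrac = 0.25) {
  idx <- which(roiMask, arr.ind = TRUE)
  ctr <- colMeans(idx)                     # (row, col)
  dx <- direction[1L]; dy <- direction[2L] # x = col, y = row
  t <- ((idx[, 2L] - ctr[2L]) * dx + (idx[, 1L] - ctr[1L]) * dy) * spacingMM
  tmin <- min(t); tmax <- max(t)
  start <- c(ctr[1L] + dy * tmin / spacingMM, ctr[2L] + dx * tmin / spacingMM)
  end <- c(ctr[1L] + dy * tmax / spacingMM, ctr[2L] + dx * tmax / spacingMM)
  list(line = profileLine(start, end, spacingMM * stepFrac),
       extentMM = tmax - tmin)
}

#' Extent of an ROI along a direction
#'
#' Range of the ROI pixel centres projected onto a unit direction, in mm.
#' This is the length the wave-quality rubric counts wavelengths over.
#'
#' @param roi an \code{\link{ROIMask}}.
#' @param direction length-2 (dx, dy) unit vector (x = columns, y = rows).
#' @param pixelSpacingMM pixel spacing (mm).
#' @return Extent in mm.
#' @export
roiExtentAlongMM <- function(roi, direction, pixelSpacingMM) {
  stopifnot(is(roi, "ROIMask"))
  idx <- which(roi@mask, arr.ind = TRUE)
  t <- (idx[, 2L] * direction[1L] + idx[, 1L] * direction[2L]) *
    pixelSpacingMM
  diff(range(t))
}

# Number of wavelengths across the ROI along `direction`: range of the
# unwrapped harmonic phase along the centroid line, divided by 2*pi.
.wavelengthCount <- function(H, roiMask, direction, spacingMM) {
  cl <- .centroidLine(roiMask, direction, spacingMM)
  line <- cl$line
  n1 <- nrow(H); n2 <- ncol(H)
  clamp <- function(p) c(min(max(p[1L], 1), n1), min(max(p[2L], 1), n2))
  line <- profileLine(clamp(line@start), clamp(line@end),
                      line@samplingStepMM)
  re <- extractProfile(Re(H), line, spacingMM)
  im <- extractProfile(Im(H), line, spacingMM)
  h <- complex(real = re@values, imaginary = im@values)
  inc <- Arg(h[-1L] * Conj(h[-length(h)]))
  cum <- cumsum(c(0, inc))
  diff(range(cum)) / (2 * pi)
}

#' Automated 5-point wave-quality score
#'
#' Automates the visual rubric: score 1 when no coherent waves are present
#' (mean |H| in the ROI below \code{coherenceMin} times the noise floor);
#' score 2 when waves are coherent but not planar (circular variance of the
#' |H|^2-weighted local phase-gradient directions above \code{circVarMax},
#' or no dominant propagation direction); otherwise the number of
#' wavelengths W across the ROI along the propagation direction (range of
#' unwrapped phase / 2*pi) maps to 3 (W < 1), 4 (1 <= W < 2) or
#' 5 (W >= 2).
#'
#' @param field a \code{\link{WaveField}}.
#' @param roi the muscle \code{\link{ROIMask}}.
#' @param direction optional (dx, dy) propagation direction; estimated from
#'   the field when \code{NULL}.
#' @param background optional signal-free \code{\link{ROIMask}}; together
#'   with \code{magnitudeImg} it is used to predict the tissue noise floor
#'   from the magnitude SNR. Without magnitude information the floor falls
#'   back to the background harmonic (only meaningful when the background
#'   phase noise is representative of the ROI), or to zero when neither is
#'   given.
#' @param magnitudeImg optional magnitude image matching the field.
#' @param noiseFloor optional explicit noise floor (expected mean |H| under
#'   noise alone); overrides the estimates.
#' @param thresholds see \code{\link{defaultQualityThresholds}}.
#' @return Integer score in 1..5.
#' @export
scoreWaveQuality <- function(field, roi, direction = NULL, background = NULL,
                             magnitudeImg = NULL, noiseFloor = NULL,
                             thresholds = defaultQualityThresholds()) {
  stopifnot(is(field, "WaveField"), is(roi, "ROIMask"))
  H <- field@harmonic
  m <- roi@mask
  if (!identical(dim(m), dim(H)))
    stop("ROI shape does not match the wave field")
  if (!any(m)) stop("ROI is empty")
  sp <- field@meta@pixelSpacingMM
  bgMask <- if (!is.null(background)) background@mask else !m
  s <- mean(Mod(H[m]))
  est <- if (!is.null(noiseFloor)) noiseFloor
    else if (!is.null(magnitudeImg) && !is.null(background))
      .predictedNoiseFloor(magnitudeImg, m, bgMask, field@meta@nOffsets)
    else if (!is.null(background))
      .harmonicNoiseSigma(H, bgMask) * sqrt(pi / 2)
    else 0
  floorVal <- max(est, 1e-12 * max(s, 1e-300))
  coherence <- s / floorVal
  if (!is.finite(coherence) || coherence < thresholds$coherenceMin)
    return(1L)
  if (is.null(direction)) {
    direction <- tryCatch(estimatePropagationDirection(field, roi),
                          error = function(e) NULL)
    if (is.null(direction)) return(2L)
  }
  g <- .phaseGradient(H, sp)
  valid <- m
  valid[nrow(m), ] <- FALSE
  valid[, ncol(m)] <- FALSE
  w <- Mod(H)^2 * valid
  gm <- sqrt(g$gx^2 + g$gy^2)
  ok <- w > 0 & gm > 0
  if (!any(ok)) return(2L)
  z <- complex(real = g$gx[ok], imaginary = g$gy[ok]) / gm[ok]
  rbar <- Mod(sum(w[ok] * z)) / sum(w[ok])
  if (1 - rbar > thresholds$circVarMax) return(2L)
  W <- .wavelengthCount(H, m, direction, sp)
  if (W < 1) 3L else if (W < 2) 4L else 5L
}

#' Shear stiffness from wavelength
#'
#' The plane-wave shear-stiffness relation mu = rho*(lambda*f)^2, with
#' lambda in metres, f in Hz and rho in kg/m^3 (1000 for muscle).
#'
#' @param lambdaM wavelength in metres.
#' @param fHz vibration frequency (Hz).
#' @param rhoKgM3 tissue density (kg/m^3).
#' @return Shear stiffness in Pa.
#' @examples
#' computeStiffness(0.02, 100)  # 4000 Pa
#' @export
computeStiffness <- function(lambdaM, fHz, rhoKgM3 = 1000) {
  .assertScalarPositive(lambdaM, "lambdaM")
  .assertScalarPositive(fHz, "fHz")
  .assertScalarPositive(rhoKgM3, "rhoKgM3")
  rhoKgM3 * (lambdaM * fHz)^2
}

#' Rician-corrected magnitude SNR
#'
#' SNR = 0.655 * mean(magnitude in tissue ROI) / sd(magnitude in background
#' ROI), where the factor 0.655 corrects for the Rician (Rayleigh)
#' distribution of background magnitude; the sample (n-1) SD is used.
#'
#' @param magnitudeImg 2D magnitude matrix.
#' @param roiM tissue \code{\link{ROIMask}}.
#' @param roiBg signal-free background \code{\link{ROIMask}} (>= 30 pixels,
#'   disjoint from \code{roiM}).
#' @return An \code{\link{SNRResult}}.
#' @export
computeSNR <- function(magnitudeImg, roiM, roiBg) {
  stopifnot(is.matrix(magnitudeImg), is(roiM, "ROIMask"), is(roiBg, "ROIMask"))
  if (any(roiM@mask & roiBg@mask)) stop("tissue and background ROIs overlap")
  if (sum(roiBg@mask) < 30L)
    stop("background ROI must contain at least 30 pixels")
  sRoi <- mean(magnitudeImg[roiM@mask])
  sigmaBg <- stats::sd(magnitudeImg[roiBg@mask])
  if (!is.finite(sigmaBg) || sigmaBg <= 0)
    stop("background ROI has zero magnitude variance")
  new("SNRResult", sRoi = sRoi, sigmaBg = sigmaBg,
      snr = .ricianFactor * sRoi / sigmaBg)
}

#' Simulated observer for the caliper procedure
#'
#' A surrogate for a human observer: the automated caliper geometry is
#' perturbed by Gaussian jitter of the profile-line endpoints and of the
#' detected extremum positions (both in mm). Zero jitter reproduces the
#' automated measurement exactly.
#'
#' @param endpointJitterMM SD of the 2D perturbation of each profile
#'   endpoint (mm).
#' @param extremumJitterMM SD of the perturbation of each extremum position
#'   along the profile (mm).
#' @return A list of class \code{"ObserverModel"}.
#' @export
observerModel <- function(endpointJitterMM = 2, extremumJitterMM = 0.5) {
  if (endpointJitterMM < 0 || extremumJitterMM < 0)
    stop("jitter SDs must be >= 0")
  structure(list(endpointJitterMM = endpointJitterMM,
                 extremumJitterMM = extremumJitterMM),
            class = "ObserverModel")
}

# Caliper wavelength from jittered extremum positions: mean of consecutive
# like-extremum spacings, peaks and troughs pooled.
.lambdaFromExtrema <- function(peaks, troughs) {
  spac <- c(if (length(peaks) >= 2L) diff(peaks),
            if (length(troughs) >= 2L) diff(troughs))
  if (length(spac) == 0L) NA_real_ else mean(spac)
}

#' Quality-gated stiffness estimate for one dataset
#'
#' The full caliper pipeline: temporal first harmonic, spatial bandpass,
#' optional directional filter, 8-frame synthesis, per-frame caliper
#' wavelength and wave-quality score along a profile through the ROI
#' centroid in the propagation direction, quality gating (frames scoring
#' below 3 are discarded), and stiffness mu = rho*(lambda_mean*f)^2.
#'
#' @param dataset an \code{\link{MREDataset}}.
#' @param roi the muscle \code{\link{ROIMask}}.
#' @param background optional background \code{\link{ROIMask}} for the
#'   noise-floor estimate.
#' @param line optional \code{\link{ProfileLine}}; when \code{NULL} the
#'   profile runs through the ROI centroid along the estimated propagation
#'   direction, clipped to the ROI extent.
#' @param bandMM length-2 bandpass wavelengths (mm); default
#'   \code{c(4 * pixelSpacing, 2 * ROI extent)}.
#' @param useDirectionalFilter apply \code{\link{directionalFilter}} along
#'   the estimated direction (off by default, matching the main analysis).
#' @param minProminenceFrac caliper prominence threshold.
#' @param rhoKgM3 assumed tissue density.
#' @param observer optional \code{\link{observerModel}}; uses the current
#'   RNG stream for its jitters.
#' @param thresholds rubric thresholds, see
#'   \code{\link{defaultQualityThresholds}}.
#' @return A \code{\link{StiffnessResult}}.
#' @export
estimateStiffness <- function(dataset, roi, background = NULL, line = NULL,
                              bandMM = NULL, useDirectionalFilter = FALSE,
                              minProminenceFrac = 0.1, rhoKgM3 = 1000,
                              observer = NULL,
                              thresholds = defaultQualityThresholds()) {
  stopifnot(is(dataset, "MREDataset"), is(roi, "ROIMask"))
  sp <- dataset@meta@pixelSpacingMM
  field <- extractFirstHarmonic(dataset)
  # air pixels carry uniform random phase whose harmonic is large; left in,
  # the spatial filter rings it into the tissue edge. Mask the harmonic to
  # tissue (magnitude support) before filtering, as wave-image processors do.
  tissue <- dataset@magnitude > 0.3 * mean(dataset@magnitude[roi@mask])
  field@harmonic[!(tissue | roi@mask)] <- 0 + 0i
  # provisional extent from the ROI bounding box for the default band
  idx <- which(roi@mask, arr.ind = TRUE)
  extent0 <- max(diff(range(idx[, 1L])), diff(range(idx[, 2L]))) * sp
  if (is.null(bandMM)) bandMM <- c(4 * sp, 2 * extent0)
  field <- smoothBandpass(field, bandMM[1L], bandMM[2L])

  if (is.null(line)) {
    direction <- estimatePropagationDirection(field, roi)
  } else {
    dvec <- (line@end - line@start)   # (row, col) delta
    direction <- c(dvec[2L], dvec[1L]) / sqrt(sum(dvec^2))
  }
  if (useDirectionalFilter)
    field <- directionalFilter(field, direction)

  # rubric components shared across frames; noise floor predicted from the
  # magnitude SNR (air phase is uniform noise, so the background harmonic
  # itself would grossly overestimate the tissue phase-noise floor)
  H <- field@harmonic
  m <- roi@mask
  bgMask <- if (!is.null(background)) background@mask else !m
  est <- if (!is.null(background))
    .predictedNoiseFloor(dataset@magnitude, m, bgMask,
                         dataset@meta@nOffsets)
  else 0
  s <- mean(Mod(H[m]))
  floorVal <- max(est, 1e-12 * max(s, 1e-300))
  coherent <- is.finite(s / floorVal) && s / floorVal >= thresholds$coherenceMin
  g <- .phaseGradient(H, sp)
  valid <- m; valid[nrow(m), ] <- FALSE; valid[, ncol(m)] <- FALSE
  w <- Mod(H)^2 * valid
  gm <- sqrt(g$gx^2 + g$gy^2)
  ok <- w > 0 & gm > 0
  planar <- FALSE
  if (any(ok)) {
    z <- complex(real = g$gx[ok], imaginary = g$gy[ok]) / gm[ok]
    planar <- (1 - Mod(sum(w[ok] * z)) / sum(w[ok])) <= thresholds$circVarMax
  }

  n1 <- nrow(H); n2 <- ncol(H)
  clampPt <- function(p) c(min(max(p[1L], 1), n1), min(max(p[2L], 1), n2))
  autoLine <- is.null(line)
  if (autoLine) {
    cl <- .centroidLine(m, direction, sp)
    line <- cl$line
  }
  if (!is.null(observer) && observer$endpointJitterMM > 0) {
    jit <- stats::rnorm(4, 0, observer$endpointJitterMM / sp)
    line <- profileLine(clampPt(line@start + jit[1:2]),
                        clampPt(line@end + jit[3:4]),
                        line@samplingStepMM)
  }
  # the rubric counts wavelengths over the muscle extent (the line as
  # placed); the caliper itself may read extrema beyond the delineated
  # muscle where the wave continues, so the sampled profile is extended
  # downstream by up to half the extent -- but only while it stays on
  # tissue (air pixels carry uniform random phase whose harmonic is large
  # and would inject spurious extrema)
  extentMM <- sqrt(sum((line@end - line@start)^2)) * sp
  calLine <- line
  if (autoLine) {
    dRC <- (line@end - line@start) / sqrt(sum((line@end - line@start)^2))
    sRoi <- mean(dataset@magnitude[m])
    extSteps <- floor(0.5 * extentMM / line@samplingStepMM)
    endPt <- line@end
    for (i in seq_len(extSteps)) {
      cand <- line@end + dRC * i * line@samplingStepMM / sp
      if (cand[1L] < 1 || cand[1L] > n1 || cand[2L] < 1 || cand[2L] > n2)
        break
      if (.bilinear(dataset@magnitude, cand[1L], cand[2L]) < 0.3 * sRoi)
        break
      endPt <- cand
    }
    calLine <- profileLine(line@start, endPt, line@samplingStepMM)
  }

  fr <- synthesizeFrames(field)@frames
  nf <- dim(fr)[3L]
  lambdas <- rep(NA_real_, nf)
  quality <- rep(NA_integer_, nf)
  extrema <- vector("list", nf)
  for (k in seq_len(nf)) {
    tr <- extractProfile(fr[, , k], calLine, sp)
    wl <- measureWavelength(tr, minProminenceFrac)
    peaks <- wl$peaksMM
    troughs <- wl$troughsMM
    if (!is.null(observer) && observer$extremumJitterMM > 0) {
      if (length(peaks))
        peaks <- sort(peaks + stats::rnorm(length(peaks), 0,
                                           observer$extremumJitterMM))
      if (length(troughs))
        troughs <- sort(troughs + stats::rnorm(length(troughs), 0,
                                               observer$extremumJitterMM))
    }
    lam <- .lambdaFromExtrema(peaks, troughs)
    lambdas[k] <- lam
    extrema[[k]] <- list(peaksMM = peaks, troughsMM = troughs)
    quality[k] <- if (!coherent) 1L
      else if (!planar) 2L
      else if (is.na(lam)) 3L
      else {
        Wk <- extentMM / lam
        if (Wk < 1) 3L else if (Wk < 2) 4L else 5L
      }
  }
  msr <- new("WavelengthMeasurement", perFrameLambdaMM = lambdas,
             perFrameQuality = quality, extremaPositions = extrema)
  used <- which(quality >= 3L & !is.na(lambdas))
  if (length(used) == 0L)
    stop("insufficient wave quality: no frame scored 3 or above with a measurable wavelength")
  lambdaMeanM <- mean(lambdas[used]) / 1000
  mu <- computeStiffness(lambdaMeanM, dataset@meta@frequencyHz, rhoKgM3)
  new("StiffnessResult", lambdaMeanM = lambdaMeanM,
      fHz = dataset@meta@frequencyHz, rhoKgM3 = rhoKgM3, muPa = mu,
      framesUsed = used, measurement = msr,
      datasetScore = max(quality))
}
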