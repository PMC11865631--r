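# Synthetic plane-wave MRE phantoms with known ground-truth stiffness.
#
# The phantom emulates a single oblique-axial slice through the upper
# trapezius: a band-shaped muscle ROI inside a larger "body" disc, bright
# fiducial-marker capsules, a signal-free air background, a propagating
# plane shear wave encoded into the phase images, and complex Gaussian
# receiver noise (so the magnitude is Rician and the phase noise is
# signal-dependent).

#' Phantom specification
#'
#' Ground truth and geometry for \code{\link{makePhantom}}. The wave
#' displacement field at phase offset k (of N) is
#' \deqn{u(x, t_k) = A e^{-\alpha d} \cos(2\pi k/N - 2\pi d/\lambda)}
#' with d the projection of the pixel position onto the propagation
#' direction measured from the upstream edge of the ROI band, A the source
#' displacement amplitude (um) and alpha the amplitude attenuation (1/mm).
#' The wavelength lambda follows from the ground-truth stiffness via
#' lambda = sqrt(mu/rho)/f.
#'
#' @slot mu0Pa ground-truth shear stiffness at the reference frequency (Pa).
#' @slot gamma dispersion exponent (>= 0); stiffness at frequency f is
#'   \code{mu0Pa * (f/f0Hz)^gamma}. Zero gives frequency-independent
#'   stiffness (the cross-fibre, HAP-like case).
#' @slot f0Hz reference frequency for \code{mu0Pa} (Hz).
#' @slot rhoKgM3 assumed tissue density, default 1000 kg/m^3.
#' @slot propagationAngleDeg in-plane wave direction, degrees from the +x
#'   (column) axis towards +y (row).
#' @slot amplitudeUm displacement amplitude at the source edge (um).
#' @slot attenuationPerMM exponential amplitude decay (1/mm).
#' @slot noiseSigma per-channel complex Gaussian noise SD (magnitude units).
#' @slot tissueLevel magnitude signal level inside the body (arbitrary
#'   units).
#' @slot roiGeometry list(lengthMM, widthMM): extent of the muscle band
#'   along and across the propagation direction.
#' @slot markerPositions n x 2 matrix of (row, col) fiducial centres;
#'   may have zero rows.
#' @slot backgroundPhaseRad static background phase inside the body (rad).
#' @slot matrixSize image matrix size (square).
#' @slot seed RNG seed used by \code{\link{makePhantom}}.
#' @export
setClass("PhantomSpec",
  representation(mu0Pa = "numeric", gamma = "numeric", f0Hz = "numeric",
                 rhoKgM3 = "numeric", propagationAngleDeg = "numeric",
                 amplitudeUm = "numeric", attenuationPerMM = "numeric",
                 noiseSigma = "numeric", tissueLevel = "numeric",
                 roiGeometry = "list", markerPositions = "matrix",
                 backgroundPhaseRad = "numeric", matrixSize = "integer",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@mu0Pa <= 0) msg <- c(msg, "mu0Pa must be positive")
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (object@f0Hz <= 0) msg <- c(msg, "f0Hz must be positive")
  if (object@rhoKgM3 <= 0) msg <- c(msg, "rhoKgM3 must be positive")
  if (object@attenuationPerMM < 0)
    msg <- c(msg, "attenuationPerMM must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@amplitudeUm < 0) msg <- c(msg, "amplitudeUm must be >= 0")
  if (object@matrixSize < 16L) msg <- c(msg, "matrixSize must be >= 16")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults emulate the study conditions: 128 x 128 matrix over an 18 cm
#' FOV, a 100 x 24 mm muscle band, three bright fiducial capsules near the
#' actuator edge, 20 um source amplitude, 0.05/mm attenuation and a tissue
#' magnitude of 100 with per-channel noise SD 3 (magnitude SNR about 33,
#' comfortably above the study's floor of 20).
#'
#' @param mu0Pa ground-truth shear stiffness at \code{f0Hz} (Pa).
#' @param gamma dispersion exponent (see \code{\link{dispersionLaw}}).
#' @param f0Hz reference frequency (Hz).
#' @param rhoKgM3 tissue density (kg/m^3).
#' @param propagationAngleDeg wave direction (degrees from +x towards +y).
#' @param amplitudeUm source displacement amplitude (um).
#' @param attenuationPerMM amplitude decay (1/mm).
#' @param noiseSigma per-channel complex noise SD; 0 for noise-free.
#' @param tissueLevel magnitude level inside the body.
#' @param roiGeometry list(lengthMM, widthMM) of the muscle band.
#' @param markerPositions n x 2 (row, col) marker centres, or NULL for the
#'   default three capsules.
#' @param backgroundPhaseRad static phase inside the body (rad).
#' @param matrixSize square image matrix size.
#' @param seed RNG seed.
#' @return A \code{PhantomSpec}.
#' @export
phantomSpec <- function(mu0Pa, gamma = 0, f0Hz = 60, rhoKgM3 = 1000,
                        propagationAngleDeg = 0, amplitudeUm = 20,
                        attenuationPerMM = 0.05, noiseSigma = 3,
                        tissueLevel = 100,
                        roiGeometry = list(lengthMM = 100, widthMM = 24),
                        markerPositions = NULL,
                        backgroundPhaseRad = 0.2,
                        matrixSize = 128L, seed = 1L) {
  if (is.null(markerPositions)) {
    n <- matrixSize
    markerPositions <- cbind(round(n * c(0.25, 0.5, 0.75)), round(n * 0.08))
  }
  new("PhantomSpec", mu0Pa = as.numeric(mu0Pa), gamma = as.numeric(gamma),
      f0Hz = as.numeric(f0Hz), rhoKgM3 = as.numeric(rhoKgM3),
      propagationAngleDeg = as.numeric(propagationAngleDeg),
      amplitudeUm = as.numeric(amplitudeUm),
      attenuationPerMM = as.numeric(attenuationPerMM),
      noiseSigma = as.numeric(noiseSigma),
      tissueLevel = as.numeric(tissueLevel), roiGeometry = roiGeometry,
      markerPositions = matrix(as.numeric(markerPositions), ncol = 2),
      backgroundPhaseRad = as.numeric(backgroundPhaseRad),
      matrixSize = as.integer(matrixSize), seed = as.integer(seed))
}

#' Power-law stiffness dispersion
#'
#' Emulates the frequency dependence of apparent muscle stiffness along the
#' fibre direction: \code{mu = mu0 * (f/f0)^gamma}. \code{gamma = 0} gives
#' frequency-independent stiffness, the behaviour observed across fibres.
#'
#' @param mu0Pa stiffness at the reference frequency (Pa).
#' @param fHz target vibration frequency (Hz).
#' @param f0Hz reference frequency (Hz).
#' @param gamma dispersion exponent (>= 0).
#' @return Stiffness at \code{fHz} (Pa).
#' @examples
#' dispersionLaw(4000, 120, 60, gamma = 1)  # 8000
#' @export
dispersionLaw <- function(mu0Pa, fHz, f0Hz, gamma) {
  .assertScalarPositive(mu0Pa, "mu0Pa")
  .assertScalarPositive(fHz, "fHz")
  .assertScalarPositive(f0Hz, "f0Hz")
  if (gamma < 0) stop("gamma must be >= 0")
  mu0Pa * (fHz / f0Hz)^gamma
}

#' Fit the dispersion exponent to stiffness-versus-frequency means
#'
#' Least-squares fit of the power-law exponent gamma in
#' mu(f) = mu(f0) * (f/f0)^gamma, performed in log space through the origin
#' (the curve is anchored at f0).
#'
#' @param frequenciesHz vector of frequencies (Hz).
#' @param meansPa stiffness means at those frequencies (same units
#'   throughout).
#' @param f0Hz anchor frequency (must be one of \code{frequenciesHz}).
#' @return The fitted exponent gamma.
#' @export
fitDispersionGamma <- function(frequenciesHz, meansPa, f0Hz) {
  if (length(frequenciesHz) != length(meansPa) || length(meansPa) < 2L)
    stop("need matching frequency and mean vectors of length >= 2")
  i0 <- match(f0Hz, frequenciesHz)
  if (is.na(i0)) stop("f0Hz must be one of frequenciesHz")
  x <- log(frequenciesHz / f0Hz)
  y <- log(meansPa / meansPa[i0])
  sum(x * y) / sum(x * x)
}

#' Shear wavelength implied by stiffness
#'
#' Inverts the plane-wave relation mu = rho*(lambda*f)^2:
#' lambda = sqrt(mu/rho)/f.
#'
#' @param muPa shear stiffness (Pa).
#' @param fHz vibration frequency (Hz).
#' @param rhoKgM3 tissue density (kg/m^3).
#' @return Wavelength in mm.
#' @examples
#' wavelengthFromStiffness(4000, 100)  # 20 mm
#' @export
wavelengthFromStiffness <- function(muPa, fHz, rhoKgM3 = 1000) {
  .assertScalarPositive(muPa, "muPa")
  .assertScalarPositive(fHz, "fHz")
  sqrt(muPa / rhoKgM3) / fHz * 1000
}

# Band ROI running along the propagation direction, centred on the image.
# Returns logical matrix.
.bandMask <- function(n, spacingMM, angleDeg, lengthMM, widthMM) {
  a <- angleDeg * pi / 180
  dx <- cos(a); dy <- sin(a)
  ctr <- (n + 1) / 2
  cc <- matrix(rep(seq_len(n), each = n), n)   # column index
  rr <- matrix(rep(seq_len(n), n), n)          # row index
  x <- (cc - ctr) * spacingMM
  y <- (rr - ctr) * spacingMM
  along <- x * dx + y * dy
  across <- -x * dy + y * dx
  abs(along) <= lengthMM / 2 & abs(across) <= widthMM / 2
}

.discMask <- function(n, centerRC, radiusPx) {
  cc <- matrix(rep(seq_len(n), each = n), n)
  rr <- matrix(rep(seq_len(n), n), n)
  (rr - centerRC[1L])^2 + (cc - centerRC[2L])^2 <= radiusPx^2
}

#' Generate a synthetic phase-offset MRE dataset with known ground truth
#'
#' Builds the magnitude image (body disc at \code{tissueLevel}, bright
#' fiducial markers at twice that level, signal-free air outside), encodes a
#' propagating, exponentially attenuated plane shear wave into the phase
#' offsets, adds complex Gaussian noise to the complex-valued image before
#' magnitude/phase extraction (so magnitude noise is Rician and phase noise
#' signal-dependent), and returns the dataset together with the muscle-band
#' and background ROI masks and the ground truth.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param meta an \code{\link{acquisitionMeta}}; its frequency selects the
#'   ground-truth stiffness through the spec's dispersion law.
#' @return A list with elements \code{dataset} (\code{MREDataset}),
#'   \code{roi} and \code{background} (\code{ROIMask}), and \code{truth}
#'   (list with \code{muPa}, \code{lambdaMM}, \code{direction}).
#' @examples
#' ph <- makePhantom(phantomSpec(4000, noiseSigma = 0), acquisitionMeta(100))
#' ph$truth$lambdaMM  # 20 mm
#' @export
makePhantom <- function(spec, meta) {
  stopifnot(is(spec, "PhantomSpec"), is(meta, "AcquisitionMeta"))
  validObject(spec); validObject(meta)
  n <- spec@matrixSize
  sp <- meta@pixelSpacingMM
  muPa <- dispersionLaw(spec@mu0Pa, meta@frequencyHz, spec@f0Hz, spec@gamma)
  lambdaMM <- wavelengthFromStiffness(muPa, meta@frequencyHz, spec@rhoKgM3)
  if (lambdaMM < 3 * sp)
    stop(sprintf("wavelength %.2f mm is below the resolvability limit of 3 pixels (%.2f mm)",
                 lambdaMM, 3 * sp))
  geo <- spec@roiGeometry
  fovMM <- n * sp
  if (geo$lengthMM > fovMM || geo$widthMM > fovMM)
    stop("ROI band does not fit inside the image")

  a <- spec@propagationAngleDeg * pi / 180
  dir <- c(cos(a), sin(a))          # (dx, dy) = (col, row) direction
  ctr <- (n + 1) / 2
  cc <- matrix(rep(seq_len(n), each = n), n)
  rr <- matrix(rep(seq_len(n), n), n)
  x <- (cc - ctr) * sp
  y <- (rr - ctr) * sp
  along <- x * dir[1L] + y * dir[2L]
  # distance from the upstream edge of the muscle band (the "source" edge)
  d <- along + geo$lengthMM / 2

  body <- .discMask(n, c(ctr, ctr), 0.47 * n)
  roi <- .bandMask(n, sp, spec@propagationAngleDeg, geo$lengthMM,
                   geo$widthMM) & body
  if (!any(roi)) stop("ROI band is empty")

  mag0 <- matrix(0, n, n)
  mag0[body] <- spec@tissueLevel
  if (nrow(spec@markerPositions))
    for (i in seq_len(nrow(spec@markerPositions))) {
      mk <- .discMask(n, spec@markerPositions[i, ], 2)
      mag0[mk] <- 2 * spec@tissueLevel
    }

  # background ROI: a disc in the top-left air corner
  bgCtr <- round(n * 0.08)
  bg <- .discMask(n, c(bgCtr, bgCtr), max(4, round(n * 0.05))) & !body
  if (sum(bg) < 30) stop("background ROI too small")

  env <- spec@amplitudeUm * exp(-spec@attenuationPerMM * pmax(d, 0))
  env[!body] <- 0
  N <- meta@nOffsets
  enc <- meta@encodingScaleRadPerUm
  phi0 <- matrix(0, n, n)
  phi0[body] <- spec@backgroundPhaseRad

  set.seed(spec@seed)
  phase <- array(0, c(n, n, N))
  magOut <- NULL
  for (k in seq_len(N) - 1L) {
    u <- env * cos(2 * pi * k / N - 2 * pi * d / lambdaMM)
    ph <- phi0 + enc * u
    z <- complex(modulus = mag0, argument = ph)
    if (spec@noiseSigma > 0)
      z <- z + complex(real = rnorm(n * n, 0, spec@noiseSigma),
                       imaginary = rnorm(n * n, 0, spec@noiseSigma))
    if (k == 0L) magOut <- matrix(Mod(z), n, n)
    phase[, , k + 1L] <- Arg(z)
  }
  # noise-free magnitude has Arg(z)=ph already exact; keep phase as written
  ds <- mreDataset(magnitude = magOut, phaseStack = phase, meta = meta)
  list(dataset = ds,
       roi = roiMask(roi, "UT"),
       background = roiMask(bg, "background"),
       truth = list(muPa = muPa, lambdaMM = lambdaMM, direction = dir))
}

#' Radial-source phantom (non-planar waves)
#'
#' Generates a wave field radiating from a point source inside the ROI;
#' used to exercise quality score 2 (coherent but non-planar waves).
#' Same noise and magnitude model as \code{\link{makePhantom}}.
#'
#' @inheritParams makePhantom
#' @param sourceRC (row, col) of the point source; defaults to the image
#'   centre.
#' @return Same structure as \code{\link{makePhantom}}.
#' @export
makeRadialPhantom <- function(spec, meta, sourceRC = NULL) {
  stopifnot(is(spec, "PhantomSpec"), is(meta, "AcquisitionMeta"))
  n <- spec@matrixSize
  sp <- meta@pixelSpacingMM
  muPa <- dispersionLaw(spec@mu0Pa, meta@frequencyHz, spec@f0Hz, spec@gamma)
  lambdaMM <- wavelengthFromStiffness(muPa, meta@frequencyHz, spec@rhoKgM3)
  ctr <- (n + 1) / 2
  if (is.null(sourceRC)) sourceRC <- c(ctr, ctr)
  cc <- matrix(rep(seq_len(n), each = n), n)
  rr <- matrix(rep(seq_len(n), n), n)
  d <- sqrt(((rr - sourceRC[1L]) * sp)^2 + ((cc - sourceRC[2L]) * sp)^2)
  body <- .discMask(n, c(ctr, ctr), 0.47 * n)
  geo <- spec@roiGeometry
  roi <- .bandMask(n, sp, spec@propagationAngleDeg, geo$lengthMM,
                   geo$widthMM) & body
  mag0 <- matrix(0, n, n); mag0[body] <- spec@tissueLevel
  bgCtr <- round(n * 0.08)
  bg <- .discMask(n, c(bgCtr, bgCtr), max(4, round(n * 0.05))) & !body
  env <- spec@amplitudeUm * exp(-spec@attenuationPerMM * d) /
    sqrt(pmax(d / lambdaMM, 0.25))   # cylindrical spreading, capped at source
  env[!body] <- 0
  N <- meta@nOffsets
  set.seed(spec@seed)
  phase <- array(0, c(n, n, N))
  magOut <- NULL
  for (k in seq_len(N) - 1L) {
    u <- env * cos(2 * pi * k / N - 2 * pi * d / lambdaMM)
    ph <- spec@backgroundPhaseRad * (mag0 > 0) + meta@encodingScaleRadPerUm * u
    z <- complex(modulus = mag0, argument = ph)
    if (spec@noiseSigma > 0)
      z <- z + complex(real = rnorm(n * n, 0, spec@noiseSigma),
                       imaginary = rnorm(n * n, 0, spec@noiseSigma))
    if (k == 0L) magOut <- matrix(Mod(z), n, n)
    phase[, , k + 1L] <- Arg(z)
  }
  ds <- mreDataset(magnitude = magOut, phaseStack = phase, meta = meta)
  list(dataset = ds, roi = roiMask(roi, "UT"),
       background = roiMask(bg, "background"),
       truth = list(muPa = muPa, lambdaMM = lambdaMM, direction = NULL))
}
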