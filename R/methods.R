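# Accessors and show methods.

#' @rdname MREDataset-class
#' @export
setMethod("magnitude", "MREDataset", function(object) object@magnitude)

#' @rdname MREDataset-class
#' @export
setMethod("phaseStack", "MREDataset", function(object) object@phaseStack)

#' @rdname AcquisitionMeta-class
#' @export
setMethod("meta", "MREDataset", function(object) object@meta)

#' @rdname AcquisitionMeta-class
#' @export
setMethod("meta", "WaveField", function(object) object@meta)

#' @rdname AcquisitionMeta-class
#' @export
setMethod("meta", "WaveFrames", function(object) object@meta)

#' @rdname WaveField-class
#' @export
setMethod("harmonic", "WaveField", function(object) object@harmonic)

#' @rdname WaveFrames-class
#' @export
setMethod("frames", "WaveFrames", function(object) object@frames)

#' @rdname ROIMask-class
#' @export
setMethod("maskMatrix", "ROIMask", function(object) object@mask)

#' @rdname StiffnessResult-class
#' @export
setMethod("stiffnessPa", "StiffnessResult", function(object) object@muPa)

#' @rdname SNRResult-class
#' @export
setMethod("snrValue", "SNRResult", function(object) object@snr)

setMethod("show", "AcquisitionMeta", function(object) {
  cat(sprintf(
    "AcquisitionMeta: %g Hz, %d offsets, %.5g mm px, %s/%s, subject %s\n",
    object@frequencyHz, object@nOffsets, object@pixelSpacingMM,
    object@actuatorPosition, object@side, object@subjectId))
})

setMethod("show", "MREDataset", function(object) {
  d <- dim(object@phaseStack)
  cat(sprintf("MREDataset: %d x %d magnitude, %d phase offsets\n",
              d[1L], d[2L], d[3L]))
  show(object@meta)
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask '%s': %d x %d, %d pixels set\n", object@label,
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
})

setMethod("show", "WaveField", function(object) {
  cat(sprintf("WaveField: %d x %d complex first harmonic, max |H| = %.4g\n",
              nrow(object@harmonic), ncol(object@harmonic),
              max(Mod(object@harmonic))))
})

setMethod("show", "WaveFrames", function(object) {
  d <- dim(object@frames)
  cat(sprintf("WaveFrames: %d x %d x %d\n", d[1L], d[2L], d[3L]))
})

setMethod("show", "StiffnessResult", function(object) {
  cat(sprintf(
    paste0("StiffnessResult: mu = %.3f kPa (lambda = %.2f mm, f = %g Hz,",
           " %d/%d frames used, score %d)\n"),
    object@muPa / 1000, object@lambdaMeanM * 1000, object@fHz,
    length(object@framesUsed),
    length(object@measurement@perFrameLambdaMM), object@datasetScore))
})

setMethod("show", "SNRResult", function(object) {
  cat(sprintf("SNRResult: SNR = %.2f (S = %.3g, sigma_bg = %.3g)\n",
              object@snr, object@sRoi, object@sigmaBg))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf(
    paste0("AgreementReport: kappa = %.3f (%s), ICC = %.3f, bias = %.3f,",
           " LoA = %.3f [%.3f, %.3f], CV = %.1f%%\n"),
    object@kappa, object@kappaBand, object@icc, object@bias, object@loa,
    object@lb, object@ub, object@cvPercent))
})

setMethod("show", "FactorialResult", function(object) {
  cat(sprintf("FactorialResult: chi2 = %.3f, df = %d, p = %.3g (%d pairwise)\n",
              object@chi2, object@df, object@p, nrow(object@pairwise)))
})
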