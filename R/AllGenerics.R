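#' @rdname MREDataset-class
#' @param object an object.
#' @export
setGeneric("magnitude", function(object) standardGeneric("magnitude"))

#' @rdname MREDataset-class
#' @export
setGeneric("phaseStack", function(object) standardGeneric("phaseStack"))

#' @rdname AcquisitionMeta-class
#' @param object an object carrying acquisition metadata.
#' @export
setGeneric("meta", function(object) standardGeneric("meta"))

#' @rdname WaveField-class
#' @param object an object.
#' @export
setGeneric("harmonic", function(object) standardGeneric("harmonic"))

#' @rdname WaveFrames-class
#' @param object an object.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname ROIMask-class
#' @param object an object.
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @rdname StiffnessResult-class
#' @param object an object carrying a stiffness value.
#' @export
setGeneric("stiffnessPa", function(object) standardGeneric("stiffnessPa"))

#' @rdname SNRResult-class
#' @param object an object carrying an SNR value.
#' @export
setGeneric("snrValue", function(object) standardGeneric("snrValue"))
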