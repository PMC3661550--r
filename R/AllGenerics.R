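#' @rdname HaplotypePanel-class
#' @param x,object an object.
#' @export
setGeneric("hapMatrix", function(x) standardGeneric("hapMatrix"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("populationLabel", function(x) standardGeneric("populationLabel"))

#' @rdname MotifMatrix-class
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' @rdname MotifMatrix-class
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname MotifMatrix-class
#' @export
setGeneric("motifProbs", function(x) standardGeneric("motifProbs"))

#' @rdname MotifMatrix-class
#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))

#' @rdname AnnotationTrack-class
#' @export
setGeneric("trackName", function(x) standardGeneric("trackName"))

#' @rdname AnnotationTrack-class
#' @export
setGeneric("trackClass", function(x) standardGeneric("trackClass"))

#' @rdname AnnotationTrack-class
#' @export
setGeneric("trackRanges", function(x) standardGeneric("trackRanges"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("cdsExons", function(x) standardGeneric("cdsExons"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("transcriptTss", function(x) standardGeneric("transcriptTss"))
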