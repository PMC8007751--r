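#' @name ztwbes-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param x an object.
#' @param ... further arguments for methods.
#' @keywords internal
NULL

#' @rdname ztwbes-generics
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname ztwbes-generics
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))

#' @rdname ztwbes-generics
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname ztwbes-generics
#' @export
setGeneric("emotions", function(x) standardGeneric("emotions"))

#' @rdname ztwbes-generics
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))

#' @rdname ztwbes-generics
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))

#' @rdname ztwbes-generics
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname ztwbes-generics
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname ztwbes-generics
#' @export
setGeneric("trialData", function(x, id) standardGeneric("trialData"))

#' @rdname ztwbes-generics
#' @export
setGeneric("winnerLocation", function(x) standardGeneric("winnerLocation"))

#' @rdname ztwbes-generics
#' @export
setGeneric("eliteElectrodes", function(x) standardGeneric("eliteElectrodes"))

#' @rdname ztwbes-generics
#' @export
setGeneric("electrodeVotes", function(x) standardGeneric("electrodeVotes"))

#' @rdname ztwbes-generics
#' @export
setGeneric("voteMargin", function(x) standardGeneric("voteMargin"))

#' @rdname ztwbes-generics
#' @export
setGeneric("relevanceRho", function(x) standardGeneric("relevanceRho"))

#' @rdname ztwbes-generics
#' @export
setGeneric("relevantElectrodes",
           function(x, emotion, band) standardGeneric("relevantElectrodes"))

#' @rdname ztwbes-generics
#' @export
setGeneric("trainingAccuracy", function(x) standardGeneric("trainingAccuracy"))
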