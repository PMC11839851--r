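#' @name SpectCertainty-generics
#' @title Accessor generics
#' @description Accessor generics for the classes in this package.
#' @param x,object an object.
#' @param ... further arguments.
#' @keywords internal
NULL

#' @rdname SpectCertainty-generics
#' @export
setGeneric("nScans", function(x) standardGeneric("nScans"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("nInstances", function(x) standardGeneric("nInstances"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("scanInfo", function(x) standardGeneric("scanInfo"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("instanceInfo", function(x) standardGeneric("instanceInfo"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("readerVotes", function(x) standardGeneric("readerVotes"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("severities", function(x) standardGeneric("severities"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("trueClasses", function(x) standardGeneric("trueClasses"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("slabImage", function(x, i) standardGeneric("slabImage"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("targetProportions", function(x) standardGeneric("targetProportions"))

#' @rdname SpectCertainty-generics
#' @export
setGeneric("parameterAccount", function(x) standardGeneric("parameterAccount"))
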