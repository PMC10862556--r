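#' @name accessors
#' @title Accessor generics for dustbiome containers
#' @param x a dustbiome object.
#' @param object a dustbiome object (show methods).
#' @description Slot access goes through these accessors; slots are an
#'   implementation detail.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("elementNames", function(x) standardGeneric("elementNames"))

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("uncertainties", function(x) standardGeneric("uncertainties"))

#' @rdname accessors
#' @export
setGeneric("pm10Mass", function(x) standardGeneric("pm10Mass"))

#' @rdname accessors
#' @export
setGeneric("pm25Mass", function(x) standardGeneric("pm25Mass"))

#' @rdname accessors
#' @export
setGeneric("sourceNames", function(x) standardGeneric("sourceNames"))

#' @rdname accessors
#' @export
setGeneric("massFractions", function(x) standardGeneric("massFractions"))

#' @rdname accessors
#' @export
setGeneric("massFractionUnc", function(x) standardGeneric("massFractionUnc"))

#' @rdname accessors
#' @export
setGeneric("otuIDs", function(x) standardGeneric("otuIDs"))

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname accessors
#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))

#' @rdname accessors
#' @export
setGeneric("covariateValues", function(x) standardGeneric("covariateValues"))

#' @rdname accessors
#' @export
setGeneric("sourceContributions", function(x) standardGeneric("sourceContributions"))

#' @rdname accessors
#' @export
setGeneric("contributionUnc", function(x) standardGeneric("contributionUnc"))
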