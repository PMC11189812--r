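#' @importFrom BiocGenerics counts
NULL

#' Region names of an object
#' @param x an object holding per-region data.
#' @return character vector of region abbreviations.
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' Treatment groups of an object
#' @param x an object annotated with treatment labels.
#' @return factor (or character) of group labels.
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' Animal identifiers of an object
#' @param x an object annotated with animal ids.
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' z-score matrix (animals x regions)
#' @param x a ZScoreMatrix.
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' Activation pattern vector
#' @param x an ActivationPattern.
#' @export
setGeneric("activation", function(x) standardGeneric("activation"))

#' Fitted slow baseline
#' @param x a BaselineFit.
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))

#' Event table of an EventLog or EvokedResponseSet
#' @param x the object.
#' @export
setGeneric("events", function(x) standardGeneric("events"))
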