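#' @rdname EvolutionHistory-class
#' @param x an object.
#' @export
setGeneric("tipSequences", function(x) standardGeneric("tipSequences"))

#' @rdname EvolutionHistory-class
#' @export
setGeneric("ancestorSequences",
           function(x) standardGeneric("ancestorSequences"))

#' @rdname EvolutionHistory-class
#' @export
setGeneric("nodeSequences", function(x) standardGeneric("nodeSequences"))

#' @rdname EvolutionHistory-class
#' @export
setGeneric("trueAlignment", function(x) standardGeneric("trueAlignment"))

#' @rdname EvolutionHistory-class
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' @rdname EvolutionHistory-class
#' @export
setGeneric("siteCategories", function(x) standardGeneric("siteCategories"))

#' @rdname AncestralReconstruction-class
#' @param x an object.
#' @export
setGeneric("ancestralSequences",
           function(x) standardGeneric("ancestralSequences"))

#' @rdname AncestralReconstruction-class
#' @export
setGeneric("presenceCalls", function(x) standardGeneric("presenceCalls"))

#' @rdname MarginalPosterior-class
#' @param x an object.
#' @export
setGeneric("aminoAcidPosterior",
           function(x) standardGeneric("aminoAcidPosterior"))

#' @rdname MarginalPosterior-class
#' @export
setGeneric("presencePosterior",
           function(x) standardGeneric("presencePosterior"))

#' @rdname MarginalPosterior-class
#' @export
setGeneric("totalLogLikelihood",
           function(x) standardGeneric("totalLogLikelihood"))

#' @rdname RateModel-class
#' @param x an object.
#' @export
setGeneric("categoryRates", function(x) standardGeneric("categoryRates"))

#' @rdname RateModel-class
#' @export
setGeneric("stationaryFrequencies",
           function(x) standardGeneric("stationaryFrequencies"))
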