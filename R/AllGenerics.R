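#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname accessors
#' @export
setGeneric("indIds", function(x) standardGeneric("indIds"))

#' @rdname accessors
#' @export
setGeneric("generationIndex", function(x) standardGeneric("generationIndex"))

#' @rdname accessors
#' @export
setGeneric("markerEffects", function(x) standardGeneric("markerEffects"))

#' @rdname accessors
#' @export
setGeneric("overallMean", function(x) standardGeneric("overallMean"))

#' @rdname accessors
#' @export
setGeneric("recombFreq", function(x) standardGeneric("recombFreq"))

#' @rdname accessors
#' @export
setGeneric("chromAssign", function(x) standardGeneric("chromAssign"))

#' @rdname accessors
#' @export
setGeneric("nChrom", function(x) standardGeneric("nChrom"))

#' @rdname accessors
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' @rdname accessors
#' @export
setGeneric("crossPairs", function(x) standardGeneric("crossPairs"))

#' @rdname accessors
#' @export
setGeneric("nCrosses", function(x) standardGeneric("nCrosses"))

#' @rdname gebv
#' @export
setGeneric("gebv", function(x, trait, ...) standardGeneric("gebv"))

#' @rdname potentials
#' @export
setGeneric("lowerPotential", function(x, trait, ...)
  standardGeneric("lowerPotential"))

#' @rdname potentials
#' @export
setGeneric("upperPotential", function(x, trait, ...)
  standardGeneric("upperPotential"))

#' @rdname makeProgeny
#' @export
setGeneric("makeProgeny", function(x, pair, nProgeny, map, ...)
  standardGeneric("makeProgeny"))
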