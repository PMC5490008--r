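#' @include AllClasses.R
NULL

#' Accessors for virodiv classes
#'
#' Small accessor generics for the package's S4 containers; slot access
#' from user code is discouraged.
#'
#' @param x an object.
#' @return The corresponding component.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("parentId", function(x) standardGeneric("parentId"))
#' @rdname accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))
#' @rdname accessors
#' @export
setGeneric("islands", function(x) standardGeneric("islands"))
#' @rdname accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("focalId", function(x) standardGeneric("focalId"))
#' @rdname accessors
#' @export
setGeneric("focalGenome", function(x) standardGeneric("focalGenome"))
#' @rdname accessors
#' @export
setGeneric("mate1", function(x) standardGeneric("mate1"))
#' @rdname accessors
#' @export
setGeneric("mate2", function(x) standardGeneric("mate2"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))
#' @rdname accessors
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))
#' @rdname accessors
#' @export
setGeneric("siteDepth", function(x) standardGeneric("siteDepth"))
#' @rdname accessors
#' @export
setGeneric("mappedBases", function(x) standardGeneric("mappedBases"))
#' @rdname accessors
#' @export
setGeneric("aniPct", function(x) standardGeneric("aniPct"))
#' @rdname accessors
#' @export
setGeneric("alignedFraction", function(x) standardGeneric("alignedFraction"))
#' @rdname accessors
#' @export
setGeneric("recoveryTable", function(x) standardGeneric("recoveryTable"))
#' @rdname accessors
#' @export
setGeneric("contigSummary", function(x) standardGeneric("contigSummary"))
#' @rdname accessors
#' @export
setGeneric("alleleTable", function(x) standardGeneric("alleleTable"))
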