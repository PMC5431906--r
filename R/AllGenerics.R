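#' Accessors for GenomeAnnotation
#'
#' Return the component tables of a [GenomeAnnotation-class]. All
#' coordinates are 0-based half-open.
#'
#' @param x a GenomeAnnotation
#' @return a data.frame (see the class documentation for columns)
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname annotation-accessors
#' @export
setGeneric("transcriptTable", function(x) standardGeneric("transcriptTable"))

#' @rdname annotation-accessors
#' @export
setGeneric("exonTable", function(x) standardGeneric("exonTable"))

#' @rdname annotation-accessors
#' @export
setGeneric("polyASiteTable", function(x) standardGeneric("polyASiteTable"))

#' @rdname annotation-accessors
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))

#' @rdname annotation-accessors
#' @export
setMethod("geneTable", "GenomeAnnotation", function(x) x@genes)

#' @rdname annotation-accessors
#' @export
setMethod("transcriptTable", "GenomeAnnotation", function(x) x@transcripts)

#' @rdname annotation-accessors
#' @export
setMethod("exonTable", "GenomeAnnotation", function(x) x@exons)

#' @rdname annotation-accessors
#' @export
setMethod("polyASiteTable", "GenomeAnnotation", function(x) x@polyASites)

#' @rdname annotation-accessors
#' @export
setMethod("domainTable", "GenomeAnnotation", function(x) x@domains)
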