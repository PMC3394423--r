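#' @rdname accessors
#' @export
setGeneric("geneIndices", function(x) standardGeneric("geneIndices"))

#' @rdname accessors
#' @export
setGeneric("conditionIndices", function(x) standardGeneric("conditionIndices"))

#' @rdname accessors
#' @export
setGeneric("biclusterSize", function(x) standardGeneric("biclusterSize"))

#' @rdname archive-accessors
#' @export
setGeneric("archiveSize", function(x) standardGeneric("archiveSize"))

#' @rdname archive-accessors
#' @export
setGeneric("archiveObjectives", function(x) standardGeneric("archiveObjectives"))

#' @rdname archive-accessors
#' @export
setGeneric("archiveBiclusters", function(x) standardGeneric("archiveBiclusters"))
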