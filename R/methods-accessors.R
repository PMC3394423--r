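#' Accessors for Bicluster objects
#'
#' @param x a [Bicluster-class].
#' @return \code{geneIndices}/\code{conditionIndices}: integer index vectors;
#'   \code{biclusterSize}: number of cells |g| * |c|.
#' @name accessors
#' @aliases geneIndices,Bicluster-method conditionIndices,Bicluster-method
#'   biclusterSize,Bicluster-method
NULL

#' @rdname accessors
#' @export
setMethod("geneIndices", "Bicluster", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("conditionIndices", "Bicluster", function(x) x@conditions)

#' @rdname accessors
#' @export
setMethod("biclusterSize", "Bicluster",
          function(x) length(x@genes) * length(x@conditions))

#' Accessors for the epsilon-dominance archive
#'
#' @param x an [EpsArchive-class].
#' @return \code{archiveSize}: member count; \code{archiveObjectives}: the
#'   objective matrix (one row per member); \code{archiveBiclusters}: list of
#'   [Bicluster-class] decoded from the stored positions.
#' @name archive-accessors
#' @aliases archiveSize,EpsArchive-method archiveObjectives,EpsArchive-method
#'   archiveBiclusters,EpsArchive-method
NULL

#' @rdname archive-accessors
#' @export
setMethod("archiveSize", "EpsArchive", function(x) nrow(x@objectives))

#' @rdname archive-accessors
#' @export
setMethod("archiveObjectives", "EpsArchive", function(x) x@objectives)

#' @rdname archive-accessors
#' @export
setMethod("archiveBiclusters", "EpsArchive", function(x) {
  if (x@n < 1L || x@m < 1L)
    stop("archive carries no matrix dimensions; positions cannot be decoded")
  lapply(x@positions, decodeBicluster, n = x@n, m = x@m)
})

setMethod("show", "Bicluster", function(object) {
  cat(sprintf("Bicluster: %d genes x %d conditions (size %d)\n",
              length(object@genes), length(object@conditions),
              biclusterSize(object)))
})

setMethod("show", "PlantedBicluster", function(object) {
  cat(sprintf("PlantedBicluster (%s): %d genes x %d conditions, noise sd %.3g\n",
              object@pattern, length(object@genes),
              length(object@conditions), object@noiseSd))
})

setMethod("show", "EpsArchive", function(object) {
  cat(sprintf("EpsArchive: %d member(s), epsilon = (%s)\n",
              archiveSize(object),
              paste(signif(object@epsilon, 3), collapse = ", ")))
  if (archiveSize(object) > 0) {
    rng <- apply(object@objectives, 2, range)
    cat("objective ranges:\n")
    for (j in seq_len(ncol(rng)))
      cat(sprintf("  f%d: [%.4g, %.4g]\n", j, rng[1, j], rng[2, j]))
  }
})

setMethod("show", "SFLConfig", function(object) {
  cat("SFLConfig:\n")
  cat(sprintf("  swarm: %d frogs, %d memeplexes, %d cycles, %d generations\n",
              object@nFrogs, object@nMemeplexes, object@cyclesPerMemeplex,
              object@nGenerations))
  cat(sprintf("  delta = %g, epsilon = (%s)\n", object@delta,
              paste(object@epsilon, collapse = ", ")))
  cat(sprintf("  population in [%d, %d], selectionRatio %.2f, growthStep %d\n",
              object@popMin, object@popMax, object@selectionRatio,
              object@growthStep))
})

setMethod("show", "SFLRun", function(object) {
  cat(sprintf("SFLRun on a %d x %d matrix (seed %d): %d generations, %d archived bicluster(s)\n",
              object@dim[1], object@dim[2], object@seed,
              nrow(object@log), archiveSize(object@archive)))
})
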