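.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Recovery of planted biclusters
#'
#' For each ground-truth plant, the maximum over found biclusters of the
#' Jaccard index on gene sets and on condition sets (each maximised
#' independently), and the maximum Jaccard on cell sets (gene x condition
#' pairs, the combined score). An empty found list scores zero.
#'
#' @param found list of [Bicluster-class] (e.g. [archiveBiclusters()]).
#' @param truth list of [Bicluster-class] / [PlantedBicluster-class].
#' @return data.frame(plant, geneJaccard, conditionJaccard, cellJaccard),
#'   one row per plant.
#' @export
recoveryScore <- function(found, truth) {
  cells <- function(B) {
    as.vector(outer(B@genes, B@conditions,
                    function(g, c) paste(g, c, sep = ":")))
  }
  rows <- lapply(seq_along(truth), function(ti) {
    tr <- truth[[ti]]
    if (length(found) == 0L)
      return(data.frame(plant = ti, geneJaccard = 0,
                        conditionJaccard = 0, cellJaccard = 0))
    gj <- vapply(found, function(B) .jaccard(B@genes, tr@genes), numeric(1))
    cj <- vapply(found, function(B)
      .jaccard(B@conditions, tr@conditions), numeric(1))
    tc <- cells(tr)
    xj <- vapply(found, function(B) .jaccard(cells(B), tc), numeric(1))
    data.frame(plant = ti, geneJaccard = max(gj),
               conditionJaccard = max(cj), cellJaccard = max(xj))
  })
  do.call(rbind, rows)
}

#' Coverage of the matrix by a set of biclusters
#'
#' Union-based fractions of genes, conditions and cells touched by at least
#' one bicluster; each cell counts once regardless of multiplicity.
#'
#' @param found list of [Bicluster-class].
#' @param n,m matrix dimensions.
#' @return named numeric vector c(genes, conditions, cells), each in [0, 1].
#' @examples
#' coverageStats(list(Bicluster(1:10, 1:5)), 100, 20)
#' @export
coverageStats <- function(found, n, m) {
  if (length(found) == 0L)
    return(c(genes = 0, conditions = 0, cells = 0))
  gCov <- logical(n); cCov <- logical(m)
  cellCov <- matrix(FALSE, n, m)
  for (B in found) {
    gCov[B@genes] <- TRUE
    cCov[B@conditions] <- TRUE
    cellCov[B@genes, B@conditions] <- TRUE
  }
  c(genes = mean(gCov), conditions = mean(cCov), cells = mean(cellCov))
}
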