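#' Hypergeometric enrichment p-value
#'
#' Probability of observing at least \code{k} genes of a functional category
#' in a bicluster of \code{n} genes drawn from a genome of \code{g} genes of
#' which \code{mCat} belong to the category:
#' \deqn{p = 1 - \sum_{i=0}^{k-1} \binom{m}{i}\binom{g-m}{n-i} / \binom{g}{n}}
#' Computed as an upper hypergeometric tail via [stats::phyper()], which
#' works in log space and stays stable at genome scale where naive
#' factorials overflow.
#'
#' @param k observed category genes inside the bicluster (>= 0).
#' @param n bicluster gene count (> 0).
#' @param mCat category size in the genome (>= 0).
#' @param g genome size (> 0).
#' @return p-value in [0, 1]; \code{k = 0} gives exactly 1.
#' @examples
#' hypergeomPvalue(2, 5, 4, 10)  # 1 - 66/252
#' @export
hypergeomPvalue <- function(k, n, mCat, g) {
  if (any(c(k, mCat) < 0) || any(c(n, g) < 1))
    stop("require k >= 0, mCat >= 0, n >= 1, g >= 1")
  if (k > min(n, mCat)) stop("k cannot exceed min(n, mCat)")
  if (mCat > g || n > g) stop("category and bicluster must fit in the genome")
  if (k == 0) return(1)
  stats::phyper(k - 1, mCat, g - mCat, n, lower.tail = FALSE)
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then tab-separated gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene-set file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                     paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets
}

#' Gene-set enrichment of a bicluster
#'
#' One row per gene set with the overlap count \code{k} and the
#' hypergeometric p-value of observing at least \code{k} category genes in
#' the bicluster, sorted ascending by p. Raw p-values are reported (as in
#' the original analysis); a Bonferroni-adjusted column is added as a
#' clearly labelled extension. Bicluster genes not present in any set are
#' silently ignored apart from a message with their count.
#'
#' @param bicluster a [Bicluster-class].
#' @param geneIds character vector labelling the matrix rows.
#' @param geneSets named list of character vectors (see [readGMT()]).
#' @param g genome size; defaults to \code{length(geneIds)}.
#' @return data.frame(set, k, n, mCat, g, p, pBonferroni).
#' @export
enrichBicluster <- function(bicluster, geneIds, geneSets,
                            g = length(geneIds)) {
  if (length(geneSets) == 0L) stop("empty gene-set collection")
  genes <- geneIds[geneIndices(bicluster)]
  known <- unique(unlist(geneSets, use.names = FALSE))
  nUnknown <- sum(!genes %in% known)
  if (nUnknown > 0)
    message(nUnknown, " bicluster gene(s) absent from every gene set")
  n <- length(genes)
  rows <- lapply(names(geneSets), function(nm) {
    set <- geneSets[[nm]]
    mCat <- length(set)
    k <- sum(genes %in% set)
    data.frame(set = nm, k = k, n = n, mCat = mCat, g = g,
               p = hypergeomPvalue(k, n, mCat, g))
  })
  out <- do.call(rbind, rows)
  out$pBonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p), , drop = FALSE]
}

#' Write an enrichment table as TSV
#'
#' @param table data.frame from [enrichBicluster()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEnrichmentTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
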