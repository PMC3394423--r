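#' Decode a binary membership vector into a Bicluster
#'
#' A candidate bicluster is a binary string of fixed length n + m: the first
#' n bits select genes, the last m bits select conditions. A set bit means
#' the corresponding gene or condition belongs to the bicluster.
#'
#' @param bits logical or 0/1 vector of length \code{n + m}.
#' @param n,m matrix dimensions.
#' @return A [Bicluster-class].
#' @examples
#' decodeBicluster(c(1, 1, 0, 0, 0, 1, 1, 1, 0), n = 5, m = 4)  # 2 x 3, size 6
#' @export
decodeBicluster <- function(bits, n, m) {
  b <- asBits(bits)
  if (length(b) != n + m)
    stop(sprintf("bit vector has length %d; expected n + m = %d",
                 length(b), n + m))
  g <- which(b[seq_len(n)])
  c <- which(b[n + seq_len(m)])
  if (length(g) == 0L || length(c) == 0L)
    stop("degenerate bicluster: no gene or no condition bit set")
  Bicluster(g, c)
}

#' Encode gene/condition membership as a binary vector
#'
#' Inverse of [decodeBicluster()]. The low-level interface accepts bare
#' (possibly empty) index vectors; pass a [Bicluster-class] via \code{x}.
#'
#' @param x a [Bicluster-class], or an integer vector of gene indices.
#' @param conditions integer vector of condition indices (ignored when
#'   \code{x} is a Bicluster).
#' @param n,m matrix dimensions.
#' @return Logical vector of length \code{n + m}.
#' @examples
#' encodeBicluster(Bicluster(1:2, 1:3), n = 5, m = 4)
#' @export
encodeBicluster <- function(x, conditions = NULL, n, m) {
  if (is(x, "Bicluster")) {
    genes <- x@genes; conditions <- x@conditions
  } else genes <- as.integer(x)
  conditions <- as.integer(conditions)
  if (length(genes) && (min(genes) < 1L || max(genes) > n))
    stop("gene index out of range")
  if (length(conditions) && (min(conditions) < 1L || max(conditions) > m))
    stop("condition index out of range")
  bits <- logical(n + m)
  bits[genes] <- TRUE
  bits[n + conditions] <- TRUE
  bits
}

# fast internal scorer on raw index vectors; returns c(msr, rvar)
# population (divide-by-count) normalisation throughout
.scoreSub <- function(M, gi, ci) {
  sub <- M[gi, ci, drop = FALSE]
  rm <- rowMeans(sub)
  cm <- colMeans(sub)
  mu <- mean(sub)
  dev <- sub - rm                       # recycles down rows
  # a single row or column has identically zero residue (the row/column
  # mean absorbs every cell), so return the exact value
  msr <- if (length(gi) == 1L || length(ci) == 1L) 0 else {
    res <- dev - rep(cm - mu, each = length(gi))
    mean(res * res)
  }
  c(msr = msr, rvar = mean(dev * dev))
}

.checkBicluster <- function(M, B) {
  stopIfNotMatrix(M)
  if (length(B@genes) == 0L || length(B@conditions) == 0L)
    stop("degenerate bicluster: empty gene or condition set")
  if (max(B@genes) > nrow(M) || max(B@conditions) > ncol(M))
    stop("bicluster indices exceed matrix dimensions")
}

#' Dimension means of a bicluster
#'
#' Per-gene means d_ic (mean of gene i over the selected conditions),
#' per-condition means d_gj, and the overall mean d_gc of all selected cells.
#'
#' @param M numeric expression matrix.
#' @param B a [Bicluster-class].
#' @return list(gene, condition, overall).
#' @examples
#' D <- matrix(c(1, 3, 2, 5), 2, 2)
#' dimensionMeans(D, Bicluster(1:2, 1:2))
#' @export
dimensionMeans <- function(M, B) {
  .checkBicluster(M, B)
  sub <- M[B@genes, B@conditions, drop = FALSE]
  list(gene = rowMeans(sub), condition = colMeans(sub), overall = mean(sub))
}

#' Mean squared residue of a bicluster
#'
#' The Cheng–Church coherence score: the residue of cell (i, j) is
#' \code{r_ij = d_ij - d_ic - d_gj + d_gc}; the mean squared residue is the
#' average of \code{r_ij^2} over the bicluster. It is 0 for any perfectly
#' additive pattern \code{d_ij = a_i + b_j} and for any single-row or
#' single-column bicluster.
#'
#' @inheritParams dimensionMeans
#' @return Non-negative numeric scalar.
#' @examples
#' D <- matrix(c(1, 3, 2, 5), 2, 2)
#' biclusterMSR(D, Bicluster(1:2, 1:2))  # 0.0625
#' @export
biclusterMSR <- function(M, B) {
  .checkBicluster(M, B)
  unname(.scoreSub(M, B@genes, B@conditions)["msr"])
}

#' Row variance of a bicluster
#'
#' The average squared deviation of each cell from its gene's mean within
#' the bicluster, \code{RVAR = mean((d_ij - d_ic)^2)}. High row variance
#' separates biologically interesting biclusters from trivially flat ones.
#'
#' @inheritParams dimensionMeans
#' @return Non-negative numeric scalar.
#' @examples
#' D <- matrix(c(1, 3, 2, 5), 2, 2)
#' biclusterRowVariance(D, Bicluster(1:2, 1:2))  # 0.625
#' @export
biclusterRowVariance <- function(M, B) {
  .checkBicluster(M, B)
  unname(.scoreSub(M, B@genes, B@conditions)["rvar"])
}

#' The three minimisation objectives of a bicluster
#'
#' \itemize{
#'   \item f1 = n m / Size(B): inverse relative size (1 for the full matrix);
#'   \item f2 = MSR(B) / delta: residue scaled by the homogeneity threshold;
#'   \item f3 = 1 / RVAR(B): inverse row variance, replaced by a large finite
#'     penalty when the bicluster is flat (RVAR ~ 0) so that dominance
#'     comparisons stay well-defined.
#' }
#'
#' @inheritParams dimensionMeans
#' @param delta homogeneity threshold, > 0.
#' @param rvarPenalty finite value returned as f3 when RVAR <= 1e-12.
#' @return Numeric vector c(f1, f2, f3).
#' @examples
#' D <- matrix(c(1, 3, 2, 5), 2, 2)
#' biclusterFitness(D, Bicluster(1:2, 1:2), delta = 1)  # c(1, 0.0625, 1.6)
#' @export
biclusterFitness <- function(M, B, delta, rvarPenalty = 1e12) {
  .checkBicluster(M, B)
  if (!is.finite(delta) || delta <= 0) stop("delta must be finite and > 0")
  s <- .scoreSub(M, B@genes, B@conditions)
  f1 <- (nrow(M) * ncol(M)) / (length(B@genes) * length(B@conditions))
  f2 <- s[["msr"]] / delta
  f3 <- if (s[["rvar"]] <= 1e-12) rvarPenalty else 1 / s[["rvar"]]
  c(f1 = f1, f2 = f2, f3 = f3)
}

#' Summarise biclusters as a data.frame
#'
#' One row per bicluster with the columns Genes, Conditions, Residue and
#' RowVariance (gene/condition counts, MSR, RVAR) plus Size.
#'
#' @param M numeric expression matrix.
#' @param biclusters list of [Bicluster-class].
#' @return data.frame.
#' @export
biclusterTable <- function(M, biclusters) {
  rows <- lapply(biclusters, function(B) {
    s <- .scoreSub(M, B@genes, B@conditions)
    data.frame(Genes = length(B@genes), Conditions = length(B@conditions),
               Size = biclusterSize(B), Residue = s[["msr"]],
               RowVariance = s[["rvar"]])
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(Genes = integer(), Conditions = integer(),
                                      Size = integer(), Residue = numeric(),
                                      RowVariance = numeric())
  out
}

#' Serialise biclusters to JSON
#'
#' One record per bicluster: gene_ids, condition_ids, msr, row_variance,
#' size. Labels come from the matrix dimnames.
#'
#' @inheritParams biclusterTable
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBiclustersJSON <- function(M, biclusters, path) {
  recs <- lapply(biclusters, function(B) {
    s <- .scoreSub(M, B@genes, B@conditions)
    list(gene_ids = rownames(M)[B@genes],
         condition_ids = colnames(M)[B@conditions],
         gene_indices = B@genes, condition_indices = B@conditions,
         msr = s[["msr"]], row_variance = s[["rvar"]],
         size = biclusterSize(B))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read biclusters from the JSON produced by [writeBiclustersJSON()]
#'
#' @param path JSON file.
#' @return list of [Bicluster-class].
#' @export
readBiclustersJSON <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r)
    Bicluster(unlist(r$gene_indices), unlist(r$condition_indices)))
}
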