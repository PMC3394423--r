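#' Read a tab-separated expression matrix
#'
#' Expects a header row of condition identifiers and a first column of gene
#' identifiers; all remaining cells numeric. Missing values (cells equal to
#' \code{missingSentinel}) are kept as \code{NA} and must be imputed with
#' [imputeMissing()] before running the optimiser.
#'
#' @param path path to the TSV file.
#' @param missingSentinel token(s) marking a missing value (default "NA").
#' @return A numeric matrix with gene ids as rownames and condition ids as
#'   colnames; missing cells are \code{NA}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2", "g1\t1\t2", "g2\t3\t5"), tf)
#' readExpressionMatrix(tf)
#' @export
readExpressionMatrix <- function(path, missingSentinel = "NA") {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("matrix must have at least 2 gene rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  m <- length(header) - 1L
  if (m < 2L) stop("matrix must have at least 2 condition columns")
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != m + 1L))
    stop(sprintf("ragged row(s) at line(s) %s: expected %d fields",
                 paste(which(widths != m + 1L) + 1L, collapse = ", "), m + 1L))
  geneIds <- vapply(body, `[[`, character(1), 1L)
  condIds <- header[-1L]
  if (anyDuplicated(geneIds)) stop("duplicate gene identifiers")
  if (anyDuplicated(condIds)) stop("duplicate condition identifiers")
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  cells[cells %in% missingSentinel] <- NA_character_
  vals <- suppressWarnings(as.numeric(cells))
  bad <- is.na(vals) & !is.na(cells)
  if (any(bad))
    stop("non-numeric cell(s): ", paste(utils::head(cells[bad], 3), collapse = ", "))
  M <- matrix(vals, nrow = length(geneIds), ncol = m, byrow = TRUE,
              dimnames = list(geneIds, condIds))
  M
}

#' Write an expression matrix as TSV
#'
#' @param M numeric matrix with dimnames.
#' @param path output file.
#' @param missingSentinel token written for \code{NA} cells.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(M, path, missingSentinel = "NA") {
  stopIfNotMatrix(M)
  df <- data.frame(gene = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = missingSentinel)
  invisible(path)
}

#' Impute missing expression values with uniform draws
#'
#' Every \code{NA} cell is replaced by an independent draw from
#' Uniform(low, high); all other cells are untouched. The published
#' preprocessing uses [0, 800] for yeast-style data (even though the data lie
#' in [0, 600] — the imputation range deliberately follows the original
#' protocol) and [-800, 800] for human B-cell-style data; both are exposed,
#' not hard-coded, because the random fill demonstrably influences which
#' biclusters are discovered.
#'
#' @param M numeric matrix, possibly with \code{NA} cells.
#' @param low,high imputation range, \code{low < high}.
#' @param seed optional integer; when given the imputation is reproducible
#'   and the caller's RNG state is left untouched.
#' @return The matrix with all cells finite.
#' @examples
#' M <- matrix(c(1, NA, 3, 4), 2, 2, dimnames = list(c("g1","g2"), c("c1","c2")))
#' imputeMissing(M, 0, 800, seed = 1)
#' @export
imputeMissing <- function(M, low = 0, high = 800, seed = NULL) {
  stopIfNotMatrix(M)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("imputation range requires low < high")
  miss <- which(is.na(M))
  if (length(miss) == 0L) return(M)
  M[miss] <- withSeed(seed, stats::runif(length(miss), low, high))
  M
}

#' Generate a synthetic expression matrix with planted biclusters
#'
#' Background cells are drawn i.i.d. from \code{background}; each plant then
#' overwrites its submatrix (overlapping plants: last writer wins). Plant
#' patterns: constant (\code{mu + noise}), additive
#' (\code{mu + a_i + b_j + noise}, which has zero mean squared residue when
#' noise-free), shifted (\code{mu + a_i + noise}). The result is a pure
#' function of the arguments including \code{seed}.
#'
#' @param n,m matrix dimensions (genes x conditions).
#' @param background list: \code{dist} ("normal" or "uniform") plus
#'   \code{mean}/\code{sd} or \code{min}/\code{max}.
#' @param plants list of [PlantedBicluster-class] objects.
#' @param seed integer seed.
#' @return list with \code{matrix} (dimnames g1..gn / c1..cm) and
#'   \code{plants} (the ground truth, unchanged).
#' @examples
#' p <- plantedBicluster(1:4, 1:3, "additive", noiseSd = 0)
#' s <- generateSyntheticMatrix(20, 8, plants = list(p), seed = 1)
#' biclusterMSR(s$matrix, p)  # 0 up to machine precision
#' @export
generateSyntheticMatrix <- function(n, m,
                                    background = list(dist = "normal",
                                                      mean = 0, sd = 1),
                                    plants = list(), seed = 1L) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 2L || m < 2L) stop("need n >= 2 and m >= 2")
  for (p in plants) {
    if (!is(p, "PlantedBicluster")) stop("plants must be PlantedBicluster objects")
    if (max(p@genes) > n || max(p@conditions) > m)
      stop("plant exceeds matrix bounds")
  }
  withSeed(seed, {
    vals <- switch(background$dist %||% "normal",
      normal = stats::rnorm(n * m, background$mean %||% 0, background$sd %||% 1),
      uniform = stats::runif(n * m, background$min %||% 0, background$max %||% 1),
      stop("unknown background dist: ", background$dist))
    M <- matrix(vals, n, m,
                dimnames = list(paste0("g", seq_len(n)), paste0("c", seq_len(m))))
    for (p in plants) {
      gi <- p@genes; ci <- p@conditions
      nr <- length(gi); nc <- length(ci)
      block <- matrix(p@mu, nr, nc)
      if (p@pattern %in% c("additive", "shifted"))
        block <- block + stats::rnorm(nr, 0, p@rowEffectSd)
      if (p@pattern == "additive")
        block <- block + rep(stats::rnorm(nc, 0, p@colEffectSd), each = nr)
      if (p@noiseSd > 0)
        block <- block + stats::rnorm(nr * nc, 0, p@noiseSd)
      M[gi, ci] <- block
    }
    list(matrix = M, plants = plants)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The standard planted-bicluster benchmark instance
#'
#' A 200 x 30 matrix with N(0, 1) background and one additive 40 x 10 plant
#' (row effects sd 1, column effects sd 2, cell noise sd 0.5 — half the
#' background sd). This is the instance the package's recovery tests and the
#' acceptance script run on; \code{delta = 1} is a generous homogeneity
#' threshold for it (about four times the plant's expected residue).
#'
#' @param seed integer seed.
#' @param noiseSd plant noise sd (default 0.5).
#' @return As [generateSyntheticMatrix()], plus \code{delta}.
#' @export
syntheticBenchmark <- function(seed = 1L, noiseSd = 0.5) {
  plant <- plantedBicluster(1:40, 1:10, pattern = "additive",
                            noiseSd = noiseSd, mu = 0,
                            rowEffectSd = 1, colEffectSd = 2)
  out <- generateSyntheticMatrix(200, 30, plants = list(plant), seed = seed)
  out$delta <- 1
  out
}

#' Write a synthetic fixture: TSV matrix plus JSON ground truth
#'
#' @param synth result of [generateSyntheticMatrix()].
#' @param matrixPath,truthPath output paths.
#' @return invisible list of the two paths.
#' @export
writeSyntheticFixture <- function(synth, matrixPath, truthPath) {
  writeExpressionMatrix(synth$matrix, matrixPath)
  truth <- lapply(synth$plants, function(p) list(
    genes = rownames(synth$matrix)[p@genes],
    conditions = colnames(synth$matrix)[p@conditions],
    gene_indices = p@genes, condition_indices = p@conditions,
    pattern = p@pattern, noise_sd = p@noiseSd))
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA)
  invisible(list(matrix = matrixPath, truth = truthPath))
}

#' Read a planted-bicluster ground-truth sidecar
#'
#' @param path JSON file written by [writeSyntheticFixture()].
#' @return list of [Bicluster-class] objects (index-based).
#' @export
readTruth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(truth)) truth <- split(truth, seq_len(nrow(truth)))
  lapply(truth, function(t)
    Bicluster(unlist(t$gene_indices), unlist(t$condition_indices)))
}
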