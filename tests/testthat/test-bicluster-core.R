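D22 <- matrix(c(1, 3, 2, 5), 2, 2)   # columns (1,3) and (2,5)

test_that("binary encoding decodes to the intended gene/condition sets", {
  # 2 gene bits and 3 condition bits set -> a 2 x 3 bicluster of size 6
  bits <- c(1, 1, 0, 0, 0, 1, 1, 1, 0)
  B <- decodeBicluster(bits, n = 5, m = 4)
  expect_identical(geneIndices(B), 1:2)
  expect_identical(conditionIndices(B), 1:3)
  expect_equal(biclusterSize(B), 6)

  full <- decodeBicluster(rep(TRUE, 9), n = 5, m = 4)
  expect_equal(biclusterSize(full), 20)

  expect_error(decodeBicluster(c(1, 0, 1), n = 5, m = 4), "length")
  expect_error(decodeBicluster(rep(0, 9), n = 5, m = 4), "degenerate")
})

test_that("encode and decode are mutually inverse", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:30, 1); m <- sample(2:12, 1)
    idx <- randomBiclusterIdx(n, m)
    B <- Bicluster(idx$g, idx$c)
    bits <- encodeBicluster(B, n = n, m = m)
    expect_length(bits, n + m)
    B2 <- decodeBicluster(bits, n, m)
    expect_identical(geneIndices(B2), geneIndices(B))
    expect_identical(conditionIndices(B2), conditionIndices(B))

    raw <- runif(n + m) < 0.5
    raw[sample(n, 1)] <- TRUE; raw[n + sample(m, 1)] <- TRUE
    expect_identical(encodeBicluster(decodeBicluster(raw, n, m), n = n, m = m),
                     raw)
  }
  # low-level interface tolerates an empty condition section
  bits <- encodeBicluster(c(1L, 2L), integer(0), n = 5, m = 4)
  expect_identical(bits[6:9], rep(FALSE, 4))
  expect_error(encodeBicluster(c(1L, 9L), 1L, n = 5, m = 4), "out of range")
})

test_that("dimension means match their defining formulas", {
  got <- dimensionMeans(D22, Bicluster(1:2, 1:2))
  expect_equal(unname(got$gene), c(1.5, 4))
  expect_equal(unname(got$condition), c(2, 3.5))
  expect_equal(got$overall, 2.75)

  Cst <- matrix(7, 4, 3)
  gc <- dimensionMeans(Cst, Bicluster(1:3, 1:2))
  expect_true(all(unlist(gc) == 7))

  one <- dimensionMeans(D22, Bicluster(2L, 1L))
  expect_equal(unname(unlist(one)), c(3, 3, 3))
})

test_that("mean squared residue matches hand calculation and vanishes on additive patterns", {
  expect_equal(biclusterMSR(D22, Bicluster(1:2, 1:2)), 0.0625)

  set.seed(7)
  A <- outer(rnorm(8), rep(1, 6)) + outer(rep(1, 8), rnorm(6))  # a_i + b_j
  expect_lt(biclusterMSR(A, Bicluster(1:8, 1:6)), 1e-18)

  M <- matrix(rnorm(60), 10, 6)
  expect_equal(biclusterMSR(M, Bicluster(3L, 1:6)), 0)  # single row
  expect_equal(biclusterMSR(M, Bicluster(1:10, 4L)), 0) # single column
})

test_that("residue is invariant under row/column shifts and matches the naive oracle", {
  set.seed(19)
  for (rep in 1:30) {
    M <- matrix(rnorm(100), 10, 10)
    idx <- randomBiclusterIdx(10, 10)
    B <- Bicluster(idx$g, idx$c)
    expect_lt(abs(biclusterMSR(M, B) - naiveMSR(M, idx$g, idx$c)), 1e-9)
    expect_lt(abs(biclusterRowVariance(M, B) - naiveRVAR(M, idx$g, idx$c)),
              1e-9)
    expect_gte(biclusterMSR(M, B), 0)
    expect_gte(biclusterRowVariance(M, B), 0)

    M2 <- M; M2[idx$g[1], ] <- M2[idx$g[1], ] + 5       # shift a full row
    expect_equal(biclusterMSR(M2, B), biclusterMSR(M, B), tolerance = 1e-9)
    M3 <- M; M3[, idx$c[1]] <- M3[, idx$c[1]] - 3       # shift a full column
    expect_equal(biclusterMSR(M3, B), biclusterMSR(M, B), tolerance = 1e-9)
    # row variance follows the row mean, so a row shift leaves it unchanged
    expect_equal(biclusterRowVariance(M2, B), biclusterRowVariance(M, B),
                 tolerance = 1e-9)
  }
})

test_that("row variance matches hand calculation and is zero for constant rows", {
  expect_equal(biclusterRowVariance(D22, Bicluster(1:2, 1:2)), 0.625)
  Flat <- matrix(rep(c(1, 2, 3), each = 4), 3, 4, byrow = TRUE)
  expect_equal(biclusterRowVariance(Flat, Bicluster(1:3, 1:4)), 0)
})

test_that("the three objectives follow their definitions, with the flat-bicluster guard", {
  f <- biclusterFitness(D22, Bicluster(1:2, 1:2), delta = 1)
  expect_equal(unname(f), c(1, 0.0625, 1.6))

  f2 <- biclusterFitness(D22, Bicluster(1:2, 1:2), delta = 4)
  expect_equal(unname(f2[2]), 0.0625 / 4)

  Flat <- matrix(5, 4, 4)
  ff <- biclusterFitness(Flat, Bicluster(1:2, 1:3), delta = 1)
  expect_equal(unname(ff[3]), 1e12)
  ffp <- biclusterFitness(Flat, Bicluster(1:2, 1:3), delta = 1,
                          rvarPenalty = 99)
  expect_equal(unname(ffp[3]), 99)

  expect_error(biclusterFitness(D22, Bicluster(1L, 1L), delta = 0), "delta")
})

test_that("the inverse-size objective is minimised exactly by the full matrix", {
  set.seed(3)
  M <- matrix(rnorm(48), 8, 6)
  expect_equal(unname(biclusterFitness(M, Bicluster(1:8, 1:6), 1)[1]), 1)
  for (rep in 1:20) {
    idx <- randomBiclusterIdx(8, 6)
    f1 <- unname(biclusterFitness(M, Bicluster(idx$g, idx$c), 1)[1])
    expect_gte(f1, 1)
    if (length(idx$g) < 8 || length(idx$c) < 6) expect_gt(f1, 1)
  }
})

test_that("bicluster summaries serialise to table and JSON and read back", {
  set.seed(5)
  M <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  bics <- list(Bicluster(1:4, 1:3), Bicluster(c(2, 7, 9), c(1, 5)))
  tab <- biclusterTable(M, bics)
  expect_identical(tab$Genes, c(4L, 3L))
  expect_identical(tab$Conditions, c(3L, 2L))
  expect_equal(tab$Residue[1], biclusterMSR(M, bics[[1]]))

  jp <- tempfile(fileext = ".json")
  writeBiclustersJSON(M, bics, jp)
  back <- readBiclustersJSON(jp)
  expect_length(back, 2L)
  expect_identical(geneIndices(back[[2]]), c(2L, 7L, 9L))
  expect_identical(conditionIndices(back[[2]]), c(1L, 5L))
})

test_that("degenerate or out-of-range biclusters are rejected by the scorers", {
  expect_error(Bicluster(integer(0), 1:2), "at least one gene")
  expect_error(Bicluster(c(1, 1), 1:2), "duplicate")
  expect_error(biclusterMSR(D22, Bicluster(1:2, 3L)), "exceed")
})
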