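tinyMatrix <- function(seed = 1, n = 40, m = 10) {
  generateSyntheticMatrix(n, m,
    plants = list(plantedBicluster(1:10, 1:4, "additive", noiseSd = 0.2)),
    seed = seed)$matrix
}

frogValid <- function(fr, n, m) {
  is.logical(fr$pos) && length(fr$pos) == n + m &&
    any(fr$pos[seq_len(n)]) && any(fr$pos[n + seq_len(m)]) &&
    all(is.finite(fr$obj))
}

test_that("the GA initialiser returns an evaluated, repaired population", {
  M <- tinyMatrix()
  cfg <- sflConfig(delta = 1, initGenerations = 5L)
  set.seed(2)
  pop <- initializePopulation(M, cfg)
  expect_length(pop, cfg@initPopSize)
  expect_true(all(vapply(pop, frogValid, logical(1), n = 40, m = 10)))

  set.seed(2)
  pop2 <- initializePopulation(M, cfg)
  expect_identical(lapply(pop, `[[`, "pos"), lapply(pop2, `[[`, "pos"))

  cfg0 <- sflConfig(delta = 1, initGenerations = 0L, nFrogs = 17L)
  set.seed(3)
  rnd <- initializePopulation(M, cfg0)
  expect_length(rnd, 17L)
  expect_true(all(vapply(rnd, frogValid, logical(1), n = 40, m = 10)))
})

test_that("memeplex dealing is round-robin over the quality ranking", {
  set.seed(7)
  F <- matrix(runif(36), 12, 3)
  plex <- partitionMemeplexes(F, 3L)
  expect_length(plex, 3L)
  expect_identical(lengths(plex), rep(4L, 3))
  expect_setequal(unlist(plex), 1:12)

  F60 <- matrix(runif(180), 60, 3)
  plex6 <- partitionMemeplexes(F60, 6L)
  expect_identical(lengths(plex6), rep(10L, 6))

  # one memeplex reproduces the global ranking; ranks are dealt in order
  one <- partitionMemeplexes(F, 1L)[[1]]
  expect_identical(sort(one), 1:12)
  expect_identical(unlist(lapply(1:4, function(r)
    vapply(plex, `[`, integer(1), r))), one)

  expect_error(partitionMemeplexes(F, 13L), "fewer frogs")
})

test_that("velocity updates vanish at consensus and respect the clamp", {
  cfg <- sflConfig(delta = 1)
  x <- c(TRUE, FALSE, TRUE, FALSE)
  v <- velocityUpdate(rep(0, 4), x, x, x, x, cfg, omega = 0.9)
  expect_identical(v, rep(0, 4))

  set.seed(13)
  for (rep in 1:50) {
    vel <- runif(6, -10, 10)
    pos <- runif(6) < 0.5
    v2 <- velocityUpdate(vel, pos, runif(6) < 0.5, runif(6) < 0.5,
                         runif(6) < 0.5, cfg)
    expect_true(all(abs(v2) <= cfg@vMax + 1e-12))
  }
  expect_error(velocityUpdate(rep(0, 3), x, x, x, x, cfg), "length")
})

test_that("a unit attraction step stays inside its closed-form bounds", {
  # one bit, omega = 1, xi = 1, v = 0, x = 0, all guides 1:
  # v' = c1 r1 + k mu1 c2 r2 + mu2 c3 r3 with k = +/-1, so v' in (-1, 5]
  cfg <- sflConfig(delta = 1, xi = 1, omegaStart = 1)
  set.seed(19)
  vs <- replicate(500, velocityUpdate(0, FALSE, TRUE, TRUE, TRUE, cfg,
                                      omega = 1))
  expect_true(all(vs > -1 & vs <= 5))
  expect_gt(max(vs), 2)    # the k = +1 branch is exercised
  expect_lt(min(vs), 0)    # and the k = -1 branch too
})

test_that("position thresholding is inclusive at zero", {
  expect_identical(positionUpdate(c(FALSE, FALSE, TRUE, TRUE),
                                  c(0, -0.1, 0.3, -1.5)),
                   c(TRUE, FALSE, TRUE, FALSE))
  expect_error(positionUpdate(c(TRUE, FALSE), 0), "mismatch")
})

test_that("worst-frog improvement always yields a valid memeplex", {
  M <- tinyMatrix()
  cfg <- sflConfig(delta = 1)
  set.seed(23)
  arch <- newEpsArchive(cfg@epsilon, 40L, 10L)
  frogs <- initializePopulation(M, sflConfig(delta = 1, initGenerations = 0L,
                                             nFrogs = 8L))
  for (fr in frogs) arch <- archiveInsert(arch, fr$obj, fr$pos)
  for (rep in 1:20) {
    frogs <- improveWorstFrog(frogs, M, cfg, arch)
    expect_length(frogs, 8L)
    expect_true(all(vapply(frogs, frogValid, logical(1), n = 40, m = 10)))
  }
})

test_that("with only the random-replacement step the worst frog is always replaced", {
  M <- tinyMatrix()
  cfg4 <- sflConfig(delta = 1, steps = 4L, nMemeplexes = 2L)
  set.seed(29)
  frogs <- initializePopulation(M, sflConfig(delta = 1, initGenerations = 0L,
                                             nFrogs = 5L, nMemeplexes = 2L))
  arch <- newEpsArchive(cfg4@epsilon, 40L, 10L)
  ord <- frogbic:::.rankOrder(frogbic:::.objMatrix(frogs))
  worst <- ord[length(ord)]
  before <- frogs[[worst]]$pos
  out <- improveWorstFrog(frogs, M, cfg4, arch)
  expect_false(identical(out[[worst]]$pos, before))
  # the other frogs are untouched
  for (i in setdiff(seq_along(frogs), worst))
    expect_identical(out[[i]]$pos, frogs[[i]]$pos)
})

test_that("population growth respects popMax, falls back to random, and reports spawns", {
  M <- tinyMatrix()
  cfg <- sflConfig(delta = 1, growthStep = 6L, popMax = 20L, popMin = 4L)
  set.seed(31)
  frogs <- initializePopulation(M, sflConfig(delta = 1, initGenerations = 0L,
                                             nFrogs = 18L))
  empty <- newEpsArchive(cfg@epsilon, 40L, 10L)
  g1 <- growPopulation(frogs, empty, M, cfg)       # empty archive: random
  expect_length(g1$frogs, 20L)                     # absorbed up to popMax
  expect_length(g1$spawned, 6L)
  expect_true(all(vapply(g1$spawned, frogValid, logical(1), 40, 10)))

  full <- g1$frogs
  g2 <- growPopulation(full, empty, M, cfg)        # at popMax: unchanged
  expect_identical(g2$frogs, full)
  expect_length(g2$spawned, 0L)

  arch <- empty
  for (fr in frogs) arch <- archiveInsert(arch, fr$obj, fr$pos)
  g3 <- growPopulation(frogs[1:10], arch, M, cfg)
  expect_length(g3$frogs, 16L)
  expect_lte(length(g3$frogs), cfg@popMax)
})

test_that("population shrinkage keeps the floor and removes ~half the shortlist", {
  M <- tinyMatrix()
  cfg <- sflConfig(delta = 1, popMin = 4L, selectionRatio = 0.2)
  set.seed(37)
  frogs <- initializePopulation(M, sflConfig(delta = 1, initGenerations = 0L,
                                             nFrogs = 50L))
  arch <- newEpsArchive(cfg@epsilon, 40L, 10L)
  for (fr in frogs) arch <- archiveInsert(arch, fr$obj, fr$pos)

  atFloor <- shrinkPopulation(frogs[1:4], arch, cfg)
  expect_length(atFloor, 4L)
  expect_identical(shrinkPopulation(frogs, arch,
                                    sflConfig(delta = 1, selectionRatio = 0)),
                   frogs)

  # candidates = floor(0.2 * 50) = 10, each removed with probability 1/2
  removals <- replicate(400, 50 - length(shrinkPopulation(frogs, arch, cfg)))
  expect_true(all(removals <= 10))
  exp_mean <- 5; sdm <- sqrt(10 * 0.25) / sqrt(400)
  expect_lt(abs(mean(removals) - exp_mean), 4 * sdm + 0.05)
})

test_that("a zero-generation run archives the epsilon-filtered initial population", {
  M <- tinyMatrix()
  cfg <- sflConfig(delta = 1, nGenerations = 0L, initGenerations = 3L)
  run <- runMODPSFLB(M, cfg, seed = 5)
  set.seed(5)
  pop <- initializePopulation(M, cfg)
  arch <- newEpsArchive(cfg@epsilon, 40L, 10L)
  for (fr in pop) arch <- archiveInsert(arch, fr$obj, fr$pos)
  expect_identical(archiveObjectives(run@archive), archiveObjectives(arch))
  expect_identical(nrow(run@log), 0L)
})

test_that("runs are bit-identical under a fixed seed and bounded in population", {
  M <- tinyMatrix()
  cfg <- sflConfig(delta = 1, nGenerations = 6L, initGenerations = 3L,
                   growthStep = 10L, popMin = 10L, popMax = 60L)
  r1 <- runMODPSFLB(M, cfg, seed = 11)
  r2 <- runMODPSFLB(M, cfg, seed = 11)
  expect_identical(archiveObjectives(r1@archive), archiveObjectives(r2@archive))
  expect_identical(r1@archive@positions, r2@archive@positions)
  expect_identical(r1@log, r2@log)

  r3 <- runMODPSFLB(M, cfg, seed = 12)
  expect_false(identical(archiveObjectives(r1@archive),
                         archiveObjectives(r3@archive)))

  expect_true(all(r1@log$popSize >= cfg@popMin))
  expect_true(all(r1@log$popSize <= cfg@popMax))
  expect_true(all(vapply(archiveBiclusters(r1@archive), function(B)
    length(geneIndices(B)) >= 1 && length(conditionIndices(B)) >= 1,
    logical(1))))
})

test_that("non-finite matrices are refused before optimisation", {
  M <- tinyMatrix()
  M[3, 3] <- NA
  expect_error(runMODPSFLB(M, sflConfig(delta = 1)), "imputeMissing")
})
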