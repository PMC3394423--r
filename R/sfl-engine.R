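# ---- frog plumbing (internal) ----------------------------------------------
# A frog is a plain list: pos (logical n+m), vel (numeric n+m),
# obj (active objectives), pbPos / pbObj (personal best). Plain lists keep
# the inner loop cheap; S4 wraps only the user-facing results.

.repairPosition <- function(pos, n, m) {
  if (!any(pos[seq_len(n)])) pos[sample.int(n, 1L)] <- TRUE
  if (!any(pos[n + seq_len(m)])) pos[n + sample.int(m, 1L)] <- TRUE
  pos
}

# Random positions use heterogeneous sparsity: each frog draws its own
# gene- and condition-inclusion probabilities, so the initial swarm spans
# bicluster sizes from a handful of cells to half the matrix instead of
# clustering around 50% density.
.randomPosition <- function(n, m) {
  pg <- stats::runif(1, 0.02, 0.5)
  pc <- stats::runif(1, 0.07, 0.5)
  .repairPosition(c(stats::runif(n) < pg, stats::runif(m) < pc), n, m)
}

# active-objective evaluation of a repaired position
.evalPos <- function(M, pos, cfg) {
  n <- nrow(M); m <- ncol(M)
  gi <- which(pos[seq_len(n)])
  ci <- which(pos[n + seq_len(m)])
  s <- .scoreSub(M, gi, ci)
  f <- c((n * m) / (length(gi) * length(ci)),
         s[["msr"]] / cfg@delta,
         if (s[["rvar"]] <= 1e-12) cfg@rvarPenalty else 1 / s[["rvar"]])
  f[cfg@activeObjectives]
}

# Fresh frogs start with velocities drawn from U(-vMax/2, 0): under the
# hard threshold rule (bit on iff x + v >= 0) a zero or positive velocity
# switches every unattracted bit on, so leaps would always bloat the
# bicluster; a negative resting velocity keeps bits off unless the guides
# actively pull them on.
.newFrog <- function(pos, M, cfg) {
  pos <- .repairPosition(pos, nrow(M), ncol(M))
  obj <- .evalPos(M, pos, cfg)
  list(pos = pos, vel = stats::runif(length(pos), -cfg@vMax / 2, 0),
       obj = obj, pbPos = pos, pbObj = obj)
}

# Bit-flip mutation balanced across the two membership sections: the
# overall per-bit rate is preserved, but the expected number of flips is
# split evenly between gene bits and condition bits, so condition moves are
# proposed as often as gene moves even though m << n.
.mutateBalanced <- function(pos, n, m, rate) {
  half <- rate * (n + m) / 2
  xor(pos, c(stats::runif(n) < min(0.5, half / n),
             stats::runif(m) < min(0.5, half / m)))
}

.objMatrix <- function(frogs) {
  matrix(unlist(lapply(frogs, `[[`, "obj")), nrow = length(frogs),
         byrow = TRUE)
}

# personal-best update: replace on dominance, coin-flip on mutual
# non-dominance, keep otherwise
.updatePb <- function(frog) {
  if (dominates(frog$obj, frog$pbObj) ||
      (!dominates(frog$pbObj, frog$obj) && stats::runif(1) < 0.5)) {
    frog$pbPos <- frog$pos
    frog$pbObj <- frog$obj
  }
  frog
}

# ---- ranking ----------------------------------------------------------------

# fast non-dominated sort; returns 1-based front ranks
.ndRank <- function(F) {
  n <- nrow(F)
  if (n == 1L) return(1L)
  rank <- integer(n)
  dc <- integer(n)
  doms <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    fi <- F[i, ]
    for (j in (i + 1L):n) {
      fj <- F[j, ]
      if (all(fi <= fj) && any(fi < fj)) {
        doms[[i]] <- c(doms[[i]], j); dc[j] <- dc[j] + 1L
      } else if (all(fj <= fi) && any(fj < fi)) {
        doms[[j]] <- c(doms[[j]], i); dc[i] <- dc[i] + 1L
      }
    }
  }
  front <- which(dc == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) for (j in doms[[i]]) {
      dc[j] <- dc[j] - 1L
      if (dc[j] == 0L) nxt <- c(nxt, j)
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}

# order of rows of F from best to worst: non-domination rank ascending,
# then crowding distance (within front) descending
.rankOrder <- function(F) {
  rank <- .ndRank(F)
  crowd <- numeric(nrow(F))
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowdingDistance(F[idx, , drop = FALSE])
  }
  order(rank, -crowd)
}

# ---- exported engine operations ---------------------------------------------

#' Initialise the swarm with a small non-dominated-sorting GA
#'
#' The initial population is produced by running a compact NSGA-II-style GA
#' (binary tournament on non-domination rank and crowding distance, uniform
#' crossover, per-bit mutation, elitist truncation) with
#' \code{cfg@initPopSize} individuals (default 50) for
#' \code{cfg@initGenerations} generations (default 20). With
#' \code{initGenerations = 0} a purely random population of
#' \code{cfg@nFrogs} repaired frogs is returned instead.
#'
#' @param M numeric expression matrix.
#' @param cfg an [SFLConfig-class].
#' @return list of frogs (internal list representation), all repaired and
#'   evaluated. Deterministic given the RNG state.
#' @export
initializePopulation <- function(M, cfg) {
  n <- nrow(M); m <- ncol(M)
  if (cfg@initGenerations == 0L)
    return(lapply(seq_len(cfg@nFrogs),
                  function(i) .newFrog(.randomPosition(n, m), M, cfg)))
  N <- cfg@initPopSize
  pop <- lapply(seq_len(N), function(i) .randomPosition(n, m))
  objs <- t(vapply(pop, .evalPos, numeric(length(cfg@activeObjectives)),
                   M = M, cfg = cfg))
  pbm <- 1 / (n + m)
  for (gen in seq_len(cfg@initGenerations)) {
    ord <- .rankOrder(objs)
    pos <- integer(N); pos[ord] <- seq_len(N)   # smaller = better
    tournament <- function() {
      ij <- sample.int(N, 2L)
      if (pos[ij[1L]] <= pos[ij[2L]]) ij[1L] else ij[2L]
    }
    kids <- vector("list", N)
    for (i in seq_len(N)) {
      p1 <- pop[[tournament()]]
      if (stats::runif(1) < 0.9) {
        p2 <- pop[[tournament()]]
        mask <- stats::runif(n + m) < 0.5
        child <- ifelse(mask, p1, p2)
      } else child <- p1
      flips <- stats::runif(n + m) < pbm
      child <- xor(child, flips)
      kids[[i]] <- .repairPosition(child, n, m)
    }
    kobjs <- t(vapply(kids, .evalPos, numeric(ncol(objs)), M = M, cfg = cfg))
    allPop <- c(pop, kids)
    allObjs <- rbind(objs, kobjs)
    sel <- .rankOrder(allObjs)[seq_len(N)]
    pop <- allPop[sel]
    objs <- allObjs[sel, , drop = FALSE]
  }
  lapply(seq_len(N), function(i) {
    list(pos = pop[[i]], vel = stats::runif(n + m, -cfg@vMax / 2, 0),
         obj = objs[i, ], pbPos = pop[[i]], pbObj = objs[i, ])
  })
}

#' Deal frogs into memeplexes
#'
#' Frogs are ranked (non-domination rank, then crowding distance descending)
#' and dealt round-robin: the r-th best frog goes to memeplex
#' \code{((r - 1) mod k) + 1}, so every memeplex receives a cross-section of
#' the quality spectrum and the first-ranked member of each memeplex is its
#' best, the last its worst.
#'
#' @param x list of frogs (each carrying \code{$obj}) or a numeric objective
#'   matrix with one row per frog.
#' @param nMemeplexes number of memeplexes (<= number of frogs).
#' @return list of integer index vectors into \code{x}, each ordered best to
#'   worst.
#' @export
partitionMemeplexes <- function(x, nMemeplexes) {
  F <- if (is.matrix(x)) x else .objMatrix(x)
  if (nrow(F) < nMemeplexes)
    stop("fewer frogs than memeplexes")
  ord <- .rankOrder(F)
  lapply(seq_len(nMemeplexes), function(k) {
    ord[seq(k, length(ord), by = nMemeplexes)]
  })
}

#' Velocity update of the worst frog
#'
#' Per bit d, with fresh uniform r1, r2, r3 and a direction k drawn once per
#' update uniformly from \{+1, -1\}:
#' \deqn{v' = \xi(\omega v + c_1 r_1 (Pb_d - x_d) + k \mu_1 c_2 r_2 (gb_d -
#' x_d) + \mu_2 c_3 r_3 (XB_d - x_d))}
#' clamped to \code{[-vMax, vMax]}. Pb is the frog's personal best, XB the
#' memeplex best, gb the global guide drawn from the archive.
#'
#' @param vel current velocity vector.
#' @param pos,pb,xb,gb logical position vectors of equal length.
#' @param cfg an [SFLConfig-class].
#' @param omega inertia weight for this generation.
#' @return numeric velocity vector.
#' @export
velocityUpdate <- function(vel, pos, pb, xb, gb, cfg, omega = cfg@omegaStart) {
  len <- length(vel)
  if (any(c(length(pos), length(pb), length(xb), length(gb)) != len))
    stop("velocity and position vectors must share one length")
  x <- as.numeric(pos)
  k <- if (stats::runif(1) < 0.5) 1 else -1
  r1 <- stats::runif(len); r2 <- stats::runif(len); r3 <- stats::runif(len)
  v <- cfg@xi * (omega * vel +
                   cfg@c1 * r1 * (as.numeric(pb) - x) +
                   k * cfg@mu1 * cfg@c2 * r2 * (as.numeric(gb) - x) +
                   cfg@mu2 * cfg@c3 * r3 * (as.numeric(xb) - x))
  clamp(v, -cfg@vMax, cfg@vMax)
}

#' Position update by hard thresholding
#'
#' Bit d of the new position is 1 iff \code{x_d + v_d >= 0} (the boundary is
#' inclusive: a zero bit with zero velocity switches on).
#'
#' @param pos logical position vector.
#' @param vel numeric velocity vector of the same length.
#' @return logical position vector.
#' @examples
#' positionUpdate(c(FALSE, FALSE, TRUE), c(0, -0.1, 0.3))  # TRUE FALSE TRUE
#' @export
positionUpdate <- function(pos, vel) {
  if (length(pos) != length(vel)) stop("position/velocity length mismatch")
  (as.numeric(pos) + vel) >= 0
}

.crossover <- function(a, b, type) {
  len <- length(a)
  if (type == "uniform") {
    mask <- stats::runif(len) < 0.5
    ifelse(mask, a, b)
  } else {
    cut <- sample.int(len - 1L, 1L)
    c(a[seq_len(cut)], b[(cut + 1L):len])
  }
}

#' Improve the worst frog of a memeplex
#'
#' The four-step sequential fallback applied to the memeplex's worst frog:
#' \enumerate{
#'   \item a velocity/position leap toward its personal best, the memeplex
#'     best and an archive guide ([velocityUpdate()], [positionUpdate()]);
#'   \item bit-flip mutation at \code{cfg@mutationRate};
#'   \item crossover with the archive guide;
#'   \item unconditional replacement by a fresh random repaired frog.
#' }
#' Steps 1-3 keep their candidate when the old position does not weakly
#' dominate it (strict improvement under a single active objective);
#' otherwise the next step runs.
#' Which steps run is controlled by \code{cfg@steps}. The personal best is
#' updated whenever a move is accepted.
#'
#' @param frogs list of frogs forming one memeplex.
#' @param M numeric expression matrix.
#' @param cfg an [SFLConfig-class].
#' @param archive the current [EpsArchive-class] (source of the guide).
#' @param omega inertia weight for this generation.
#' @param offerFn optional callback \code{function(objectives, position)};
#'   when supplied, every candidate evaluated during the improvement is
#'   reported through it (the runner uses this to keep the epsilon-Pareto
#'   archive updated during the selection operation).
#' @return The updated memeplex (same length, every frog valid).
#' @export
improveWorstFrog <- function(frogs, M, cfg, archive,
                             omega = cfg@omegaStart, offerFn = NULL) {
  n <- nrow(M); m <- ncol(M)
  ord <- .rankOrder(.objMatrix(frogs))
  worst <- ord[length(ord)]
  best <- ord[1L]
  frog <- frogs[[worst]]
  gb <- if (archiveSize(archive) > 0L) {
    g <- archive@positions[[selectLocalGuide(frog$obj, archive)]]
    if (is.null(g)) .randomPosition(n, m) else g
  } else .randomPosition(n, m)

  # A move is kept when the old position does not weakly dominate the new
  # one: dominating moves and mutually non-dominated moves pass, moves that
  # are dominated by (or identical to) the old position fall through to the
  # next step. With a single active objective this reduces to strict
  # improvement. Requiring the new position to dominate outright would
  # reject every trade-off move (any gene or condition dropped to improve
  # coherence worsens the size objective), starving the local search; the
  # archive, not the swarm, enforces Pareto monotonicity.
  accept <- function(pos, vel = NULL) {
    pos <- .repairPosition(pos, n, m)
    obj <- .evalPos(M, pos, cfg)
    if (!is.null(offerFn)) offerFn(obj, pos)
    if (!dominates(frog$obj, obj) && !all(obj == frog$obj)) {
      frog$pos <<- pos
      frog$obj <<- obj
      if (!is.null(vel)) frog$vel <<- vel
      frog <<- .updatePb(frog)
      TRUE
    } else FALSE
  }

  done <- FALSE
  if (1L %in% cfg@steps) {
    v <- velocityUpdate(frog$vel, frog$pos, frog$pbPos,
                        frogs[[best]]$pos, gb, cfg, omega)
    done <- accept(positionUpdate(frog$pos, v), vel = v)
  }
  if (!done && 2L %in% cfg@steps)
    done <- accept(.mutateBalanced(frog$pos, n, m, cfg@mutationRate))
  if (!done && 3L %in% cfg@steps)
    done <- accept(.crossover(frog$pos, gb, cfg@crossoverType))
  if (!done && 4L %in% cfg@steps) {
    frog <- .newFrog(.randomPosition(n, m), M, cfg)
    if (!is.null(offerFn)) offerFn(frog$obj, frog$pos)
  }
  frogs[[worst]] <- frog
  frogs
}

#' Spawn new frogs from the archive (population-adding strategy)
#'
#' Generates \code{cfg@growthStep} candidate frogs per generation. Each
#' candidate derives from archive parents chosen by size-4 tournament on the
#' row-variance objective (the coherent, high-variance end of the front,
#' where structured biclusters concentrate): with probability 0.7 two
#' parents are recombined uniformly, otherwise one parent is copied; the
#' result is bit-flip mutated at twice the mutation rate
#' (section-balanced). With an empty archive the candidates are purely
#' random frogs.
#'
#' The swarm absorbs candidates only up to \code{cfg@popMax}; all of them,
#' absorbed or not, are returned so the caller can offer them to the
#' epsilon-Pareto archive.
#'
#' @param frogs current swarm (list of frogs).
#' @param archive the [EpsArchive-class].
#' @param M numeric expression matrix.
#' @param cfg an [SFLConfig-class].
#' @return list with \code{frogs} (the grown swarm, size <=
#'   \code{cfg@popMax}) and \code{spawned} (every candidate generated).
#' @export
growPopulation <- function(frogs, archive, M, cfg) {
  nNew <- cfg@growthStep
  if (nNew <= 0L || length(frogs) >= cfg@popMax)
    return(list(frogs = frogs, spawned = list()))
  n <- nrow(M); m <- ncol(M)
  k <- archiveSize(archive)
  f3col <- match(3L, cfg@activeObjectives)
  pick <- function() {
    ij <- sample.int(k, min(4L, k))
    col <- if (is.na(f3col)) ncol(archive@objectives) else f3col
    ij[which.min(archive@objectives[ij, col])]
  }
  spawned <- lapply(seq_len(nNew), function(i) {
    if (k == 0L) return(.newFrog(.randomPosition(n, m), M, cfg))
    p1 <- archive@positions[[pick()]]
    if (is.null(p1)) p1 <- .randomPosition(n, m)
    pos <- if (k >= 2L && stats::runif(1) < 0.7) {
      p2 <- archive@positions[[pick()]]
      if (is.null(p2)) p2 <- .randomPosition(n, m)
      mask <- stats::runif(n + m) < 0.5
      ifelse(mask, p1, p2)
    } else p1
    .newFrog(.mutateBalanced(pos, n, m, 2 * cfg@mutationRate), M, cfg)
  })
  room <- max(0L, cfg@popMax - length(frogs))
  list(frogs = c(frogs, spawned[seq_len(min(room, nNew))]),
       spawned = spawned)
}

#' Shrink the swarm by removing sigma-redundant frogs
#'
#' Each frog's distance (in sigma space) to its own archive guide is
#' computed; frogs are ranked by that distance, farthest first, and the top
#' \code{selectionRatio} fraction are each removed independently with
#' probability 0.5 — a stochastic allocation that trims redundancy while
#' preserving diversity. The population never drops below \code{cfg@popMin}.
#' With an empty archive or zero ratio the swarm is returned unchanged.
#'
#' @inheritParams growPopulation
#' @return The (possibly) reduced swarm.
#' @export
shrinkPopulation <- function(frogs, archive, cfg) {
  N <- length(frogs)
  if (N <= cfg@popMin || cfg@selectionRatio <= 0 || archiveSize(archive) == 0L)
    return(frogs)
  q <- floor(cfg@selectionRatio * N)
  if (q < 1L) return(frogs)
  d <- vapply(frogs, function(fr) {
    gi <- selectLocalGuide(fr$obj, archive)
    gobj <- archive@objectives[gi, ]
    if (length(fr$obj) == 1L) abs(fr$obj - gobj)
    else sqrt(sum((sigmaValue(fr$obj) - sigmaValue(gobj))^2))
  }, numeric(1))
  cand <- order(d, decreasing = TRUE)[seq_len(q)]
  coin <- stats::runif(q) < 0.5
  drop <- integer(0)
  for (i in seq_len(q)) {
    if (coin[i] && (N - length(drop) - 1L) >= cfg@popMin)
      drop <- c(drop, cand[i])
  }
  if (length(drop)) frogs[-drop] else frogs
}

#' Run the multi-objective dynamic-population shuffled frog-leaping search
#'
#' The full optimiser: a GA-seeded swarm evolves over
#' \code{cfg@nGenerations} shuffling generations. Each generation the swarm
#' (i) grows into sparse archive regions, (ii) is dealt into memeplexes,
#' (iii) runs \code{cfg@cyclesPerMemeplex} worst-frog improvement cycles per
#' memeplex, (iv) is recombined, offered to the epsilon-dominance archive,
#' and (v) shrunk by sigma redundancy. The archive is the result: the
#' epsilon-Pareto set of biclusters found.
#'
#' @param M numeric expression matrix (all cells finite; impute first).
#' @param cfg an [SFLConfig-class].
#' @param seed integer seed; the whole run is a deterministic function of
#'   (M, cfg, seed).
#' @param trace record every objective vector offered to the archive (for
#'   replay checks); off by default.
#' @param verbose print a line per generation.
#' @return An [SFLRun-class] holding the archive, the per-generation log and
#'   the configuration.
#' @examples
#' \donttest{
#' s <- syntheticBenchmark(seed = 1)
#' cfg <- sflConfig(delta = s$delta, nGenerations = 5)
#' run <- runMODPSFLB(s$matrix, cfg, seed = 1)
#' run
#' }
#' @export
runMODPSFLB <- function(M, cfg = sflConfig(), seed = 1L, trace = FALSE,
                        verbose = FALSE) {
  stopIfNotMatrix(M)
  if (any(!is.finite(M)))
    stop("matrix contains non-finite cells; run imputeMissing() first")
  validObject(cfg)
  set.seed(seed)
  n <- nrow(M); m <- ncol(M)
  nobj <- length(cfg@activeObjectives)
  archive <- newEpsArchive(rep_len(cfg@epsilon, 3L)[cfg@activeObjectives],
                           n = n, m = m)
  offered <- if (trace) vector("list", 0L) else NULL

  offerOne <- function(obj, pos) {
    archive <<- archiveInsert(archive, obj, pos)
    if (trace) offered[[length(offered) + 1L]] <<- obj
  }
  offer <- function(frogs) {
    for (fr in frogs) offerOne(fr$obj, fr$pos)
  }

  frogs <- initializePopulation(M, cfg)
  offer(frogs)

  G <- cfg@nGenerations
  logRows <- vector("list", G)
  for (gen in seq_len(G)) {
    omega <- cfg@omegaStart +
      (cfg@omegaEnd - cfg@omegaStart) * (gen - 1) / max(1L, G - 1L)
    grown <- growPopulation(frogs, archive, M, cfg)
    frogs <- grown$frogs
    offer(grown$spawned)
    plexes <- partitionMemeplexes(frogs, cfg@nMemeplexes)
    for (p in plexes) {
      mf <- frogs[p]
      for (cyc in seq_len(cfg@cyclesPerMemeplex))
        mf <- improveWorstFrog(mf, M, cfg, archive, omega,
                               offerFn = offerOne)
      frogs[p] <- mf
    }
    offer(frogs)
    frogs <- shrinkPopulation(frogs, archive, cfg)
    bests <- apply(archive@objectives, 2, min)
    logRows[[gen]] <- data.frame(generation = gen,
                                 popSize = length(frogs),
                                 archiveSize = archiveSize(archive),
                                 t(stats::setNames(bests,
                                     paste0("bestF", cfg@activeObjectives))))
    if (verbose)
      message(sprintf("gen %d: pop %d, archive %d", gen, length(frogs),
                      archiveSize(archive)))
  }
  log <- if (G > 0) do.call(rbind, logRows) else
    data.frame(generation = integer(), popSize = integer(),
               archiveSize = integer())
  tr <- if (trace && length(offered))
    matrix(unlist(offered), ncol = nobj, byrow = TRUE)
  else matrix(numeric(0), 0L, nobj)
  new("SFLRun", archive = archive, log = log, config = cfg,
      seed = as.integer(seed), dim = c(n, m), trace = tr)
}
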