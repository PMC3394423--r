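#' @import methods
NULL

#' Bicluster: a gene subset crossed with a condition subset
#'
#' A bicluster is a submatrix of an expression matrix, identified by the
#' (1-based) row indices of its genes and column indices of its conditions.
#' Coherence statistics (mean squared residue, row variance) are computed
#' against a matrix with [biclusterMSR()] and [biclusterRowVariance()].
#'
#' @slot genes integer vector of gene (row) indices, duplicate-free, >= 1.
#' @slot conditions integer vector of condition (column) indices,
#'   duplicate-free, >= 1.
#'
#' @seealso [Bicluster()], [decodeBicluster()], [encodeBicluster()]
#' @exportClass Bicluster
setClass("Bicluster",
  representation(genes = "integer", conditions = "integer"))

setValidity("Bicluster", function(object) {
  msgs <- character()
  if (length(object@genes) < 1L) msgs <- c(msgs, "at least one gene index required")
  if (length(object@conditions) < 1L) msgs <- c(msgs, "at least one condition index required")
  if (anyDuplicated(object@genes)) msgs <- c(msgs, "duplicate gene indices")
  if (anyDuplicated(object@conditions)) msgs <- c(msgs, "duplicate condition indices")
  if (length(object@genes) && any(object@genes < 1L)) msgs <- c(msgs, "gene indices must be >= 1")
  if (length(object@conditions) && any(object@conditions < 1L)) msgs <- c(msgs, "condition indices must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Bicluster
#'
#' @param genes integer vector of gene (row) indices.
#' @param conditions integer vector of condition (column) indices.
#' @return A [Bicluster-class] object.
#' @examples
#' Bicluster(c(1, 3), c(2, 4, 5))
#' @export
Bicluster <- function(genes, conditions) {
  new("Bicluster", genes = sort(as.integer(genes)),
      conditions = sort(as.integer(conditions)))
}

#' Planted bicluster: ground truth for synthetic matrices
#'
#' Extends [Bicluster-class] with the generative pattern written into a
#' synthetic expression matrix, so recovery can be scored against it.
#' Patterns: \code{"constant"} (mu + noise), \code{"additive"}
#' (mu + row effect + column effect + noise; zero mean squared residue when
#' noiseSd = 0), \code{"shifted"} (mu + row effect + noise; constant rows up
#' to noise).
#'
#' @slot pattern character, one of "constant", "additive", "shifted".
#' @slot noiseSd non-negative numeric, sd of the i.i.d. Gaussian cell noise.
#' @slot mu numeric baseline of the plant.
#' @slot rowEffectSd sd of per-gene additive effects (additive/shifted).
#' @slot colEffectSd sd of per-condition additive effects (additive only).
#'
#' @seealso [plantedBicluster()], [generateSyntheticMatrix()]
#' @exportClass PlantedBicluster
setClass("PlantedBicluster", contains = "Bicluster",
  representation(pattern = "character", noiseSd = "numeric",
                 mu = "numeric", rowEffectSd = "numeric",
                 colEffectSd = "numeric"))

setValidity("PlantedBicluster", function(object) {
  msgs <- character()
  if (!object@pattern %in% c("constant", "additive", "shifted"))
    msgs <- c(msgs, "pattern must be one of constant/additive/shifted")
  if (length(object@genes) < 2L || length(object@conditions) < 2L)
    msgs <- c(msgs, "a plant needs at least 2 genes and 2 conditions")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PlantedBicluster
#'
#' @inheritParams Bicluster
#' @param pattern "constant", "additive" or "shifted".
#' @param noiseSd sd of the Gaussian noise added to every plant cell.
#' @param mu baseline expression level of the plant.
#' @param rowEffectSd sd of the per-gene effects a_i.
#' @param colEffectSd sd of the per-condition effects b_j.
#' @return A [PlantedBicluster-class] object.
#' @export
plantedBicluster <- function(genes, conditions, pattern = "additive",
                             noiseSd = 0, mu = 0,
                             rowEffectSd = 1, colEffectSd = 2) {
  new("PlantedBicluster", genes = sort(as.integer(genes)),
      conditions = sort(as.integer(conditions)),
      pattern = pattern, noiseSd = noiseSd, mu = mu,
      rowEffectSd = rowEffectSd, colEffectSd = colEffectSd)
}

#' Epsilon-dominance Pareto archive
#'
#' The bounded external archive of the optimiser. Objective space is gridded
#' into boxes of side epsilon (box index floor(f / epsilon)); the archive
#' holds at most one member per box and only mutually non-dominated members.
#' Every objective vector ever offered to the archive and rejected is
#' epsilon-dominated (additively: f <= g + epsilon componentwise) by some
#' final member.
#'
#' @slot objectives numeric matrix, one row per member.
#' @slot boxes integer matrix of box indices, conformable with objectives.
#' @slot positions list of logical membership vectors (length n + m) encoding
#'   each member's bicluster; may hold NULL rows when the archive is used on
#'   bare objective vectors.
#' @slot epsilon positive numeric vector, one box width per objective.
#' @slot n,m dimensions of the expression matrix the positions refer to.
#'
#' @seealso [newEpsArchive()], [archiveInsert()], [archiveBiclusters()]
#' @exportClass EpsArchive
setClass("EpsArchive",
  representation(objectives = "matrix", boxes = "matrix",
                 positions = "list", epsilon = "numeric",
                 n = "integer", m = "integer"))

setValidity("EpsArchive", function(object) {
  msgs <- character()
  if (any(object@epsilon <= 0)) msgs <- c(msgs, "epsilon must be positive")
  if (nrow(object@objectives) != length(object@positions))
    msgs <- c(msgs, "one position per objective row required")
  if (nrow(object@objectives) && ncol(object@objectives) != length(object@epsilon))
    msgs <- c(msgs, "objective dimension must match epsilon length")
  if (length(msgs)) msgs else TRUE
})

#' Create an empty epsilon-dominance archive
#'
#' @param epsilon positive numeric vector of per-objective box widths.
#' @param n,m dimensions of the underlying expression matrix (0 when the
#'   archive is used on bare objective vectors).
#' @return An empty [EpsArchive-class].
#' @examples
#' a <- newEpsArchive(c(0.02, 0.02, 0.02))
#' archiveSize(a)
#' @export
newEpsArchive <- function(epsilon = c(0.02, 0.02, 0.02), n = 0L, m = 0L) {
  if (any(!is.finite(epsilon)) || any(epsilon <= 0))
    stop("epsilon components must be finite and > 0")
  new("EpsArchive",
      objectives = matrix(numeric(0), 0L, length(epsilon)),
      boxes = matrix(numeric(0), 0L, length(epsilon)),
      positions = list(), epsilon = as.numeric(epsilon),
      n = as.integer(n), m = as.integer(m))
}

#' Configuration of the shuffled frog-leaping optimiser
#'
#' Holds every tunable of the search. Field-level defaults follow the
#' published parameterisation where one exists (60 frogs, 6 memeplexes, 10
#' improvement cycles per memeplex, acceleration coefficients c1 = c2 = c3 =
#' 2, influence factors mu1 = mu2 = 0.5) and standard binary-swarm practice
#' otherwise (constriction xi = 0.729, velocity clamp 4, inertia schedule
#' 0.9 -> 0.4). See [sflConfig()].
#'
#' @slot nFrogs nominal swarm size; size of the random initial population
#'   when the GA initialiser is disabled.
#' @slot nMemeplexes number of memeplexes the swarm is dealt into.
#' @slot cyclesPerMemeplex worst-frog improvement cycles between shuffles.
#' @slot nGenerations number of shuffling generations.
#' @slot delta homogeneity threshold (maximum acceptable mean squared
#'   residue) scaling the residue objective.
#' @slot epsilon per-objective box widths of the Pareto archive.
#' @slot c1,c2,c3 acceleration coefficients of the velocity update.
#' @slot mu1,mu2 influence factors of the global-best and memeplex-best terms.
#' @slot xi constriction factor.
#' @slot omegaStart,omegaEnd linear inertia-weight schedule over generations.
#' @slot vMax per-bit velocity clamp.
#' @slot mutationRate per-bit flip probability of the mutation operator.
#' @slot crossoverType "uniform" or "single-point".
#' @slot popMin,popMax hard bounds of the dynamic population size.
#' @slot selectionRatio fraction of the swarm shortlisted for removal.
#' @slot growthStep archive-derived candidates spawned per generation.
#' @slot initPopSize,initGenerations size and length of the GA initialiser.
#' @slot rvarPenalty finite penalty replacing 1/RVAR for flat biclusters.
#' @slot steps which of the four worst-frog improvement steps are active.
#' @slot activeObjectives which objectives (of f1, f2, f3) are active.
#'
#' @exportClass SFLConfig
setClass("SFLConfig",
  representation(nFrogs = "integer", nMemeplexes = "integer",
                 cyclesPerMemeplex = "integer", nGenerations = "integer",
                 delta = "numeric", epsilon = "numeric",
                 c1 = "numeric", c2 = "numeric", c3 = "numeric",
                 mu1 = "numeric", mu2 = "numeric", xi = "numeric",
                 omegaStart = "numeric", omegaEnd = "numeric",
                 vMax = "numeric", mutationRate = "numeric",
                 crossoverType = "character",
                 popMin = "integer", popMax = "integer",
                 selectionRatio = "numeric", growthStep = "integer",
                 initPopSize = "integer", initGenerations = "integer",
                 rvarPenalty = "numeric", steps = "integer",
                 activeObjectives = "integer"))

setValidity("SFLConfig", function(object) {
  msgs <- character()
  chk <- function(cond, msg) if (!cond) msgs <<- c(msgs, msg)
  chk(object@nMemeplexes >= 1L, "nMemeplexes must be >= 1")
  chk(object@nFrogs >= object@nMemeplexes, "nFrogs must be >= nMemeplexes")
  chk(object@cyclesPerMemeplex >= 1L, "cyclesPerMemeplex must be >= 1")
  chk(object@nGenerations >= 0L, "nGenerations must be >= 0")
  chk(is.finite(object@delta) && object@delta > 0, "delta must be > 0")
  chk(all(object@epsilon > 0), "epsilon components must be > 0")
  chk(object@mutationRate >= 0 && object@mutationRate <= 1,
      "mutationRate must lie in [0, 1]")
  chk(object@selectionRatio >= 0 && object@selectionRatio <= 1,
      "selectionRatio must lie in [0, 1]")
  chk(object@popMin >= 1L && object@popMax >= object@popMin,
      "population bounds need 1 <= popMin <= popMax")
  chk(object@crossoverType %in% c("uniform", "single-point"),
      "crossoverType must be 'uniform' or 'single-point'")
  chk(object@vMax > 0, "vMax must be > 0")
  chk(length(object@steps) >= 1L && all(object@steps %in% 1:4),
      "steps must be a non-empty subset of 1:4")
  chk(length(object@activeObjectives) >= 1L &&
        all(object@activeObjectives %in% 1:3),
      "activeObjectives must be a non-empty subset of 1:3")
  chk(object@growthStep >= 0L, "growthStep must be >= 0")
  chk(object@initPopSize >= 2L, "initPopSize must be >= 2")
  chk(object@initGenerations >= 0L, "initGenerations must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Build an optimiser configuration
#'
#' All arguments have working defaults; \code{preset} switches the
#' homogeneity threshold delta to the published dataset presets
#' (\code{"yeast"}: delta = 300; \code{"human"}: delta = 1200).
#'
#' @param preset "none", "yeast" or "human".
#' @param nFrogs,nMemeplexes,cyclesPerMemeplex,nGenerations swarm geometry.
#' @param delta homogeneity threshold (> 0); overrides the preset.
#' @param epsilon per-objective archive box widths.
#' @param c1,c2,c3,mu1,mu2,xi,omegaStart,omegaEnd,vMax velocity-update
#'   parameters.
#' @param mutationRate,crossoverType variation operators.
#' @param popMin,popMax,selectionRatio,growthStep dynamic-population controls.
#' @param initPopSize,initGenerations GA initialiser controls.
#' @param rvarPenalty finite stand-in for 1/RVAR on flat biclusters.
#' @param steps active improvement steps (subset of 1:4).
#' @param activeObjectives active objectives (subset of 1:3).
#' @return A validated [SFLConfig-class].
#' @examples
#' cfg <- sflConfig(preset = "yeast")
#' cfg@delta
#' @export
sflConfig <- function(preset = c("none", "yeast", "human"),
                      nFrogs = 60L, nMemeplexes = 6L,
                      cyclesPerMemeplex = 10L, nGenerations = 100L,
                      delta = NULL, epsilon = c(0.02, 0.02, 0.02),
                      c1 = 2, c2 = 2, c3 = 2, mu1 = 0.5, mu2 = 0.5,
                      xi = 0.729, omegaStart = 0.9, omegaEnd = 0.4,
                      vMax = 4, mutationRate = 0.01,
                      crossoverType = c("uniform", "single-point"),
                      popMin = 40L, popMax = 120L, selectionRatio = 0.2,
                      growthStep = 120L, initPopSize = 50L,
                      initGenerations = 20L, rvarPenalty = 1e12,
                      steps = 1:4, activeObjectives = 1:3) {
  preset <- match.arg(preset)
  if (is.null(delta))
    delta <- switch(preset, none = 300, yeast = 300, human = 1200)
  crossoverType <- match.arg(crossoverType)
  new("SFLConfig",
      nFrogs = as.integer(nFrogs), nMemeplexes = as.integer(nMemeplexes),
      cyclesPerMemeplex = as.integer(cyclesPerMemeplex),
      nGenerations = as.integer(nGenerations),
      delta = as.numeric(delta), epsilon = as.numeric(epsilon),
      c1 = c1, c2 = c2, c3 = c3, mu1 = mu1, mu2 = mu2, xi = xi,
      omegaStart = omegaStart, omegaEnd = omegaEnd, vMax = vMax,
      mutationRate = mutationRate, crossoverType = crossoverType,
      popMin = as.integer(popMin), popMax = as.integer(popMax),
      selectionRatio = selectionRatio, growthStep = as.integer(growthStep),
      initPopSize = as.integer(initPopSize),
      initGenerations = as.integer(initGenerations),
      rvarPenalty = rvarPenalty, steps = as.integer(sort(unique(steps))),
      activeObjectives = as.integer(sort(unique(activeObjectives))))
}

#' Result of an optimiser run
#'
#' @slot archive the final [EpsArchive-class] of non-dominated biclusters.
#' @slot log per-generation data.frame (population size, archive size, best
#'   value of each active objective).
#' @slot config the [SFLConfig-class] used.
#' @slot seed integer seed of the run.
#' @slot dim dimensions (n genes, m conditions) of the input matrix.
#' @slot trace matrix of every objective vector offered to the archive
#'   (empty unless the run was traced).
#'
#' @seealso [runMODPSFLB()]
#' @exportClass SFLRun
setClass("SFLRun",
  representation(archive = "EpsArchive", log = "data.frame",
                 config = "SFLConfig", seed = "integer",
                 dim = "integer", trace = "matrix"))
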