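#' Pareto dominance (minimisation)
#'
#' \code{f} dominates \code{g} iff f_i <= g_i for all objectives and
#' f_j < g_j for at least one. The relation is a strict partial order.
#'
#' @param f,g numeric objective vectors of equal length.
#' @return logical scalar.
#' @examples
#' dominates(c(1, 2, 3), c(1, 2, 4))  # TRUE
#' dominates(c(1, 2), c(2, 1))        # FALSE (incomparable)
#' @export
dominates <- function(f, g) {
  if (length(f) != length(g)) stop("objective vectors differ in length")
  all(f <= g) && any(f < g)
}

#' Non-dominated subset of a set of objective vectors
#'
#' @param F numeric matrix, one objective vector per row.
#' @return integer vector of row indices not dominated by any row of F.
#' @examples
#' paretoSet(rbind(c(1, 2), c(2, 1), c(2, 2)))  # 1 2
#' @export
paretoSet <- function(F) {
  if (!is.matrix(F)) F <- rbind(F)
  if (nrow(F) == 0L) stop("empty objective set")
  n <- nrow(F)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    fi <- F[i, ]
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      if (all(F[j, ] <= fi) && any(F[j, ] < fi)) { keep[i] <- FALSE; break }
    }
  }
  which(keep)
}

#' Relaxed (epsilon) dominance
#'
#' Additive scheme (default): f eps-dominates g iff
#' \code{f_i <= g_i + epsilon_i} for all i. This is the relation the
#' box-grid archive guarantees for rejected candidates (its boxes are
#' additive, \code{floor(f / epsilon)}). The multiplicative scheme
#' \code{f_i <= (1 + epsilon_i) g_i} — the minimisation form of the
#' textbook definition — is also available; both collapse to weak dominance
#' as epsilon -> 0, and plain dominance implies either for every
#' epsilon > 0.
#'
#' @param f,g numeric objective vectors.
#' @param epsilon positive numeric vector (recycled to the objective length).
#' @param scheme "additive" or "multiplicative".
#' @return logical scalar.
#' @examples
#' epsDominates(c(1, 1), c(1.05, 1.05), 0.1)  # TRUE (and also the reverse)
#' @export
epsDominates <- function(f, g, epsilon,
                         scheme = c("additive", "multiplicative")) {
  scheme <- match.arg(scheme)
  if (length(f) != length(g)) stop("objective vectors differ in length")
  epsilon <- rep_len(epsilon, length(f))
  if (any(epsilon <= 0)) stop("epsilon components must be > 0")
  if (scheme == "additive") all(f <= g + epsilon)
  else all(f <= (1 + epsilon) * g)
}

#' NSGA-II crowding distance
#'
#' Per objective the front is sorted, boundary members get infinite
#' distance, and interior members the neighbour gap normalised by the
#' objective range; distances are summed over objectives. Singletons and
#' pairs are all-boundary, hence infinite.
#'
#' @param F numeric matrix of a (single) front, one vector per row.
#' @return numeric vector of length nrow(F).
#' @export
crowdingDistance <- function(F) {
  if (!is.matrix(F)) F <- rbind(F)
  n <- nrow(F)
  if (n == 0L) return(numeric(0))
  d <- numeric(n)
  for (j in seq_len(ncol(F))) {
    o <- order(F[, j])
    d[o[1L]] <- Inf
    d[o[n]] <- Inf
    if (n > 2L) {
      rng <- F[o[n], j] - F[o[1L], j]
      if (rng > 0) {
        mid <- o[2:(n - 1L)]
        d[mid] <- d[mid] + (F[o[3:n], j] - F[o[1:(n - 2L)], j]) / rng
      }
    }
  }
  d
}

#' Sigma value of an objective vector
#'
#' The Sigma method's direction signature: for two objectives the scalar
#' \code{(f1^2 - f2^2) / (f1^2 + f2^2)}; for three the vector
#' \code{(f1^2 - f2^2, f2^2 - f3^2, f3^2 - f1^2) / (f1^2 + f2^2 + f3^2)}.
#' Scale-invariant (sigma(k f) = sigma(f) for k > 0), undefined at the
#' origin, with every component in [-1, 1].
#'
#' @param f numeric vector of 2 or 3 objectives.
#' @return numeric vector (length 1 for 2 objectives, 3 for 3).
#' @examples
#' sigmaValue(c(1, 0))  #  1
#' sigmaValue(c(0, 1))  # -1
#' @export
sigmaValue <- function(f) {
  s2 <- sum(f^2)
  if (s2 == 0) stop("sigma value undefined for the all-zero objective vector")
  if (length(f) == 2L) (f[1]^2 - f[2]^2) / s2
  else if (length(f) == 3L)
    c(f[1]^2 - f[2]^2, f[2]^2 - f[3]^2, f[3]^2 - f[1]^2) / s2
  else stop("sigma value is defined for 2 or 3 objectives")
}

# sigma matrix (one row per member) for rows of F; 1-objective case is
# handled by the caller
.sigmaMatrix <- function(F) {
  s <- apply(F, 1L, sigmaValue)
  if (is.matrix(s)) t(s) else matrix(s, ncol = 1L)
}

#' Select the local guide from the archive by the Sigma method
#'
#' Returns the index of the archive member whose sigma value is closest (in
#' Euclidean distance) to the sigma value of \code{f}; ties are broken
#' uniformly at random from the current RNG stream. With a single active
#' objective the guide is simply the member with the smallest objective.
#'
#' @param f numeric objective vector of a frog.
#' @param archive an [EpsArchive-class] with at least one member.
#' @return integer index into the archive.
#' @export
selectLocalGuide <- function(f, archive) {
  k <- archiveSize(archive)
  if (k == 0L) stop("cannot select a guide from an empty archive")
  if (k == 1L) return(1L)
  A <- archive@objectives
  if (length(f) == 1L) {
    d <- A[, 1L]
  } else {
    sf <- sigmaValue(f)
    sA <- .sigmaMatrix(A)
    d <- sqrt(colSums((t(sA) - sf)^2))
  }
  cand <- which(d <= min(d) + 1e-15)
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}
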