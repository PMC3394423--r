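# Independent brute-force oracles, written directly from the defining
# formulas. They deliberately share no code with the package internals.

naiveMSR <- function(M, g, c) {
  dic <- sapply(g, function(i) mean(M[i, c]))
  dgj <- sapply(c, function(j) mean(M[g, j]))
  dgc <- mean(M[g, c])
  tot <- 0
  for (a in seq_along(g)) for (b in seq_along(c)) {
    r <- M[g[a], c[b]] - dic[a] - dgj[b] + dgc
    tot <- tot + r * r
  }
  tot / (length(g) * length(c))
}

naiveRVAR <- function(M, g, c) {
  dic <- sapply(g, function(i) mean(M[i, c]))
  tot <- 0
  for (a in seq_along(g)) for (b in seq_along(c)) {
    d <- M[g[a], c[b]] - dic[a]
    tot <- tot + d * d
  }
  tot / (length(g) * length(c))
}

bruteParetoSet <- function(F) {
  n <- nrow(F)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && all(F[j, ] <= F[i, ]) && any(F[j, ] < F[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# literal transcription of the textbook crowding-distance procedure
bruteCrowding <- function(F) {
  n <- nrow(F)
  d <- rep(0, n)
  for (j in seq_len(ncol(F))) {
    idx <- order(F[, j])
    d[idx[1]] <- Inf
    d[idx[n]] <- Inf
    fmin <- F[idx[1], j]
    fmax <- F[idx[n], j]
    if (n > 2 && fmax > fmin) {
      for (r in 2:(n - 1))
        d[idx[r]] <- d[idx[r]] + (F[idx[r + 1], j] - F[idx[r - 1], j]) / (fmax - fmin)
    }
  }
  d
}

bruteSigma <- function(f) {
  s <- sum(f^2)
  if (length(f) == 2) (f[1]^2 - f[2]^2) / s
  else c(f[1]^2 - f[2]^2, f[2]^2 - f[3]^2, f[3]^2 - f[1]^2) / s
}

# exhaustive distance table for guide selection
bruteGuideDistances <- function(f, A) {
  sf <- bruteSigma(f)
  apply(A, 1, function(row) sqrt(sum((bruteSigma(row) - sf)^2)))
}

# upper hypergeometric tail by direct log-space summation
tailHyper <- function(k, n, mCat, g) {
  if (k == 0) return(1)
  terms <- vapply(0:(k - 1), function(i) {
    if (i > mCat || (n - i) > (g - mCat)) return(0)
    exp(lchoose(mCat, i) + lchoose(g - mCat, n - i) - lchoose(g, n))
  }, numeric(1))
  1 - sum(terms)
}

randomBiclusterIdx <- function(n, m) {
  list(g = sort(sample.int(n, sample(2:max(2, n %/% 2), 1))),
       c = sort(sample.int(m, sample(2:max(2, m %/% 2), 1))))
}
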