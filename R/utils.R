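# internal helpers

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# coerce a 0/1/logical vector to logical with checking
asBits <- function(bits) {
  if (is.logical(bits)) return(bits)
  b <- as.numeric(bits)
  if (any(is.na(b)) || any(!b %in% c(0, 1)))
    stop("bit vector must contain only 0/1 (or logical) values")
  b == 1
}

stopIfNotMatrix <- function(M) {
  if (!is.matrix(M) || !is.numeric(M))
    stop("expression data must be a numeric matrix")
}
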