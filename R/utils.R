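# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and a stream index,
# staying inside the 32-bit integer range R requires.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code does not perturb user simulations.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

stopifnotSquareSym <- function(M, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(what, " must be a square matrix")
  if (any(abs(M - t(M)) > 1e-9))
    stop(what, " must be symmetric")
  if (any(M < 0)) stop(what, " must be non-negative")
  invisible(TRUE)
}

# Coerce Connectome/BinaryConnectome/matrix to a plain numeric matrix.
asWeightMatrix <- function(network) {
  if (is(network, "Connectome")) return(network@weights)
  if (is(network, "BinaryConnectome")) return(network@adjacency)
  if (is.matrix(network)) return(network)
  stop("expected a Connectome, BinaryConnectome or matrix")
}
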