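`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL uses (and advances) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# Gauss-Legendre nodes/weights on [a, b], cached by (n, a, b).
gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a, b) {
  key <- paste(n, a, b, sep = "|")
  got <- gl_cache[[key]]
  if (is.null(got)) {
    got <- pracma::gaussLegendre(n, a, b)
    gl_cache[[key]] <- got
  }
  got
}

log1mexp <- function(x) {
  # log(1 - exp(x)) for x <= 0
  ifelse(x > -log(2), base::log(-expm1(x)), log1p(-exp(x)))
}
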