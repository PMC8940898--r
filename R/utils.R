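# internal helpers shared across modules

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed for a named sub-stream, kept < 2^31.
childSeed <- function(seed, stream, k = 0L) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.double(seed) * 48271 + h * 2654435.0 + k * 7919) %% 2147483647
}

# column standardization with population (1/n) variance so crossprod(X)/n is
# exactly the Pearson correlation matrix
standardizeDosages <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(Xc^2) / n)
  if (any(s == 0)) {
    stop("monomorphic variant(s): ",
         paste(colnames(X)[s == 0], collapse = ", "))
  }
  sweep(Xc, 2L, s, "/")
}

symmetricRank <- function(C, tol = 1e-8) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  sum(abs(ev) > tol * max(abs(ev), .Machine$double.eps))
}

isSquareSymmetric <- function(C, tol = 1e-8) {
  is.matrix(C) && nrow(C) == ncol(C) &&
    max(abs(C - t(C))) <= tol * max(1, max(abs(C)))
}

checkFraction <- function(x, name) {
  if (!is.numeric(x) || any(x < 0 | x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name))
  }
  invisible(x)
}
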