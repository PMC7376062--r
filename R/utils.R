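#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed, keeping values in the
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

fs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "follisim_error")))
}

# FNV-1a hash of an R object's canonical serialization; used to stamp
# experiment artifacts with a configuration fingerprint (no digest dependency).
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2, xdr = TRUE)
  # drop serialization header (R version bytes vary across sessions)
  bytes <- bytes[-seq_len(14)]
  h <- 5381
  for (b in as.integer(bytes)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Uniform random unit vectors in R^3, n x 3 matrix.
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v / sqrt(rowSums(v^2))
}

# Row-normalize a matrix of vectors; zero rows are replaced with fresh random
# unit vectors (direction undefined).
normalize_rows <- function(v) {
  nrm <- sqrt(rowSums(v^2))
  bad <- nrm < 1e-300
  if (any(bad)) {
    v[bad, ] <- random_unit_vectors(sum(bad))
    nrm[bad] <- 1
  }
  v / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
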