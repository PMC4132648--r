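# Internal numerical helpers shared across modules.

# Floor applied to densities before taking logs; prevents -Inf from extreme
# outliers without affecting any realistic value.
.DENSITY_FLOOR <- 1e-300

# Row-wise log-sum-exp of a matrix, returning one value per row.
.row_logsumexp <- function(S) {
  m <- S[, 1L]
  nc <- ncol(S)
  if (nc > 1L) for (k in 2L:nc) m <- pmax(m, S[, k])
  m + log(rowSums(exp(S - m)))
}

# Row-wise cumulative sums via multiplication with an upper-triangular matrix
# of ones; avoids apply() in the likelihood hot path.
.row_cumsum <- function(M) {
  n <- ncol(M)
  U <- matrix(0, n, n)
  U[upper.tri(U, diag = TRUE)] <- 1
  M %*% U
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# seed = NULL leaves the ambient stream untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-replicate seed derived from a master seed, independent of
# the total number of replicates. Kept within the 32-bit integer range.
.substream_seed <- function(seed, b) {
  bitwAnd(bitwXor(as.integer(seed), as.integer(b) * 7919L), 2147483647L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_permutation <- function(ord, n) {
  if (length(ord) != n || !setequal(ord, seq_len(n))) {
    .stopf("'order' must be a permutation of 1..%d", n)
  }
  invisible(as.integer(ord))
}
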