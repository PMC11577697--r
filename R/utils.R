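# internal numerical helpers

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  mid <- x > 18 & x <= 33.3
  out[lo] <- log1p(exp(x[lo]))
  out[mid] <- x[mid] + exp(-x[mid])
  # x > 33.3: log1p(exp(x)) == x to double precision
  out
}

# row-wise cumulative sums of a matrix
row_cumsum <- function(m) {
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, cumsum))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetric positive-definite inverse with a helpful error
pd_solve <- function(m, context = "information matrix") {
  out <- tryCatch(chol2inv(chol((m + t(m)) / 2)), error = function(e) NULL)
  if (is.null(out)) {
    bad <- colnames(m)[which.min(abs(diag(m)))] %||% "<unnamed>"
    stop(sprintf("singular %s (smallest diagonal at parameter '%s')",
                 context, bad), call. = FALSE)
  }
  dimnames(out) <- dimnames(m)
  out
}

as_matrix_X <- function(X, p) {
  if (is.null(X)) X <- matrix(numeric(0), nrow = 0L, ncol = p)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X) && p == 1L) X <- matrix(X, ncol = 1L)
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix", call. = FALSE)
  if (ncol(X) != p)
    stop(sprintf("X has %d columns but the family declares p = %d",
                 ncol(X), p), call. = FALSE)
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  X
}
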