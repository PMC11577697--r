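# category probabilities and log-likelihood contributions for the four families

# internal: n x K matrix of linear predictors on the baseline-logit scale for
# the softmax families (sm, ac).  Baseline is the lowest category (eta[,1]=0).
#   sm: eta_k = a_k + c_k * s,  a = c(0, rev(alpha)), c = rev(phi)
#   ac: eta_k = sum_{h<k} alpha_h + (k-1) * s
softmax_eta <- function(family, params, s) {
  K <- family$K
  n <- length(s)
  if (family$name == "sm") {
    a <- c(0, rev(params$alpha))
    cc <- rev(params$phi)
  } else {
    a <- c(0, cumsum(params$alpha))
    cc <- 0:(K - 1L)
  }
  matrix(a, n, K, byrow = TRUE) + s %o% cc
}

softmax_rows <- function(eta) {
  eta <- eta - apply(eta, 1L, max)
  ex <- exp(eta)
  ex / rowSums(ex)
}

# internal probability engine; `strict` controls whether invalid cumulative
# parameters raise an error (user-facing) or return NULL (optimizer path)
probs_engine <- function(family, params, X, strict = TRUE) {
  X <- as_matrix_X(X, family$p)
  n <- nrow(X)
  if (n == 0L) stop("no observations", call. = FALSE)
  s <- if (family$p > 0L) drop(X %*% params$beta) else rep(0, n)
  K <- family$K
  pi <- switch(family$name,
    sm = ,
    ac = softmax_rows(softmax_eta(family, params, s)),
    cr = {
      pbar <- vapply(seq_len(K - 1L),
                     function(k) stats::plogis(params$alpha[k] + s),
                     numeric(n))
      pbar <- matrix(pbar, n, K - 1L)
      surv <- cbind(rep(1, n), row_cumsum_prod(pbar))  # Pr(Y > k-1)
      cbind(surv[, seq_len(K - 1L), drop = FALSE] * (1 - pbar), surv[, K])
    },
    cm = {
      if (is.unsorted(params$alpha, strictly = TRUE)) {
        if (strict)
          stop("invalid cumulative-logit parameters: intercepts must be strictly increasing",
               call. = FALSE)
        return(NULL)
      }
      gam <- vapply(seq_len(K - 1L),
                    function(k) stats::plogis(params$alpha[k] + s),
                    numeric(n))
      gam <- matrix(gam, n, K - 1L)
      pi <- cbind(gam, 1) - cbind(0, gam)
      if (any(pi <= 0)) {
        if (strict)
          stop("invalid cumulative-logit parameters: a category probability is not positive",
               call. = FALSE)
        return(NULL)
      }
      pi
    })
  pi
}

row_cumsum_prod <- function(m) {
  if (ncol(m) == 1L) return(m)
  out <- m
  for (j in 2:ncol(m)) out[, j] <- out[, j - 1L] * m[, j]
  out
}

#' Category probabilities
#'
#' Evaluates the n x K matrix of category probabilities
#' \eqn{\pi_{ik} = \Pr(Y_i = k \mid x_i)} implied by a parameter set.
#' Rows sum to one to machine precision.  For the cumulative logit family an
#' invalid parameter set (non-increasing intercepts, or a non-positive
#' implied probability) raises an error rather than being clipped.
#'
#' @param family an [ord_family()].
#' @param params an [ord_params()] consistent with `family`.
#' @param X covariate matrix (n x p).
#' @return numeric matrix, n rows and `K` columns.
#' @export
category_probs <- function(family, params, X) {
  stopifnot(inherits(family, "ord_family"), inherits(params, "ord_params"))
  if (params$family$name != family$name || params$family$K != family$K ||
      params$family$p != family$p)
    stop("params were built for a different family", call. = FALSE)
  probs_engine(family, params, X, strict = TRUE)
}

#' Per-unit log-likelihood contributions
#'
#' \eqn{\ell_i(\theta) = \ln \pi_{i, y_i}}, the multinomial log-likelihood
#' contribution of each unit.
#'
#' @inheritParams category_probs
#' @param y integer outcomes in `1..K`.
#' @return numeric vector of length n.
#' @export
loglik_contributions <- function(family, params, y, X) {
  y <- as.integer(y)
  if (any(y < 1L | y > family$K))
    stop(sprintf("y must be coded 1..%d", family$K), call. = FALSE)
  pi <- category_probs(family, params, X)
  if (nrow(pi) != length(y)) stop("length(y) must match nrow(X)", call. = FALSE)
  log(pi[cbind(seq_along(y), y)])
}

#' Re-express adjacent-category parameters as a stereotype model
#'
#' The adjacent-category logit model is a stereotype model with fixed,
#' equally spaced scores: chaining the adjacent logits between category `k`
#' and the extremes gives baseline-category logits whose slope on
#' \eqn{\beta'x} is proportional to the category rank.  Rescaled to the
#' stereotype convention (\eqn{\phi_1 = 1}, \eqn{\phi_K = 0}) this yields
#' \eqn{\phi_k = (K - k)/(K - 1)} and a stereotype slope
#' \eqn{\beta_{SM} = (K - 1)\,\beta_{AC}}.  Category probabilities of input
#' and output agree exactly.
#'
#' @param params_ac an [ord_params()] for an `"ac"` family.
#' @return an [ord_params()] for the `"sm"` family with the same `K`, `p`.
#' @export
ac_as_sm <- function(params_ac) {
  stopifnot(inherits(params_ac, "ord_params"))
  fam <- params_ac$family
  if (fam$name != "ac") stop("params_ac must be adjacent-category parameters",
                             call. = FALSE)
  K <- fam$K
  sm <- ord_family("sm", K = K, p = fam$p)
  # package SM stores eta_k = a_k + c_k beta's with a = c(0, rev(alpha_sm)),
  # c = rev(phi); the AC chain gives a_k = sum_{h<k} alpha_ac_h, c_k = (k-1)/(K-1)
  a <- cumsum(params_ac$alpha)              # a_2..a_K
  alpha_sm <- rev(a)                        # alpha_sm_j = a_{K+1-j}
  phi <- rev((0:(K - 1L)) / (K - 1L))       # phi_j = c_{K+1-j}; phi_1=1, phi_K=0
  ord_params(sm, alpha = alpha_sm, phi = phi,
             beta = (K - 1L) * params_ac$beta)
}
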