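# outcome-dependent sampling: designs, weights, and the sampled-data model

#' Outcome-dependent sampling design descriptor
#'
#' @param N_k cohort counts per outcome category.
#' @param n_k sample sizes per category (`0 < n_k <= N_k`).
#' @return object of class `ods_design` with `K`, `N_k`, `n_k`,
#'   `f_k = n_k/N_k`, `N`, `n`, and weights `w_k = 1/f_k`.
#' @export
ods_design <- function(N_k, n_k) {
  N_k <- as.numeric(N_k); n_k <- as.numeric(n_k)
  if (length(N_k) != length(n_k))
    stop("N_k and n_k must have the same length", call. = FALSE)
  if (any(n_k <= 0) || any(N_k <= 0))
    stop("category counts must be positive", call. = FALSE)
  if (any(n_k > N_k))
    stop(sprintf("undersized category: n_k > N_k for k = %s",
                 paste(which(n_k > N_k), collapse = ", ")), call. = FALSE)
  structure(list(K = length(N_k), N_k = N_k, n_k = n_k, f_k = n_k / N_k,
                 N = sum(N_k), n = sum(n_k), w_k = N_k / n_k),
            class = "ods_design")
}

#' @export
print.ods_design <- function(x, ...) {
  cat(sprintf("<ods_design> K = %d, N = %g, n = %g\n", x$K, x$N, x$n))
  print(data.frame(k = seq_len(x$K), N_k = x$N_k, n_k = x$n_k,
                   f_k = signif(x$f_k, 4), w_k = signif(x$w_k, 4)))
  invisible(x)
}

#' Draw an outcome-dependent sample from a cohort
#'
#' Samples `n_k[k]` units without replacement from each outcome category of
#' the cohort and attaches inverse sampling-fraction weights
#' \eqn{w_i = N_k / n_k} computed from the *realized* cohort category
#' counts.  Per-category weighted counts therefore reproduce the cohort
#' counts exactly.
#'
#' @param cohort an [ord_data()] with unit weights (the full cohort).
#' @param n_k per-category sample sizes, length `K` (recycled if scalar).
#' @param seed optional integer seed making the draw reproducible.
#' @return list with `sample` (an [ord_data()] carrying the weights) and
#'   `design` (an [ods_design()]).
#' @export
sample_ods <- function(cohort, n_k, seed = NULL) {
  stopifnot(inherits(cohort, "ord_data"))
  K <- cohort$K
  n_k <- rep(as.integer(n_k), length.out = K)
  N_k <- tabulate(cohort$y, K)
  if (any(N_k < n_k))
    stop(sprintf("undersized category: cohort has fewer than n_k units in category %s",
                 paste(which(N_k < n_k), collapse = ", ")), call. = FALSE)
  design <- ods_design(N_k, n_k)
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- unlist(lapply(seq_len(K), function(k) {
    pool <- which(cohort$y == k)
    if (length(pool) == n_k[k]) pool else sample(pool, n_k[k])
  }), use.names = FALSE)
  w <- design$w_k[cohort$y[idx]]
  smp <- ord_data(cohort$y[idx],
                  if (cohort$p > 0L) cohort$X[idx, , drop = FALSE] else NULL,
                  w = w, K = K)
  list(sample = smp, design = design)
}

#' Intercepts of the sampled-data model (SM and AC only)
#'
#' Under outcome-dependent sampling the conditional category probabilities
#' of sampled units follow the same stereotype or adjacent-category model as
#' the cohort, with slopes and scores unchanged and only the intercepts
#' offset by log sampling-fraction ratios (the ordinal analogue of the
#' case-control intercept shift).  For the continuation-ratio and
#' cumulative logit families no such closed form exists in general, and the
#' function errors.
#'
#' @param family an [ord_family()], `"sm"` or `"ac"`.
#' @param params cohort-model [ord_params()].
#' @param f sampling fractions per category, length `K`, all in (0, 1].
#' @return an [ord_params()] describing the sampled-data model.
#' @export
sampled_intercepts <- function(family, params, f) {
  stopifnot(inherits(family, "ord_family"), inherits(params, "ord_params"))
  f <- as.numeric(f)
  if (length(f) != family$K) stop("f must have length K", call. = FALSE)
  if (any(f <= 0)) stop("sampling fractions must be positive", call. = FALSE)
  K <- family$K
  if (family$name == "sm") {
    # baseline-category representation: a_k -> a_k + ln(f_k / f_1); in the
    # reported indexing alpha_j corresponds to a_{K+1-j}
    off <- log(f / f[1L])
    ord_params(family, alpha = params$alpha + rev(off[-1L]),
               phi = params$phi, beta = params$beta)
  } else if (family$name == "ac") {
    # adjacent logits ln(pi_{k+1}/pi_k): alpha_k -> alpha_k + ln(f_{k+1}/f_k)
    off <- log(f[-1L] / f[-K])
    ord_params(family, alpha = params$alpha + off, beta = params$beta)
  } else {
    stop(sprintf("the sampled-data model for '%s' cannot be expressed by an intercept offset",
                 family$name), call. = FALSE)
  }
}

#' Category probabilities of the sampled-data model (Bayes route)
#'
#' Applies Bayes' theorem to the cohort probabilities:
#' \eqn{\pi^s_{ik} = f_k \pi_{ik} / \sum_h f_h \pi_{ih}}.  Valid for any
#' family.  For SM/AC it agrees with
#' `category_probs(family, sampled_intercepts(...), X)` to machine
#' precision.
#'
#' @inheritParams sampled_intercepts
#' @param X covariate matrix.
#' @return n x K probability matrix.
#' @export
sampled_probs <- function(family, params, f, X) {
  f <- as.numeric(f)
  if (length(f) != family$K) stop("f must have length K", call. = FALSE)
  if (any(f <= 0)) stop("sampling fractions must be positive", call. = FALSE)
  pi <- category_probs(family, params, X)
  num <- sweep(pi, 2L, f, `*`)
  num / rowSums(num)
}

#' Continuation-ratio special case under ODS
#'
#' The continuation-ratio family admits an intercept-offset representation
#' of the sampled-data model only when all sampling fractions above the
#' first category are equal (\eqn{f_2 = \cdots = f_K}); then only the first
#' intercept is offset, by \eqn{\ln(f_2/f_1)}, and unweighted fitting
#' recovers the cohort slopes.
#'
#' @param f sampling fractions, length `K`.
#' @param tol equality tolerance.
#' @return `TRUE` iff `f[2] == ... == f[K]` within `tol`.
#' @export
cr_special_case_check <- function(f, tol = 1e-12) {
  f <- as.numeric(f)
  if (length(f) < 2L) stop("f must have length K >= 2", call. = FALSE)
  rest <- f[-1L]
  max(rest) - min(rest) <= tol * max(1, max(abs(rest)))
}
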