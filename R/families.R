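#' Ordinal regression model families
#'
#' Constructs a model-family descriptor for one of the four ordinal
#' regression families handled by svyord:
#'
#' * `"sm"` — stereotype model: baseline-category logits with estimated
#'   score parameters \eqn{\phi_k} multiplying a shared slope vector.
#' * `"ac"` — adjacent-category logit, \eqn{\ln(\pi_{k+1}/\pi_k) = \alpha_k + \beta'x}.
#' * `"cr"` — continuation-ratio logit,
#'   \eqn{\mathrm{logit}\,\Pr(Y>k \mid Y\ge k) = \alpha_k + \beta'x}.
#' * `"cm"` — cumulative logit (proportional odds),
#'   \eqn{\mathrm{logit}\,\Pr(Y\le k) = \alpha_k + \beta'x}.
#'
#' All four families are oriented so that, for AC/CR/SM, a positive slope
#' moves probability mass toward *higher* outcome categories, while for CM a
#' positive slope moves mass toward *lower* categories (the cumulative logit
#' models the low side of the scale).  These are the orientations commonly
#' produced by ordinal-regression software and the ones under which the four
#' families can be calibrated against a common latent-probit generator.
#'
#' The free parameter count is `2K - 3 + p` for the stereotype model
#' (`K - 1` intercepts, `K - 2` free scores, `p` slopes) and `K - 1 + p`
#' for the other three.
#'
#' @param name one of `"sm"`, `"ac"`, `"cr"`, `"cm"` (case-insensitive).
#' @param K number of outcome categories (integer, `K >= 2`).
#' @param p number of covariates (integer, `p >= 0`).
#' @return an object of class `ord_family`: a list with elements `name`,
#'   `K`, `p`, `npar` and `par_names`.
#' @examples
#' ord_family("sm", K = 5, p = 2)$npar  # 2*5 - 3 + 2 = 9
#' ord_family("cm", K = 3, p = 1)$par_names
#' @export
ord_family <- function(name = c("sm", "ac", "cr", "cm"), K, p) {
  name <- match.arg(tolower(name), c("sm", "ac", "cr", "cm"))
  K <- as.integer(K); p <- as.integer(p)
  if (is.na(K) || K < 2L) stop("K must be an integer >= 2", call. = FALSE)
  if (is.na(p) || p < 0L) stop("p must be an integer >= 0", call. = FALSE)
  a_names <- paste0("alpha", seq_len(K - 1L))
  b_names <- if (p > 0L) paste0("beta", seq_len(p)) else character(0)
  if (name == "sm") {
    f_names <- if (K > 2L) paste0("phi", seq(2L, K - 1L)) else character(0)
    par_names <- c(a_names, f_names, b_names)
  } else {
    par_names <- c(a_names, b_names)
  }
  structure(list(name = name, K = K, p = p,
                 npar = length(par_names), par_names = par_names),
            class = "ord_family")
}

#' @export
print.ord_family <- function(x, ...) {
  cat(sprintf("<ord_family> %s: K = %d categories, p = %d covariates, %d free parameters\n",
              toupper(x$name), x$K, x$p, x$npar))
  invisible(x)
}

#' Parameter sets for ordinal families
#'
#' Bundles intercepts, stereotype scores and slopes into a validated
#' parameter object.  For the stereotype model the full score vector
#' \eqn{\phi_1, \ldots, \phi_K} is stored, including the fixed endpoints
#' \eqn{\phi_1 = 1} and \eqn{\phi_K = 0}; only \eqn{\phi_2,\ldots,\phi_{K-1}}
#' are free parameters.  No monotonicity constraint is imposed on the scores.
#'
#' @param family an [ord_family()].
#' @param alpha numeric vector of `K - 1` intercepts.
#' @param phi full score vector of length `K` (stereotype model only).  If
#'   omitted for an SM family, equally spaced scores `(K - k)/(K - 1)` are
#'   used.  Ignored with a warning for other families.
#' @param beta numeric vector of `p` slopes (may be omitted when `p = 0`).
#' @return an object of class `ord_params`.
#' @export
ord_params <- function(family, alpha, phi = NULL, beta = NULL) {
  stopifnot(inherits(family, "ord_family"))
  K <- family$K; p <- family$p
  alpha <- as.numeric(alpha)
  if (length(alpha) != K - 1L)
    stop(sprintf("alpha must have length K - 1 = %d", K - 1L), call. = FALSE)
  if (any(!is.finite(alpha))) stop("alpha must be finite", call. = FALSE)
  beta <- as.numeric(beta %||% numeric(p))
  if (length(beta) != p)
    stop(sprintf("beta must have length p = %d", p), call. = FALSE)
  if (any(!is.finite(beta))) stop("beta must be finite", call. = FALSE)
  if (family$name == "sm") {
    if (is.null(phi)) phi <- (K - seq_len(K)) / (K - 1)
    phi <- as.numeric(phi)
    if (length(phi) != K)
      stop(sprintf("phi must be the full score vector of length K = %d", K),
           call. = FALSE)
    if (abs(phi[1L] - 1) > 1e-12 || abs(phi[K]) > 1e-12)
      stop("identifiability requires phi[1] = 1 and phi[K] = 0", call. = FALSE)
    phi[1L] <- 1; phi[K] <- 0
  } else {
    if (!is.null(phi)) warning("phi is ignored for non-stereotype families")
    phi <- NULL
  }
  structure(list(alpha = alpha, phi = phi, beta = beta, family = family),
            class = "ord_params")
}

#' @export
print.ord_params <- function(x, ...) {
  cat(sprintf("<ord_params> %s\n", toupper(x$family$name)))
  cat("  alpha:", paste(signif(x$alpha, 4), collapse = " "), "\n")
  if (!is.null(x$phi))
    cat("  phi:  ", paste(signif(x$phi, 4), collapse = " "), "\n")
  if (length(x$beta))
    cat("  beta: ", paste(signif(x$beta, 4), collapse = " "), "\n")
  invisible(x)
}

# free-parameter vector <-> ord_params
theta_pack <- function(params) {
  fam <- params$family
  th <- if (fam$name == "sm" && fam$K > 2L) {
    c(params$alpha, params$phi[seq(2L, fam$K - 1L)], params$beta)
  } else {
    c(params$alpha, params$beta)
  }
  names(th) <- fam$par_names
  th
}

theta_unpack <- function(family, theta) {
  K <- family$K; p <- family$p
  alpha <- theta[seq_len(K - 1L)]
  if (family$name == "sm") {
    phi_free <- if (K > 2L) theta[(K - 1L) + seq_len(K - 2L)] else numeric(0)
    beta <- if (p > 0L) theta[(family$npar - p + 1L):family$npar] else numeric(0)
    ord_params(family, alpha, phi = c(1, phi_free, 0), beta = beta)
  } else {
    beta <- if (p > 0L) theta[(K - 1L) + seq_len(p)] else numeric(0)
    ord_params(family, alpha, beta = beta)
  }
}

#' Observation container for ordinal model fitting
#'
#' @param y integer outcome vector coded `1..K`.
#' @param X covariate matrix with one row per unit (or `NULL` when `p = 0`).
#' @param w optional positive sampling weights (defaults to all ones).
#' @param K number of categories; inferred as `max(y)` when omitted.
#' @return an object of class `ord_data` with elements `y`, `X`, `w`, `K`,
#'   `n` and `p`.
#' @export
ord_data <- function(y, X = NULL, w = NULL, K = NULL) {
  y <- as.integer(y)
  n <- length(y)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  if (any(is.na(y))) stop("y contains missing values", call. = FALSE)
  K <- as.integer(K %||% max(y))
  if (K < 2L) stop("need at least two outcome categories", call. = FALSE)
  if (any(y < 1L | y > K))
    stop(sprintf("y must be coded 1..%d", K), call. = FALSE)
  p <- if (is.null(X)) 0L else ncol(as.matrix(X))
  X <- as_matrix_X(X, p)
  if (nrow(X) != n && p > 0L) stop("nrow(X) must equal length(y)", call. = FALSE)
  w <- as.numeric(w %||% rep(1, n))
  if (length(w) != n) stop("weights must have length n", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be strictly positive and finite", call. = FALSE)
  structure(list(y = y, X = X, w = w, K = K, n = n, p = p),
            class = "ord_data")
}

#' @export
print.ord_data <- function(x, ...) {
  cat(sprintf("<ord_data> n = %d, K = %d, p = %d covariates%s\n", x$n, x$K, x$p,
              if (all(x$w == 1)) "" else " (weighted)"))
  invisible(x)
}
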