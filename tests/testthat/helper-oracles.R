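# independent oracles and small utilities shared by the test files.
# Everything here deliberately avoids the package's own computational paths:
# probabilities are evaluated by literal per-row loops, gradients by finite
# differences, logistic fits by a hand-rolled IRLS.

# literal per-row probability evaluation from the documented model forms
oracle_probs <- function(fam_name, K, alpha, beta, X, phi = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    s <- sum(beta * X[i, ])
    if (fam_name == "sm") {
      # ln(pi_{K+1-j} / pi_1) = alpha_j + phi_j * s, j = 1..K-1
      lp <- numeric(K)           # log pi_k up to a constant, pi_1 reference
      for (j in seq_len(K - 1L)) lp[K + 1L - j] <- alpha[j] + phi[j] * s
      out[i, ] <- exp(lp) / sum(exp(lp))
    } else if (fam_name == "ac") {
      # ln(pi_{k+1}/pi_k) = alpha_k + s
      u <- numeric(K); u[1] <- 0
      for (k in seq_len(K - 1L)) u[k + 1L] <- u[k] + alpha[k] + s
      out[i, ] <- exp(u) / sum(exp(u))
    } else if (fam_name == "cr") {
      # logit Pr(Y > k | Y >= k) = alpha_k + s
      remaining <- 1
      for (k in seq_len(K - 1L)) {
        pgt <- stats::plogis(alpha[k] + s)
        out[i, k] <- remaining * (1 - pgt)
        remaining <- remaining * pgt
      }
      out[i, K] <- remaining
    } else {
      # logit Pr(Y <= k) = alpha_k + s
      cum <- c(stats::plogis(alpha + s), 1)
      out[i, ] <- diff(c(0, cum))
    }
  }
  out
}

# hand-rolled logistic IRLS (intercept + covariates), response z in {0,1}
oracle_irls_logistic <- function(z, X, w = rep(1, length(z)), tol = 1e-12) {
  Xd <- cbind(1, X)
  b <- numeric(ncol(Xd))
  for (it in 1:100) {
    eta <- drop(Xd %*% b)
    p <- stats::plogis(eta)
    wk <- w * p * (1 - p)
    zk <- eta + (z - p) / pmax(p * (1 - p), 1e-12)
    bn <- solve(crossprod(Xd, wk * Xd), crossprod(Xd, wk * zk))
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- drop(bn)
  }
  drop(b)
}

fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# random valid free-parameter vector for a family
random_theta <- function(fam, sd_alpha = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- fam$K; p <- fam$p
  alpha <- if (fam$name == "cm") sort(stats::rnorm(K - 1, 0, 1)) else
    stats::rnorm(K - 1, 0, sd_alpha)
  beta <- stats::rnorm(p, 0, 0.6)
  th <- if (fam$name == "sm" && K > 2L) {
    phi_free <- sort(stats::runif(K - 2L, 0.05, 0.95), decreasing = TRUE)
    c(alpha, phi_free, beta)
  } else c(alpha, beta)
  stats::setNames(th, fam$par_names)
}

# dataset drawn from the family itself (guarantees model-consistent data);
# redraws until all categories are observed
random_ord_data <- function(fam, n, theta = NULL, seed = 1, weighted = FALSE) {
  set.seed(seed)
  theta <- theta %||% random_theta(fam)
  params <- svyord:::theta_unpack(fam, theta)
  for (try in 1:50) {
    X <- cbind(stats::runif(n), stats::rbinom(n, 1, 0.5))[, seq_len(fam$p), drop = FALSE]
    pi <- category_probs(fam, params, X)
    cum <- t(apply(pi, 1, cumsum))
    y <- 1L + rowSums(stats::runif(n) > cum[, seq_len(fam$K - 1L), drop = FALSE])
    if (all(tabulate(y, fam$K) > 0L)) break
  }
  w <- if (weighted) stats::runif(n, 0.5, 4) else NULL
  list(data = ord_data(y, X, w = w, K = fam$K), params = params, theta = theta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# disk-memoised truth calibration so acceptance tests can share scenarios
cache_dir <- function() {
  d <- file.path(tempdir(), "svyord-test-cache")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

cached_truth <- function(label, families, M, seed = 20240901L, K = 5L) {
  key <- file.path(cache_dir(),
                   sprintf("truth_%s_K%d_M%g_s%d.rds", label, K, M, seed))
  if (file.exists(key)) {
    truth <- readRDS(key)
    if (all(families %in% names(truth$params))) return(truth)
    families <- union(names(truth$params), families)
  }
  truth <- calibrate_truth(ods_scenario(label, K), families = families,
                           M = M, seed = seed)
  saveRDS(truth, key)
  truth
}
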