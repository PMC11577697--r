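# model-based and design-based (linearization) covariance estimation

# variance of a total from the matrix m of weighted influence contributions
# (rows w_i * z_i): with-replacement n/(n-1) form, or stratified with
# per-stratum n_k/(n_k-1) factors and optional finite population correction
wz_cov <- function(m, strata = NULL, weights = NULL, fpc = FALSE) {
  if (is.null(strata)) {
    n <- nrow(m)
    dev <- sweep(m, 2L, colMeans(m))
    return(crossprod(dev) * n / (n - 1))
  }
  V <- matrix(0, ncol(m), ncol(m))
  for (k in sort(unique(strata))) {
    sel <- strata == k
    nk <- sum(sel)
    if (nk < 2L)
      stop(sprintf("stratified design needs at least 2 sampled units in every outcome category (category %s has %d)",
                   k, nk), call. = FALSE)
    devk <- sweep(m[sel, , drop = FALSE], 2L, colMeans(m[sel, , drop = FALSE]))
    fk <- if (fpc) nk / sum(weights[sel]) else 0
    V <- V + (1 - fk) * crossprod(devk) * nk / (nk - 1)
  }
  V
}

#' Influence functions of a fitted model
#'
#' Computes the n x npar matrix with rows \eqn{z_i = I_w^{-1} U_i}, the
#' influence function of each unit under the asymptotic linearity of the
#' weighted estimator.  At the optimum the weighted column sums are zero
#' (first-order condition).
#'
#' @param fit an [ord_fit()] result (should be converged).
#' @param data the [ord_data()] the model was fitted to.
#' @return numeric matrix n x npar of class `influence_matrix`.
#' @export
influence_functions <- function(fit, data) {
  stopifnot(inherits(fit, "ord_fit"), inherits(data, "ord_data"))
  U <- per_unit_scores(fit$family, fit$params, data)
  Iinv <- pd_solve(fit$info, "observed information")
  structure(U %*% Iinv, class = "influence_matrix")
}

#' Model-based and design-based covariance of the estimates
#'
#' The model-based covariance is the inverse observed information of the
#' (pseudo-)likelihood; for weighted fits it is reported for reference but
#' is not design-consistent.  The design-based covariance approximates the
#' sampling variance of the weighted estimator by the variance of the
#' weighted sum of influence functions:
#'
#' * `design = "wr"` (default): with-replacement, weights-only form
#'   \eqn{\frac{n}{n-1}\sum_i (w_i z_i - \bar m)(w_i z_i - \bar m)'} with
#'   \eqn{\bar m} the mean of the \eqn{w_i z_i}.  This is what a
#'   weights-only survey design specification yields and, with unit weights,
#'   reduces to the standard sandwich estimator.
#' * `design = "stratified"`: outcome categories as strata, within-stratum
#'   deviations with \eqn{n_k/(n_k-1)} factors, and optionally the finite
#'   population correction \eqn{(1 - f_k)} with \eqn{f_k} estimated as
#'   \eqn{n_k / \hat N_k}, \eqn{\hat N_k = \sum_{i \in k} w_i}.
#'
#' @param fit an [ord_fit()].
#' @param data the [ord_data()] used for the fit.
#' @param design `"wr"` or `"stratified"`.
#' @param fpc logical; apply the finite population correction (stratified
#'   design only).
#' @return an object of class `ord_cov`: list with `model_based`,
#'   `design_based`, `se_model`, `se_design`, `design`.
#' @export
design_cov <- function(fit, data, design = c("wr", "stratified"), fpc = FALSE) {
  design <- match.arg(design)
  z <- unclass(influence_functions(fit, data))
  m <- data$w * z
  V <- if (design == "wr") {
    wz_cov(m)
  } else {
    wz_cov(m, strata = data$y, weights = data$w, fpc = fpc)
  }
  dimnames(V) <- list(fit$family$par_names, fit$family$par_names)
  mb <- fit$vcov_model
  structure(list(model_based = mb, design_based = V,
                 se_model = if (!is.null(mb)) sqrt(diag(mb)) else NULL,
                 se_design = sqrt(diag(V)),
                 design = design, fpc = fpc),
            class = "ord_cov")
}

#' @export
print.ord_cov <- function(x, ...) {
  cat(sprintf("<ord_cov> linearization design = %s%s\n", x$design,
              if (isTRUE(x$fpc)) " (with FPC)" else ""))
  print(round(cbind(se_model = x$se_model, se_design = x$se_design), 5))
  invisible(x)
}

#' Delta-method inference for stereotype log-odds products
#'
#' For the stereotype model the quantities of applied interest are the
#' products \eqn{\phi_k \beta_j}: the change in the relevant
#' baseline-category log odds per unit of covariate j.  Their variance is
#' obtained by the delta method,
#' \deqn{V(\hat\phi_k \hat\beta_j) = \hat\phi_k^2 V(\hat\beta_j)
#'   + \hat\beta_j^2 V(\hat\phi_k)
#'   + 2 \hat\phi_k \hat\beta_j \,\mathrm{Cov}(\hat\phi_k, \hat\beta_j).}
#' For `k = 1` the score is fixed at 1 so the variance is exactly
#' \eqn{V(\hat\beta_j)}; for `k = K` both estimate and variance are 0.
#'
#' @param fit a converged stereotype-model [ord_fit()].
#' @param cov an [ord_cov()] from [design_cov()], or a covariance matrix over
#'   the free parameters.
#' @param which `"design"` or `"model"`: which covariance in `cov` to use
#'   (ignored when `cov` is a plain matrix).
#' @return data frame with columns `k`, `j`, `term`, `estimate`, `se`.
#' @export
delta_phi_beta <- function(fit, cov, which = c("design", "model")) {
  stopifnot(inherits(fit, "ord_fit"))
  if (fit$family$name != "sm")
    stop("phi * beta products are defined for the stereotype model only",
         call. = FALSE)
  which <- match.arg(which)
  V <- if (inherits(cov, "ord_cov")) {
    if (which == "design") cov$design_based else cov$model_based
  } else cov
  if (is.null(V)) stop("requested covariance is not available", call. = FALSE)
  K <- fit$family$K; p <- fit$family$p
  phi <- fit$params$phi
  beta <- fit$params$beta
  out <- expand.grid(k = seq_len(K), j = seq_len(p))
  out$term <- sprintf("phi%d*beta%d", out$k, out$j)
  est <- se <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    k <- out$k[r]; j <- out$j[r]
    bj <- sprintf("beta%d", j)
    if (k == K) {
      est[r] <- 0; se[r] <- 0
    } else if (k == 1L) {
      est[r] <- beta[j]
      se[r] <- sqrt(V[bj, bj])
    } else {
      fk <- sprintf("phi%d", k)
      est[r] <- phi[k] * beta[j]
      v <- phi[k]^2 * V[bj, bj] + beta[j]^2 * V[fk, fk] +
        2 * phi[k] * beta[j] * V[fk, bj]
      se[r] <- sqrt(max(v, 0))
    }
  }
  out$estimate <- est
  out$se <- se
  out
}
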