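# maximum (pseudo-)likelihood fitting
#
# All four families are fitted by damped Newton iterations on the analytic
# score and observed information.  For AC/CR/CM the weighted log-likelihood
# is concave in theta, so Newton with step-halving converges globally.  The
# stereotype model has a bilinear phi * beta term, so the fit first
# alternates between the two concave conditional subproblems
# (alpha, beta | phi) and (alpha, phi | beta) and then polishes with joint
# Newton steps on the full parameter vector.

default_control <- function(control) {
  ctl <- list(tol_loglik = 1e-10, tol_score = 1e-6, max_iter = 200L)
  ctl[names(control)] <- control
  ctl
}

# starting values: empirical category log-odds for the intercepts, zero
# slopes (AC/CR/CM); the stereotype model starts from the equally spaced
# adjacent-category re-expression of a quick AC fit.
init_params <- function(family, data) {
  K <- family$K
  pk <- as.numeric(rowsum(data$w, data$y)) / sum(data$w)
  pk <- pmax(pk, 1e-10)
  switch(family$name,
    cm = ord_params(family, alpha = stats::qlogis(cumsum(pk)[seq_len(K - 1L)])),
    ac = ord_params(family, alpha = log(pk[-1L] / pk[-K])),
    cr = {
      Sge <- rev(cumsum(rev(pk)))                         # Pr(Y >= k)
      Sgt <- c(Sge[-1L], 0)                               # Pr(Y > k)
      ord_params(family, alpha = stats::qlogis((Sgt / Sge)[seq_len(K - 1L)]))
    },
    sm = {
      fam_ac <- ord_family("ac", K, family$p)
      ac_fit <- ord_fit(fam_ac, data,
                        control = list(tol_score = 1e-4, max_iter = 50L))
      ac_as_sm(ac_fit$params)
    })
}

newton_solve <- function(info, score) {
  step <- tryCatch(solve(info, score), error = function(e) NULL)
  lam <- 1e-8 * max(mean(abs(diag(info))), 1)
  while (is.null(step) && lam < 1e6) {
    step <- tryCatch(solve(info + diag(lam, nrow(info)), score),
                     error = function(e) NULL)
    lam <- lam * 100
  }
  step
}

#' Fit an ordinal regression model by weighted pseudo-likelihood
#'
#' Maximizes \eqn{\ell_w(\theta) = \sum_i w_i \ell_i(\theta)} for any of the
#' four families.  With unit weights this is ordinary maximum likelihood;
#' with inverse sampling-fraction weights it is the design-consistent
#' weighted estimator for outcome-dependent samples.  The optimizer is
#' deterministic given the data and options.
#'
#' @param family an [ord_family()].
#' @param data an [ord_data()]; every outcome category `1..K` must be
#'   observed at least once.
#' @param init optional starting values: an [ord_params()] or a named free
#'   parameter vector.
#' @param control list with any of `tol_loglik` (relative log-likelihood
#'   change, default `1e-10`), `tol_score` (score sup-norm relative to
#'   `max(1, |loglik|)`, default `1e-6`), `max_iter` (default 200).
#' @return an object of class `ord_fit` with elements `params`, `theta`,
#'   `loglik`, `score`, `info`, `vcov_model`, `converged`, `iterations`,
#'   `ll_trace` (log-likelihood after each accepted step), `family`, `n`,
#'   `weighted`.  Non-convergence (including apparent divergence under
#'   separated data) produces a warning and `converged = FALSE`, not an
#'   error.
#' @export
ord_fit <- function(family, data, init = NULL, control = list()) {
  stopifnot(inherits(family, "ord_family"), inherits(data, "ord_data"))
  if (data$K != family$K)
    stop("data has K different from family", call. = FALSE)
  if (data$p != family$p)
    stop("data has p different from family", call. = FALSE)
  cnt <- tabulate(data$y, family$K)
  if (any(cnt == 0L))
    stop(sprintf("empty outcome category: %s",
                 paste(which(cnt == 0L), collapse = ", ")), call. = FALSE)
  ctl <- default_control(control)

  params0 <- if (is.null(init)) {
    init_params(family, data)
  } else if (inherits(init, "ord_params")) {
    init
  } else {
    theta_unpack(family, as.numeric(init)[seq_len(family$npar)])
  }
  theta <- theta_pack(params0)
  d <- family$npar

  valid <- function(th) {
    if (family$name != "cm") return(TRUE)
    !is.unsorted(th[seq_len(family$K - 1L)], strictly = TRUE)
  }
  parts_at <- function(th) {
    if (!valid(th)) return(list(ll = -Inf))
    pr <- ord_parts(family, theta_unpack(family, th), data, need_info = TRUE)
    if (!is.finite(pr$ll)) return(list(ll = -Inf))
    pr
  }

  if (!valid(theta)) stop("invalid starting values", call. = FALSE)
  parts <- parts_at(theta)
  if (!is.finite(parts$ll)) stop("starting values give -Inf log-likelihood",
                                 call. = FALSE)
  iterations <- 0L
  stalled <- FALSE
  ll_trace <- parts$ll

  converged_at <- function(parts, idx) {
    max(abs(parts$score[idx])) < ctl$tol_score * max(1, abs(parts$ll))
  }

  newton_block <- function(idx, max_it) {
    conv <- converged_at(parts, idx)
    it <- 0L
    while (!conv && it < max_it && iterations < ctl$max_iter) {
      step <- newton_solve(parts$info[idx, idx, drop = FALSE],
                           parts$score[idx])
      if (is.null(step)) { stalled <<- TRUE; break }
      tfac <- 1
      improved <- FALSE
      for (h in 1:40) {
        cand <- theta
        cand[idx] <- cand[idx] + tfac * step
        pr_new <- parts_at(cand)
        if (is.finite(pr_new$ll) &&
            pr_new$ll >= parts$ll - 1e-12 * (1 + abs(parts$ll)) &&
            (pr_new$ll > parts$ll || max(abs(pr_new$score[idx])) <
               max(abs(parts$score[idx])))) {
          theta <<- cand; parts <<- pr_new; improved <- TRUE
          ll_trace <<- c(ll_trace, pr_new$ll)
          break
        }
        tfac <- tfac / 2
      }
      it <- it + 1L
      iterations <<- iterations + 1L
      if (!improved) { stalled <<- TRUE; break }
      conv <- converged_at(parts, idx)
    }
    conv
  }

  all_idx <- seq_len(d)
  if (family$name == "sm" && family$K > 2L && family$p > 0L) {
    K <- family$K; p <- family$p
    idx_ab <- c(seq_len(K - 1L), (d - p + 1L):d)
    idx_af <- seq_len(d - p)
    for (outer in 1:40) {
      ll_before <- parts$ll
      newton_block(idx_ab, 25L)
      newton_block(idx_af, 25L)
      if (parts$ll - ll_before < 1e-8 * (1 + abs(parts$ll))) break
      if (stalled || iterations >= ctl$max_iter) break
    }
    stalled <- FALSE                       # give the joint polish a chance
    conv <- newton_block(all_idx, ctl$max_iter)
  } else {
    conv <- newton_block(all_idx, ctl$max_iter)
  }

  if (conv && max(abs(theta)) > 20) {
    # a stationary point this far out on the logit scale almost always means
    # (quasi-)separated data: the likelihood flattens while the estimate
    # escapes to infinity, so the first-order condition is not trustworthy
    conv <- FALSE
    warning(sprintf("ord_fit (%s): apparent divergence (max |estimate| = %.1f); possible perfect separation",
                    family$name, max(abs(theta))))
  } else if (!conv) {
    warning(sprintf("ord_fit (%s): not converged after %d iterations (max |score| = %.3g)",
                    family$name, iterations, max(abs(parts$score))))
  }
  vcov_model <- tryCatch(pd_solve(parts$info), error = function(e) {
    warning(conditionMessage(e)); NULL
  })
  names(theta) <- family$par_names
  structure(list(family = family, params = theta_unpack(family, theta),
                 theta = theta, loglik = parts$ll, score = parts$score,
                 info = parts$info, vcov_model = vcov_model,
                 converged = conv, iterations = iterations,
                 ll_trace = ll_trace,
                 n = data$n, weighted = !all(data$w == 1)),
            class = "ord_fit")
}

#' @export
print.ord_fit <- function(x, ...) {
  cat(sprintf("<ord_fit> %s, n = %d%s, log %slikelihood = %.4f (%s, %d Newton steps)\n",
              toupper(x$family$name), x$n,
              if (x$weighted) " (weighted)" else "",
              if (x$weighted) "pseudo-" else "",
              x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED",
              x$iterations))
  est <- x$theta
  se <- if (!is.null(x$vcov_model)) sqrt(diag(x$vcov_model)) else rep(NA_real_, length(est))
  print(round(cbind(estimate = est, se_model = se), 4))
  invisible(x)
}

#' @export
coef.ord_fit <- function(object, ...) object$theta

#' @export
vcov.ord_fit <- function(object, ...) object$vcov_model

#' @export
logLik.ord_fit <- function(object, ...) {
  structure(object$loglik, df = object$family$npar, class = "logLik")
}
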