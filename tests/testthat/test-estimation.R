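# pseudo-likelihood maximization: optimizer, scores, information

test_that("K = 2 fits reproduce the logistic MLE from an IRLS oracle", {
  set.seed(21)
  n <- 400
  X <- cbind(runif(n, -1, 1))
  y <- 1L + rbinom(n, 1, plogis(-0.4 + 1.1 * X[, 1]))
  w <- runif(n, 0.5, 3)
  for (weighted in c(FALSE, TRUE)) {
    dat <- ord_data(y, X, w = if (weighted) w else NULL)
    ref <- oracle_irls_logistic(as.numeric(y == 2L), X,
                                w = if (weighted) w else rep(1, n))
    for (nm in c("sm", "ac", "cr", "cm")) {
      fit <- ord_fit(ord_family(nm, 2, 1), dat,
                     control = list(tol_score = 1e-11))
      est <- if (nm == "cm") -fit$theta else fit$theta
      expect_lt(max(abs(est - ref)), 1e-8)
    }
  }
})

test_that("cumulative-logit fits agree with an established proportional-odds fitter", {
  fam <- ord_family("cm", 4, 2)
  rd <- random_ord_data(fam, n = 1500, seed = 202)
  fit <- ord_fit(fam, rd$data)
  ref <- MASS::polr(factor(rd$data$y) ~ rd$data$X, method = "logistic")
  # polr parameterizes logit P(Y<=k) = zeta_k - eta, so slopes flip sign
  expect_equal(unname(fit$theta[1:3]), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(unname(fit$theta[4:5]), unname(-coef(ref)), tolerance = 1e-4)
})

test_that("analytic score and information match finite differences", {
  for (nm in c("sm", "ac", "cr", "cm")) {
    for (K in c(3L, 5L)) {
      fam <- ord_family(nm, K, 2)
      rd <- random_ord_data(fam, n = 60, seed = 400 + K, weighted = TRUE)
      th <- random_theta(fam, seed = 800 + K)
      params <- svyord:::theta_unpack(fam, th)
      dat <- rd$data
      si <- score_and_info(fam, params, dat)
      llf <- function(t) sum(dat$w * loglik_contributions(
        fam, svyord:::theta_unpack(fam, t), dat$y, dat$X))
      g <- fd_gradient(llf, th)
      expect_lt(max(abs(si$score - g)) / max(1, max(abs(g))), 1e-5)
      H <- matrix(NA_real_, fam$npar, fam$npar)
      for (j in seq_len(fam$npar)) {
        e <- numeric(fam$npar); e[j] <- 1e-5
        sp <- score_and_info(fam, svyord:::theta_unpack(fam, th + e), dat)$score
        sm <- score_and_info(fam, svyord:::theta_unpack(fam, th - e), dat)$score
        H[, j] <- (sp - sm) / 2e-5
      }
      expect_lt(max(abs(si$info + H)) / max(1, max(abs(H))), 1e-5)
    }
  }
})

test_that("score and information are linear in the weights", {
  fam <- ord_family("cr", 4, 2)
  rd <- random_ord_data(fam, n = 80, seed = 5, weighted = TRUE)
  params <- rd$params
  s1 <- score_and_info(fam, params, rd$data)
  double <- ord_data(rd$data$y, rd$data$X, w = 2 * rd$data$w, K = 4)
  s2 <- score_and_info(fam, params, double)
  expect_equal(s2$score, 2 * s1$score)
  expect_equal(s2$info, 2 * s1$info)
})

test_that("per-unit scores aggregate to the total score", {
  for (nm in c("sm", "cm")) {
    fam <- ord_family(nm, 4, 2)
    rd <- random_ord_data(fam, n = 40, seed = 31, weighted = TRUE)
    U <- per_unit_scores(fam, rd$params, rd$data)
    si <- score_and_info(fam, rd$params, rd$data)
    expect_equal(colSums(rd$data$w * U), si$score)
    # single-row dataset: U_1 is the whole score under unit weight
    one <- ord_data(rd$data$y[1], rd$data$X[1, , drop = FALSE], K = 4)
    expect_equal(drop(per_unit_scores(fam, rd$params, one)),
                 score_and_info(fam, rd$params, one)$score)
    # per-unit rows match per-unit finite differences on a 5-row slice
    sl <- ord_data(rd$data$y[1:5], rd$data$X[1:5, , drop = FALSE], K = 4)
    for (i in 1:5) {
      lli <- function(t) loglik_contributions(
        fam, svyord:::theta_unpack(fam, t), sl$y[i],
        sl$X[i, , drop = FALSE])
      expect_equal(per_unit_scores(fam, rd$params, sl)[i, ],
                   setNames(fd_gradient(lli, rd$theta), fam$par_names),
                   tolerance = 1e-6)
    }
  }
})

test_that("the fit satisfies first-order and second-order optimality", {
  for (nm in c("sm", "ac", "cr", "cm")) {
    fam <- ord_family(nm, 4, 2)
    rd <- random_ord_data(fam, n = 600, seed = 77, weighted = TRUE)
    fit <- ord_fit(fam, rd$data)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$score)), 1e-6 * max(1, abs(fit$loglik)))
    expect_silent(chol(fit$info))   # positive definite at the optimum
    # monotone improvement with step-halving
    expect_true(all(diff(fit$ll_trace) > -1e-9 * (1 + abs(fit$loglik))))
  }
})

test_that("rescaling all weights leaves the estimate unchanged", {
  fam <- ord_family("sm", 4, 2)
  rd <- random_ord_data(fam, n = 500, seed = 13, weighted = TRUE)
  f1 <- ord_fit(fam, rd$data)
  scaled <- ord_data(rd$data$y, rd$data$X, w = 3.7 * rd$data$w, K = 4)
  f2 <- ord_fit(fam, scaled)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
  # and an unweighted fit equals a weighted fit with w == 1 exactly
  unit <- ord_data(rd$data$y, rd$data$X, w = rep(1, rd$data$n), K = 4)
  plain <- ord_data(rd$data$y, rd$data$X, K = 4)
  expect_identical(ord_fit(fam, unit)$theta, ord_fit(fam, plain)$theta)
})

test_that("parameters are recovered on self-generated data and bias shrinks with n", {
  fam <- ord_family("ac", 5, 2)
  truth <- c(alpha1 = 0.8, alpha2 = -0.1, alpha3 = -0.2, alpha4 = -0.3,
             beta1 = 0.8, beta2 = -0.4)
  big <- random_ord_data(fam, n = 50000, theta = truth, seed = 2024)
  fit_big <- ord_fit(fam, big$data)
  se <- sqrt(diag(fit_big$vcov_model))
  expect_true(all(abs(fit_big$theta - truth) < 3.5 * se))
  small <- random_ord_data(fam, n = 2000, theta = truth, seed = 2024)
  fit_small <- ord_fit(fam, small$data)
  expect_lt(sqrt(sum((fit_big$theta - truth)^2)),
            sqrt(sum((fit_small$theta - truth)^2)))
})

test_that("stereotype fit matches a 1-D profile search over phi2 (K = 3)", {
  fam <- ord_family("sm", 3, 2)
  rd <- random_ord_data(fam, n = 400,
                        theta = c(alpha1 = 0.8, alpha2 = 0.3, phi2 = 0.55,
                                  beta1 = 1.6, beta2 = -0.8),
                        seed = 640)
  fit <- ord_fit(fam, rd$data)
  # independent profile: for fixed phi2 the model is linear in (alpha, beta);
  # maximize with optim on the literal likelihood, then search over phi2
  prof <- function(phi2) {
    nll <- function(par) {
      p <- ord_params(fam, alpha = par[1:2], phi = c(1, phi2, 0),
                      beta = par[3:4])
      -sum(loglik_contributions(fam, p, rd$data$y, rd$data$X))
    }
    stats::optim(c(fit$theta[1:2], fit$theta[4:5]), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))$value
  }
  opt <- stats::optimize(prof, interval = fit$theta["phi2"] + c(-0.15, 0.15),
                         tol = 1e-6)
  expect_lt(abs(opt$minimum - fit$theta["phi2"]), 1e-4)
  expect_lt(abs(opt$objective + fit$loglik), 1e-4)
})

test_that("degenerate inputs are reported, not silently absorbed", {
  fam <- ord_family("cm", 3, 1)
  expect_error(ord_fit(fam, ord_data(c(1, 1, 3), matrix(1:3), K = 3)),
               "empty outcome category")
  # perfect separation: flagged as non-convergence, not an exception
  x <- c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2)
  dat <- ord_data(ifelse(x < 0, 1L, 2L), cbind(x))
  expect_warning(fit <- ord_fit(ord_family("cm", 2, 1), dat), "separation")
  expect_false(fit$converged)
})
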