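# model definitions: probabilities, log-likelihood contributions, AC<->SM

test_that("parameter counts and constructors follow the family definitions", {
  expect_equal(ord_family("sm", 5, 2)$npar, 2 * 5 - 3 + 2)
  expect_equal(ord_family("sm", 3, 0)$npar, 2 * 3 - 3)
  for (nm in c("ac", "cr", "cm"))
    expect_equal(ord_family(nm, 5, 2)$npar, 5 - 1 + 2)
  expect_error(ord_family("cm", 1, 0), "K must be")
  expect_error(ord_family("xx", 3, 0))
  fam <- ord_family("sm", 4, 1)
  expect_error(ord_params(fam, alpha = c(0, 0, 0), phi = c(0.9, 0.5, 0.2, 0),
                          beta = 1), "phi\\[1\\]")
  expect_error(ord_params(fam, alpha = c(0, 0), beta = 1), "length K - 1")
})

test_that("closed-form special cases give the expected probabilities", {
  x0 <- matrix(c(0.3, -1.2), 1)
  # SM with zero intercepts and zero slopes: uniform over the K categories
  fam <- ord_family("sm", 5, 2)
  p <- ord_params(fam, alpha = rep(0, 4), phi = c(1, .75, .5, .25, 0),
                  beta = c(0, 0))
  expect_equal(drop(category_probs(fam, p, x0)), rep(0.2, 5), tolerance = 1e-12)
  # CR with all logits zero: repeated halving
  fam <- ord_family("cr", 5, 0)
  p <- ord_params(fam, alpha = rep(0, 4))
  expect_equal(drop(category_probs(fam, p, matrix(numeric(0), 1, 0))),
               c(0.5, 0.25, 0.125, 0.0625, 0.0625), tolerance = 1e-12)
  # CM, K = 2, alpha = 0: an even split
  fam <- ord_family("cm", 2, 1)
  p <- ord_params(fam, alpha = 0, beta = 0)
  expect_equal(drop(category_probs(fam, p, matrix(0.7))), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("stereotype probabilities match a frozen literal evaluation", {
  # alpha/phi/beta in the reported convention, x = (0.5, 1); expected values
  # frozen from an independent per-row evaluation of the documented contrasts
  fam <- ord_family("sm", 5, 2)
  p <- ord_params(fam, alpha = c(0.9, 1.2, 1.3, 1.5),
                  phi = c(1, 0.75, 0.5, 0.25, 0), beta = c(3.5, -1.7))
  got <- drop(category_probs(fam, p, matrix(c(0.5, 1), 1)))
  expect_equal(got,
               c(0.065219055747, 0.295968104157, 0.245366176399,
                 0.224809121281, 0.168637542417),
               tolerance = 1e-9)
})

test_that("probabilities are row-stochastic and agree with the literal oracle", {
  for (nm in c("sm", "ac", "cr", "cm")) {
    for (K in 2:6) {
      if (nm == "sm" && K == 2) next
      fam <- ord_family(nm, K, 2)
      for (rep in 1:3) {
        th <- random_theta(fam, seed = 1000 * K + rep)
        params <- svyord:::theta_unpack(fam, th)
        X <- cbind(runif(7, -1, 1), rbinom(7, 1, 0.5))
        pi <- category_probs(fam, params, X)
        expect_equal(rowSums(pi), rep(1, 7), tolerance = 1e-12)
        expect_true(all(pi > 0 & pi < 1))
        orc <- oracle_probs(nm, K, params$alpha, params$beta, X,
                            phi = params$phi)
        expect_equal(pi, orc, tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  }
})

test_that("log-likelihood contributions are the picked log-probabilities", {
  fam <- ord_family("cm", 2, 0)
  p <- ord_params(fam, alpha = 0)
  expect_equal(loglik_contributions(fam, p, 1L, matrix(numeric(0), 1, 0)),
               log(0.5))
  # sum over a dataset = log of the product of picked probabilities,
  # checked against an independent multinomial log-density loop
  set.seed(7)
  for (nm in c("sm", "ac", "cr", "cm")) {
    fam <- ord_family(nm, 4, 2)
    for (rep in 1:5) {
      th <- random_theta(fam, seed = 50 + rep)
      params <- svyord:::theta_unpack(fam, th)
      X <- cbind(runif(12), rbinom(12, 1, 0.5))
      y <- sample(1:4, 12, replace = TRUE)
      ll <- loglik_contributions(fam, params, y, X)
      orc <- oracle_probs(nm, 4, params$alpha, params$beta, X, phi = params$phi)
      manual <- vapply(1:12, function(i) log(orc[i, y[i]]), numeric(1))
      expect_equal(ll, manual, tolerance = 1e-10)
      expect_equal(sum(ll), log(prod(orc[cbind(1:12, y)])), tolerance = 1e-8)
    }
  }
  expect_error(loglik_contributions(fam, params, c(1L, 9L), X[1:2, ]),
               "coded 1")
})

test_that("adjacent-category fits are stereotype models with fixed scores", {
  # K = 2: the mapping is the identity up to constraint bookkeeping
  fam2 <- ord_family("ac", 2, 1)
  pac <- ord_params(fam2, alpha = 0.4, beta = -0.7)
  psm <- ac_as_sm(pac)
  expect_equal(psm$alpha, 0.4)
  expect_equal(psm$beta, -0.7)
  # equivalence of category probabilities for K = 2..6
  for (K in 2:6) {
    fam <- ord_family("ac", K, 2)
    th <- random_theta(fam, seed = 300 + K)
    pac <- svyord:::theta_unpack(fam, th)
    psm <- ac_as_sm(pac)
    expect_equal(psm$phi, rev((0:(K - 1)) / (K - 1)))
    X <- cbind(runif(9, -1, 1), rbinom(9, 1, 0.5))
    d <- abs(category_probs(fam, pac, X) -
               category_probs(psm$family, psm, X))
    expect_lt(max(d), 1e-10)
  }
  # zero AC slope maps to zero SM slope
  pac0 <- ord_params(ord_family("ac", 4, 1), alpha = c(.2, -.1, .3), beta = 0)
  expect_equal(ac_as_sm(pac0)$beta, 0)
  expect_error(ac_as_sm(psm), "adjacent-category")
})

test_that("for K = 2 all four families are the same Bernoulli model", {
  X <- cbind(runif(30, -1, 1))
  y <- 1L + rbinom(30, 1, 0.5)
  a <- -0.3; b <- 0.9
  ll <- sapply(c("sm", "ac", "cr", "cm"), function(nm) {
    fam <- ord_family(nm, 2, 1)
    # cm models the low side: logit P(Y<=1) = alpha + beta x, so negate
    p <- if (nm == "cm") ord_params(fam, alpha = -a, beta = -b)
         else ord_params(fam, alpha = a, beta = b)
    sum(loglik_contributions(fam, p, y, X))
  })
  expect_equal(max(ll) - min(ll), 0, tolerance = 1e-12)
})

test_that("invalid cumulative-logit parameters error instead of clipping", {
  fam <- ord_family("cm", 3, 1)
  bad <- ord_params(fam, alpha = c(0.5, -0.5), beta = 1)
  expect_error(category_probs(fam, bad, matrix(0)), "strictly increasing")
  expect_error(score_and_info(fam, bad, ord_data(c(1, 2, 3), matrix(0:2), K = 3)),
               "strictly increasing")
})

test_that("dimension mismatches are rejected", {
  fam <- ord_family("ac", 3, 2)
  p <- ord_params(fam, alpha = c(0, 0), beta = c(1, 1))
  expect_error(category_probs(fam, p, matrix(1, 2, 3)), "columns")
  fam_b <- ord_family("cr", 3, 2)
  expect_error(category_probs(fam_b, p, matrix(1, 2, 2)), "different family")
})

test_that("no spurious invariances: each free parameter moves some probability", {
  for (nm in c("sm", "ac", "cr", "cm")) {
    fam <- ord_family(nm, 4, 2)
    th <- random_theta(fam, seed = 99)
    base <- category_probs(fam, svyord:::theta_unpack(fam, th),
                           cbind(0.4, 1))
    for (j in seq_along(th)) {
      th2 <- th; th2[j] <- th2[j] + 0.05
      if (nm == "cm" && is.unsorted(th2[1:3], strictly = TRUE)) next
      moved <- category_probs(fam, svyord:::theta_unpack(fam, th2),
                              cbind(0.4, 1))
      expect_gt(max(abs(moved - base)), 1e-6)
    }
  }
})
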