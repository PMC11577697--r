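# analytic per-unit scores and observed information for the pseudo-likelihood
#
# All derivatives are taken with respect to the free parameter vector
# theta = (alpha, [phi_2..phi_{K-1}], beta) in the order of family$par_names.
# The observed information returned is that of the *pseudo*-likelihood,
# I_w = -sum_i w_i d2 l_i / d theta2.

ord_parts <- function(family, params, data, need_info = TRUE) {
  y <- data$y; X <- data$X; w <- data$w
  n <- data$n; K <- family$K; p <- family$p
  if (data$K != K) stop("data K does not match family K", call. = FALSE)
  d <- family$npar
  s <- if (p > 0L) drop(X %*% params$beta) else rep(0, n)
  iy <- cbind(seq_len(n), y)

  if (family$name %in% c("sm", "ac")) {
    eta <- softmax_eta(family, params, s)
    mx <- apply(eta, 1L, max)
    ex <- exp(eta - mx)
    den <- rowSums(ex)
    pi <- ex / den
    lli <- eta[iy] - mx - log(den)
    r <- -pi; r[iy] <- r[iy] + 1

    U <- matrix(0, n, d)
    info <- if (need_info) matrix(0, d, d) else NULL

    if (family$name == "sm") {
      cc <- rev(params$phi)                 # c_k, c_1 = 0, c_K = 1
      kmap <- K + 1L - seq_len(K - 1L)      # alpha_j <-> softmax column K+1-j
      nphi <- K - 2L
      U[, seq_len(K - 1L)] <- r[, kmap, drop = FALSE]
      if (nphi > 0L)
        U[, (K - 1L) + seq_len(nphi)] <- s * r[, kmap[2:(K - 1L)], drop = FALSE]
      if (p > 0L) {
        g <- drop(r %*% cc)
        U[, (d - p + 1L):d] <- g * X
      }
      if (need_info) {
        q <- drop(pi %*% cc)
        for (j in seq_len(K - 1L)) {
          kj <- kmap[j]
          for (j2 in j:(K - 1L)) {
            kl <- kmap[j2]
            mm <- pi[, kj] * ((kj == kl) - pi[, kl])
            info[j, j2] <- info[j2, j] <- sum(w * mm)
            if (j2 >= 2L)                                  # alpha_j x phi_{j2}
              info[j, (K - 1L) + (j2 - 1L)] <-
                info[(K - 1L) + (j2 - 1L), j] <- sum(w * s * mm)
            if (j >= 2L && j2 >= 2L) {
              info[(K - 1L) + (j - 1L), (K - 1L) + (j2 - 1L)] <-
                info[(K - 1L) + (j2 - 1L), (K - 1L) + (j - 1L)] <-
                  sum(w * s * s * mm)
            }
            if (j2 > j && j >= 2L) {                       # alpha_{j2} x phi_j
              info[j2, (K - 1L) + (j - 1L)] <-
                info[(K - 1L) + (j - 1L), j2] <- sum(w * s * mm)
            }
          }
          if (p > 0L) {
            vkj <- pi[, kj] * (cc[kj] - q)
            ab <- drop(crossprod(X, w * vkj))
            info[j, (d - p + 1L):d] <- info[(d - p + 1L):d, j] <- ab
            if (j >= 2L) {                                 # phi_j x beta
              fb <- drop(crossprod(X, w * (s * vkj - r[, kj])))
              info[(K - 1L) + (j - 1L), (d - p + 1L):d] <-
                info[(d - p + 1L):d, (K - 1L) + (j - 1L)] <- fb
            }
          }
        }
        if (p > 0L) {
          u2 <- drop(pi %*% cc^2) - q^2
          info[(d - p + 1L):d, (d - p + 1L):d] <- crossprod(X, X * (w * u2))
        }
      }
    } else {  # ac
      ranks <- 0:(K - 1L)
      Scum <- row_cumsum(pi)
      S <- 1 - Scum[, seq_len(K - 1L), drop = FALSE]       # Pr(Y > j)
      for (j in seq_len(K - 1L)) U[, j] <- (y > j) - S[, j]
      mu <- drop(pi %*% ranks)
      if (p > 0L) U[, (d - p + 1L):d] <- ((y - 1L) - mu) * X
      if (need_info) {
        Q <- pi * matrix(ranks, n, K, byrow = TRUE)
        Qcum <- row_cumsum(Q)
        for (j in seq_len(K - 1L)) {
          for (j2 in j:(K - 1L)) {
            info[j, j2] <- info[j2, j] <- sum(w * (S[, j2] - S[, j] * S[, j2]))
          }
          if (p > 0L) {
            T1j <- mu - Qcum[, j]
            ab <- drop(crossprod(X, w * (T1j - mu * S[, j])))
            info[j, (d - p + 1L):d] <- info[(d - p + 1L):d, j] <- ab
          }
        }
        if (p > 0L) {
          v <- drop(pi %*% ranks^2) - mu^2
          info[(d - p + 1L):d, (d - p + 1L):d] <- crossprod(X, X * (w * v))
        }
      }
    }
  } else if (family$name == "cr") {
    Ua <- matrix(0, n, K - 1L)
    G <- matrix(0, n, K - 1L)
    lli <- numeric(n)
    for (j in seq_len(K - 1L)) {
      at <- y >= j
      z <- as.numeric(y > j)
      eta <- params$alpha[j] + s
      pb <- stats::plogis(eta)
      lli <- lli + at * (z * eta - log1pexp(eta))
      Ua[, j] <- at * (z - pb)
      G[, j] <- at * pb * (1 - pb)
    }
    U <- if (p > 0L) cbind(Ua, rowSums(Ua) * X) else Ua
    info <- NULL
    if (need_info) {
      info <- matrix(0, d, d)
      diag(info)[seq_len(K - 1L)] <- colSums(w * G)
      if (p > 0L) {
        ab <- crossprod(X, w * G)                          # p x (K-1)
        info[(d - p + 1L):d, seq_len(K - 1L)] <- ab
        info[seq_len(K - 1L), (d - p + 1L):d] <- t(ab)
        info[(d - p + 1L):d, (d - p + 1L):d] <-
          crossprod(X, X * (w * rowSums(G)))
      }
    }
  } else {  # cm
    if (is.unsorted(params$alpha, strictly = TRUE))
      stop("invalid cumulative-logit parameters: intercepts must be strictly increasing",
           call. = FALSE)
    gam <- vapply(seq_len(K - 1L),
                  function(k) stats::plogis(params$alpha[k] + s), numeric(n))
    gam <- matrix(gam, n, K - 1L)
    g <- gam * (1 - gam)
    h <- g * (1 - 2 * gam)
    hasA <- y <= K - 1L
    hasB <- y >= 2L
    idxA <- cbind(seq_len(n), pmin(y, K - 1L))
    idxB <- cbind(seq_len(n), pmax(y - 1L, 1L))
    GA <- ifelse(hasA, gam[idxA], 1)
    GB <- ifelse(hasB, gam[idxB], 0)
    piy <- GA - GB
    gA <- ifelse(hasA, g[idxA], 0)
    gB <- ifelse(hasB, g[idxB], 0)
    hA <- ifelse(hasA, h[idxA], 0)
    hB <- ifelse(hasB, h[idxB], 0)
    lli <- log(piy)
    Ua <- matrix(0, n, K - 1L)
    Ua[idxA[hasA, , drop = FALSE]] <- (gA / piy)[hasA]
    Ua[idxB[hasB, , drop = FALSE]] <- Ua[idxB[hasB, , drop = FALSE]] -
      (gB / piy)[hasB]
    U <- if (p > 0L) cbind(Ua, ((gA - gB) / piy) * X) else Ua
    info <- NULL
    if (need_info) {
      Cm <- matrix(0, n, K - 1L)
      Cm[idxA[hasA, , drop = FALSE]] <- (w * hA / piy)[hasA]
      Cm[idxB[hasB, , drop = FALSE]] <- Cm[idxB[hasB, , drop = FALSE]] -
        (w * hB / piy)[hasB]
      Apart <- matrix(0, d, d)
      diag(Apart)[seq_len(K - 1L)] <- colSums(Cm)
      if (p > 0L) {
        ab <- crossprod(X, Cm)
        Apart[(d - p + 1L):d, seq_len(K - 1L)] <- ab
        Apart[seq_len(K - 1L), (d - p + 1L):d] <- t(ab)
        Apart[(d - p + 1L):d, (d - p + 1L):d] <- crossprod(X, X * rowSums(Cm))
      }
      info <- crossprod(U * sqrt(w)) - Apart
    }
  }

  dimnames(U) <- list(NULL, family$par_names)
  if (!is.null(info)) dimnames(info) <- list(family$par_names, family$par_names)
  list(ll = sum(w * lli), lli = lli, U = U,
       score = colSums(w * U), info = info)
}

#' Weighted score vector and observed information
#'
#' Returns the gradient \eqn{\sum_i w_i U_i(\theta)} of the weighted
#' log pseudo-likelihood and the observed information
#' \eqn{I_w = -\sum_i w_i \partial^2 \ell_i / \partial\theta^2}
#' (observed, not expected), both evaluated analytically.
#'
#' @inheritParams category_probs
#' @param data an [ord_data()] object.
#' @return list with elements `score` (named vector) and `info`
#'   (named symmetric matrix).
#' @export
score_and_info <- function(family, params, data) {
  parts <- ord_parts(family, params, data, need_info = TRUE)
  list(score = parts$score, info = parts$info)
}

#' Per-unit score contributions
#'
#' The n x npar matrix whose ith row is \eqn{U_i = \partial \ell_i /
#' \partial\theta} (unweighted).  Weighted column sums equal the total
#' score returned by [score_and_info()].
#'
#' @inheritParams score_and_info
#' @return numeric matrix with one row per unit and one column per free
#'   parameter.
#' @export
per_unit_scores <- function(family, params, data) {
  ord_parts(family, params, data, need_info = FALSE)$U
}
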