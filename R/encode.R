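## Unconstrained parameterization of the model for gradient-based
## optimization. Covariances are represented by lower Cholesky factors; the
## reference group's factor is built from canonical partial correlations
## (tanh-transformed), which fixes its diagonal at 1 (a correlation matrix)
## for every value of the unconstrained vector, so the identification
## constraints hold by construction at every optimizer step.

## x (length K(K-1)/2, row-major over rows 2..K) -> lower Cholesky factor of
## a correlation matrix
.cpc_to_chol <- function(x, K) {
  L <- matrix(0, K, K)
  L[1, 1] <- 1
  pos <- 0
  for (i in seq_len(K)[-1]) {
    cp <- 1
    for (j in seq_len(i - 1)) {
      pos <- pos + 1
      y <- tanh(x[pos])
      L[i, j] <- y * cp
      cp <- cp * sqrt(1 - y^2)
    }
    L[i, i] <- cp
  }
  L
}

.chol_to_cpc <- function(L) {
  K <- nrow(L)
  x <- numeric(K * (K - 1) / 2)
  pos <- 0
  for (i in seq_len(K)[-1]) {
    cp <- 1
    for (j in seq_len(i - 1)) {
      pos <- pos + 1
      y <- L[i, j] / cp
      y <- pmin(pmax(y, -1 + 1e-12), 1 - 1e-12)
      x[pos] <- atanh(y)
      cp <- cp * sqrt(1 - y^2)
    }
  }
  x
}

## chain rule: gradient wrt L (lower, incl. diagonal) -> gradient wrt x
.cpc_chain <- function(gL, x, K) {
  gx <- numeric(length(x))
  L <- .cpc_to_chol(x, K)
  pos <- 0
  for (i in seq_len(K)[-1]) {
    cp <- 1
    row_pos <- pos
    for (j in seq_len(i - 1)) {
      pos <- pos + 1
      y <- tanh(x[pos])
      tail_sum <- if (j < i) sum(gL[i, (j + 1):i] * L[i, (j + 1):i]) else 0
      gx[pos] <- (1 - y^2) * cp * gL[i, j] - y * tail_sum
      cp <- cp * sqrt(1 - y^2)
    }
  }
  gx
}

## positions of the free (on-support, non-fixed) DIF entries of group g
.free_gamma_idx <- function(Q, fixed_gamma_g) {
  which(Q > 0 & !fixed_gamma_g)
}

#' @keywords internal
#' @noRd
encode_params <- function(params, Q, free_dif = TRUE, fixed_zeros = NULL) {
  J <- params$J; K <- params$K; G <- params$G
  if (is.null(fixed_zeros)) {
    fixed_zeros <- list(Gamma = array(FALSE, c(J, K, G)),
                        Beta = matrix(FALSE, G, J))
  }
  sup_idx <- which(Q > 0)
  lt <- which(lower.tri(matrix(0, K, K)))

  u <- c(params$A[sup_idx], params$B)
  idx <- list(A = seq_along(sup_idx), B = length(sup_idx) + seq_len(J))
  cursor <- length(u)
  idx$Gamma <- idx$Beta <- vector("list", G)
  gamma_pos <- vector("list", G)
  beta_free <- vector("list", G)
  if (free_dif && G > 1) {
    for (g in seq_len(G)[-1]) {
      gp <- .free_gamma_idx(Q, matrix(fixed_zeros$Gamma[, , g], J, K))
      gamma_pos[[g]] <- gp
      u <- c(u, matrix(params$Gamma[, , g], J, K)[gp])
      idx$Gamma[[g]] <- cursor + seq_along(gp); cursor <- cursor + length(gp)
      bf <- which(!fixed_zeros$Beta[g, ])
      beta_free[[g]] <- bf
      u <- c(u, params$Beta[g, bf])
      idx$Beta[[g]] <- cursor + seq_along(bf); cursor <- cursor + length(bf)
    }
  }
  idx$Mu <- vector("list", G)
  if (G > 1) {
    for (g in seq_len(G)[-1]) {
      u <- c(u, params$Mu[g, ])
      idx$Mu[[g]] <- cursor + seq_len(K); cursor <- cursor + K
    }
  }
  ## reference correlation via partial correlations
  L1 <- t(chol(matrix(params$Sigma[, , 1], K, K)))
  u <- c(u, .chol_to_cpc(L1))
  idx$ref <- if (K > 1) cursor + seq_len(K * (K - 1) / 2) else integer(0)
  cursor <- cursor + length(idx$ref)
  ## focal covariances: log-diagonal + free lower triangle of the factor
  idx$L <- vector("list", G)
  if (G > 1) {
    for (g in seq_len(G)[-1]) {
      Lg <- t(chol(matrix(params$Sigma[, , g], K, K)))
      u <- c(u, log(diag(Lg)), Lg[lt])
      idx$L[[g]] <- cursor + seq_len(K + length(lt))
      cursor <- cursor + K + length(lt)
    }
  }
  pen <- integer(0)
  if (free_dif && G > 1) {
    for (g in seq_len(G)[-1]) pen <- c(pen, idx$Beta[[g]], idx$Gamma[[g]])
  }
  meta <- list(J = J, K = K, G = G, Q = Q, sup_idx = sup_idx, lt = lt,
               idx = idx, gamma_pos = gamma_pos, beta_free = beta_free,
               free_dif = free_dif, fixed_zeros = fixed_zeros,
               pen_idx = sort(pen))
  list(u = u, meta = meta)
}

#' @keywords internal
#' @noRd
decode_params <- function(u, meta, want_L = FALSE) {
  J <- meta$J; K <- meta$K; G <- meta$G
  idx <- meta$idx
  A <- matrix(0, J, K); A[meta$sup_idx] <- u[idx$A]
  B <- u[idx$B]
  Gamma <- array(0, c(J, K, G)); Beta <- matrix(0, G, J)
  Mu <- matrix(0, G, K)
  Lcube <- array(0, c(K, K, G))
  if (meta$free_dif && G > 1) {
    for (g in seq_len(G)[-1]) {
      gm <- matrix(0, J, K); gm[meta$gamma_pos[[g]]] <- u[idx$Gamma[[g]]]
      Gamma[, , g] <- gm
      Beta[g, meta$beta_free[[g]]] <- u[idx$Beta[[g]]]
    }
  }
  if (G > 1) for (g in seq_len(G)[-1]) Mu[g, ] <- u[idx$Mu[[g]]]
  L1 <- .cpc_to_chol(u[idx$ref], K)
  Lcube[, , 1] <- L1
  Sigma <- array(0, c(K, K, G))
  Sigma[, , 1] <- tcrossprod(L1)
  if (G > 1) {
    for (g in seq_len(G)[-1]) {
      v <- u[idx$L[[g]]]
      Lg <- matrix(0, K, K)
      diag(Lg) <- exp(v[seq_len(K)])
      Lg[meta$lt] <- v[-seq_len(K)]
      Lcube[, , g] <- Lg
      Sigma[, , g] <- tcrossprod(Lg)
    }
  }
  p <- structure(list(A = A, B = B, Gamma = Gamma, Beta = Beta, Mu = Mu,
                      Sigma = Sigma, J = J, K = K, G = G),
                 class = "remirt_params")
  if (want_L) attr(p, "L") <- Lcube
  p
}

## chain the C++ gradient lists back to the unconstrained vector; `u` is the
## point the gradient was evaluated at and `Lcube` the decoded factors there
.chain_grad_u <- function(gr, meta, u, Lcube) {
  idx <- meta$idx
  K <- meta$K; G <- meta$G
  gu <- numeric(length(u))
  gu[idx$A] <- gr$gA[meta$sup_idx]
  gu[idx$B] <- gr$gB
  if (meta$free_dif && G > 1) {
    for (g in seq_len(G)[-1]) {
      gu[idx$Gamma[[g]]] <- matrix(gr$gGamma[, , g], meta$J, K)[meta$gamma_pos[[g]]]
      gu[idx$Beta[[g]]] <- gr$gBeta[g, meta$beta_free[[g]]]
    }
  }
  if (G > 1) for (g in seq_len(G)[-1]) gu[idx$Mu[[g]]] <- gr$gMu[g, ]
  if (K > 1) {
    gu[idx$ref] <- .cpc_chain(matrix(gr$gL[, , 1], K, K), u[idx$ref], K)
  }
  if (G > 1) {
    for (g in seq_len(G)[-1]) {
      gLg <- matrix(gr$gL[, , g], K, K)
      Lg <- matrix(Lcube[, , g], K, K)
      gu[idx$L[[g]]] <- c(diag(gLg) * diag(Lg), gLg[meta$lt])
    }
  }
  gu
}
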