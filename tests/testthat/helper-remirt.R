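## Shared fixture builders and independent oracles. Everything is generated
## in code under fixed seeds; no stored data.

## a small random valid parameter set over a between-item Q
rand_params <- function(J = 6, K = 2, G = 3, seed = 1) {
  set.seed(seed)
  Q <- matrix(0, J, K)
  Q[cbind(seq_len(J), rep_len(seq_len(K), J))] <- 1
  A <- Q * runif(J, 0.8, 2)
  B <- runif(J, -1, 1)
  Gamma <- array(0, c(J, K, G))
  Beta <- matrix(0, G, J)
  if (G > 1) {
    for (g in 2:G) {
      Beta[g, ] <- runif(J, -0.5, 0.5) * rbinom(J, 1, 0.5)
      gm <- Q * runif(J, -0.4, 0.4) * rbinom(J, 1, 0.5)
      Gamma[, , g] <- gm
    }
  }
  Mu <- matrix(0, G, K)
  Sigma <- array(0, c(K, K, G))
  ref <- matrix(0.5, K, K); diag(ref) <- 1
  Sigma[, , 1] <- ref
  if (G > 1) {
    for (g in 2:G) {
      Mu[g, ] <- runif(K, -0.3, 0.3)
      W <- matrix(rnorm(K * K, sd = 0.3), K, K)
      Sigma[, , g] <- diag(K) + crossprod(W)
    }
  }
  remirt_params(A, B, Gamma, Beta, Mu, Sigma)
}

## random dataset drawn from rand_params
rand_instance <- function(N = 40, J = 6, K = 2, G = 3, seed = 1) {
  p <- rand_params(J, K, G, seed)
  set.seed(seed + 1000)
  group <- sort(rep_len(seq_len(G), N))
  theta <- matrix(0, N, K)
  for (g in seq_len(G)) {
    rows <- which(group == g)
    L <- t(chol(matrix(p$Sigma[, , g], K, K)))
    theta[rows, ] <- sweep(matrix(rnorm(length(rows) * K), ncol = K) %*% t(L),
                           2, p$Mu[g, ], "+")
  }
  Q <- (p$A != 0) * 1
  Y <- matrix(0, N, J)
  for (i in seq_len(N)) {
    for (j in seq_len(J)) {
      pr <- irf_prob(p, j, group[i], theta[i, ])
      Y[i, j] <- rbinom(1, 1, pr)
    }
  }
  ## guard against degenerate items in tiny samples
  Y[1, ] <- 1; Y[2, ] <- 0
  list(params = p, data = remirt_data(Y, group, Q))
}

## random variational state
rand_varstate <- function(data, seed = 1) {
  set.seed(seed)
  vs <- list(mu = matrix(rnorm(data$N * data$K, sd = 0.5), data$N, data$K),
             sigma = array(0, c(data$K, data$K, data$N)),
             xi = matrix(runif(data$N * data$J, 0.3, 2), data$N, data$J))
  for (i in seq_len(data$N)) {
    W <- matrix(rnorm(data$K^2, sd = 0.2), data$K, data$K)
    vs$sigma[, , i] <- diag(data$K) * 0.8 + crossprod(W)
  }
  vs
}

## plain Monte-Carlo estimate of the marginal log-likelihood (oracle)
mc_marginal_loglik <- function(params, data, draws = 1e6, seed = 1) {
  set.seed(seed)
  total <- 0
  for (g in seq_len(data$G)) {
    rows <- which(data$group == g)
    if (length(rows) == 0) next
    L <- t(chol(matrix(params$Sigma[, , g], data$K, data$K)))
    theta <- sweep(matrix(rnorm(draws * data$K), ncol = data$K) %*% t(L),
                   2, params$Mu[g, ], "+")
    eff <- list(A = params$A + matrix(params$Gamma[, , g], data$J, data$K),
                B = params$B + params$Beta[g, ])
    X <- sweep(theta %*% t(eff$A), 2, eff$B, "+")
    sp <- rowSums(pmax(X, 0) + log1p(exp(-abs(X))))
    for (i in rows) {
      ll <- drop(X %*% data$Y[i, ]) - sp
      m <- max(ll)
      total <- total + m + log(mean(exp(ll - m)))
    }
  }
  total
}

## elbo as a function of one DIF coordinate, for numeric oracles
elbo_coord <- function(params, varstate, data, what, g, j, k = NULL) {
  function(x) {
    p <- params
    if (what == "beta") p$Beta[g, j] <- x
    if (what == "gamma") p$Gamma[j, k, g] <- x
    if (what == "b") p$B[j] <- x
    if (what == "a") p$A[j, k] <- x
    elbo(p, varstate, data)
  }
}

## data container with zero persons (for degenerate-input checks)
empty_data <- function(J = 3, K = 2) {
  Q <- matrix(0, J, K); Q[cbind(seq_len(J), rep_len(seq_len(K), J))] <- 1
  structure(list(Y = matrix(0, 0, J), group = integer(0), Q = Q,
                 N = 0L, J = J, K = K, G = 1L,
                 support = apply(Q > 0, 1, which, simplify = FALSE)),
            class = "remirt_data")
}

## write a dataset to CSV files in a temp dir
write_csv_fixture <- function(data, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  write.csv(data$Y, file.path(dir, "responses.csv"), row.names = FALSE)
  write.csv(data.frame(group = data$group), file.path(dir, "groups.csv"),
            row.names = FALSE)
  write.csv(data$Q, file.path(dir, "qmatrix.csv"), row.names = FALSE)
  dir
}
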