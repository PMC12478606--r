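#' Item response function on the logit and probability scale
#'
#' The re-MIRT model for a correct (or "yes") response of a person in group
#' g to item j at latent trait `theta` is
#' `P = plogis((A[j,] + Gamma[j,,g]) %*% theta + B[j] + Beta[g,j])`:
#' group-specific slope and intercept offsets against the reference group
#' carry all DIF, and the reference group's offsets are zero.
#'
#' @param params a [remirt_params] object.
#' @param j item index.
#' @param g group index (1 = reference).
#' @param theta length-K latent trait vector, or a matrix with K columns for
#'   several trait values at once.
#' @return The logit (`irf_logit`) or probability in (0,1) (`irf_prob`),
#'   vectorized over rows of `theta`.
#' @export
irf_logit <- function(params, j, g, theta) {
  if (j < 1 || j > params$J) stop("item index out of range")
  if (g < 1 || g > params$G) stop("group index out of range")
  eff <- .effective(params, g)
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  if (ncol(th) != params$K) stop("theta must have K = ", params$K, " columns")
  drop(th %*% eff$A[j, ] + eff$B[j])
}

#' @rdname irf_logit
#' @export
irf_prob <- function(params, j, g, theta) {
  .sigmoid(irf_logit(params, j, g, theta))
}

## product Gauss-Hermite grid for N(mu, Sigma): list(theta = nodes (T x K),
## logw = log weights incorporating the pi^{-K/2} normalization)
.gh_grid <- function(mu, Sigma, n_nodes) {
  K <- length(mu)
  gh <- pracma::gaussHermite(n_nodes)
  idx <- do.call(expand.grid, rep(list(seq_len(n_nodes)), K))
  Z <- matrix(gh$x[as.matrix(idx)], ncol = K)
  logw <- rowSums(matrix(log(gh$w)[as.matrix(idx)], ncol = K)) - K / 2 * log(pi)
  L <- t(chol(Sigma))
  theta <- sweep(sqrt(2) * Z %*% t(L), 2, mu, "+")
  list(theta = theta, logw = logw)
}

## log p(Y_i | theta_t) for all persons in rows of Ysub, all nodes theta
.cond_loglik_nodes <- function(Ysub, Aeff, Beff, theta) {
  X <- theta %*% t(Aeff)                # T x J logits
  X <- sweep(X, 2, Beff, "+")
  sp <- rowSums(.softplus(X))           # sum_j softplus(x_tj)
  X %*% t(Ysub) - sp                    # T x n matrix of log-likelihoods
}

#' Marginal log-likelihood by product Gauss-Hermite quadrature
#'
#' Evaluates the multi-group marginal log-likelihood
#' `sum_i log \int p(Y_i | theta) N(theta; Mu[g(i),], Sigma[,,g(i)]) dtheta`
#' by a product Gauss-Hermite rule transformed to each group's Gaussian.
#' Intended as an accuracy reference for K <= 3 only; the fitting
#' algorithms never use it.
#'
#' @param params a [remirt_params] object.
#' @param data a [remirt_data] object.
#' @param n_nodes quadrature nodes per dimension (>= 5; 21 is accurate for
#'   logits bounded by ~10).
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik_gh <- function(params, data, n_nodes = 21) {
  if (data$K > 3) stop("quadrature reference supports K <= 3 only")
  if (n_nodes < 5) stop("n_nodes must be at least 5")
  total <- 0
  for (g in seq_len(data$G)) {
    rows <- which(data$group == g)
    if (length(rows) == 0) next
    grid <- .gh_grid(params$Mu[g, ], matrix(params$Sigma[, , g], data$K, data$K),
                     n_nodes)
    eff <- .effective(params, g)
    ll <- .cond_loglik_nodes(data$Y[rows, , drop = FALSE], eff$A, eff$B,
                             grid$theta)
    lw <- ll + grid$logw
    m <- apply(lw, 2, max)
    total <- total + sum(m + log(colSums(exp(sweep(lw, 2, m, "-")))))
  }
  total
}

#' Lasso-penalized marginal log-likelihood
#'
#' The quadrature marginal log-likelihood minus `N * lambda` times the L1
#' norm of all DIF parameters of the non-reference groups. The factor N
#' makes `lambda` sample-size free, matching the proximal step used in
#' estimation.
#'
#' @inheritParams marginal_loglik_gh
#' @param lambda nonnegative tuning parameter.
#' @export
penalized_loglik <- function(params, data, lambda, n_nodes = 21) {
  if (lambda < 0) stop("lambda must be nonnegative")
  pen <- sum(abs(params$Beta[-1, , drop = FALSE])) +
    sum(abs(params$Gamma[, , -1, drop = FALSE]))
  marginal_loglik_gh(params, data, n_nodes) - data$N * lambda * pen
}

#' Direct marginal maximum likelihood fit by quadrature (reference fitter)
#'
#' Maximizes the Gauss-Hermite marginal log-likelihood directly with a
#' quasi-Newton optimizer over the identified parameterization (on-support
#' slopes, intercepts, focal-group means and covariance Cholesky factors,
#' reference correlation angles). DIF parameters are held at zero, so this
#' fits the multi-group MIRT model with impact but without DIF. Only
#' feasible for small K and J; used as an independent accuracy reference
#' for the variational estimators.
#'
#' @inheritParams marginal_loglik_gh
#' @param start optional [remirt_params] starting values.
#' @param n_nodes quadrature nodes per dimension.
#' @return A list with the fitted `params`, the maximized `loglik`, and the
#'   `optim` convergence code.
#' @export
fit_mml_gh <- function(data, start = NULL, n_nodes = 21) {
  if (data$K > 3) stop("quadrature fitter supports K <= 3 only")
  if (is.null(start)) start <- .init_params(data)
  enc <- encode_params(start, data$Q, free_dif = FALSE)
  ## guard against degenerate excursions of the optimizer: covariance
  ## factors can underflow (Cholesky error), and at absurd parameter values
  ## the quadrature sum cancels catastrophically and can even turn
  ## positive, which is impossible for a true binary-data log-likelihood
  ## (it is bounded above by 0). Treat both as very poor fits.
  obj <- function(u) {
    p <- decode_params(u, enc$meta)
    v <- tryCatch(-marginal_loglik_gh(p, data, n_nodes),
                  error = function(e) Inf)
    if (!is.finite(v) || v < 0) v <- 1e10
    v
  }
  opt <- optim(enc$u, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(params = decode_params(opt$par, enc$meta), loglik = -opt$value,
       convergence = opt$convergence)
}
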