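#' Construct a validated re-MIRT parameter set
#'
#' The model's structural parameters: item slopes and intercepts, per-group
#' DIF offsets, and group latent trait means and covariances. Group 1 is the
#' reference: its DIF blocks are zero, its latent mean is zero, and its
#' latent covariance has unit diagonal (a correlation matrix), which
#' identifies the latent scale.
#'
#' @param A J x K slope matrix; entries off the Q-matrix support must be 0.
#' @param B length-J intercept vector. The item response function uses the
#'   slope-intercept convention `logit = (A[j,] + Gamma[j,,g]) %*% theta +
#'   (B[j] + Beta[g,j])`; a difficulty-style parameterization is recovered
#'   by negating `B` and `Beta`.
#' @param Gamma J x K x G array of slope DIF offsets; slice `[,,g]` is the
#'   DIF of group g against the reference. `Gamma[,,1]` must be 0.
#' @param Beta G x J matrix of intercept DIF offsets; `Beta[1,]` must be 0.
#' @param Mu G x K matrix of group latent means; `Mu[1,]` must be 0.
#' @param Sigma K x K x G array of group latent covariances, each symmetric
#'   positive definite; `diag(Sigma[,,1])` must equal 1.
#' @return An object of class `remirt_params`.
#' @export
remirt_params <- function(A, B, Gamma, Beta, Mu, Sigma) {
  A <- as.matrix(A); B <- as.numeric(B)
  J <- nrow(A); K <- ncol(A)
  Gamma <- array(Gamma, dim = c(J, K, dim(Gamma)[3]))
  G <- dim(Gamma)[3]
  Beta <- matrix(Beta, G, J)
  Mu <- matrix(Mu, G, K)
  Sigma <- array(Sigma, dim = c(K, K, G))
  p <- structure(list(A = A, B = B, Gamma = Gamma, Beta = Beta,
                      Mu = Mu, Sigma = Sigma, J = J, K = K, G = G),
                 class = "remirt_params")
  .check_params(p)
  p
}

.check_params <- function(p, tol = 1e-8) {
  stopifnot(length(p$B) == p$J, nrow(p$Beta) == p$G, ncol(p$Beta) == p$J)
  if (max(abs(p$Gamma[, , 1])) > 0 || max(abs(p$Beta[1, ])) > 0)
    stop("reference-group DIF parameters must be zero")
  if (max(abs(p$Mu[1, ])) > 0)
    stop("reference-group latent mean must be zero")
  if (max(abs(diag(p$Sigma[, , 1, drop = TRUE]) - 1)) > tol && p$K >= 1) {
    d <- diag(matrix(p$Sigma[, , 1], p$K, p$K))
    if (max(abs(d - 1)) > tol)
      stop("reference-group latent covariance must have unit diagonal")
  }
  for (g in seq_len(p$G)) {
    S <- matrix(p$Sigma[, , g], p$K, p$K)
    if (max(abs(S - t(S))) > tol) stop("Sigma[,,", g, "] is not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("Sigma[,,", g, "] is not positive definite")
  }
  invisible(p)
}

## deterministic starting values: A = Q, B = clipped logit of proportion
## correct, no DIF, standard-normal latent structure
.init_params <- function(data) {
  p_hat <- colMeans(data$Y)
  B <- pmin(pmax(qlogis(pmin(pmax(p_hat, 1e-6), 1 - 1e-6)), -3), 3)
  if (any(p_hat == 0 | p_hat == 1)) {
    warning("item(s) ", paste(which(p_hat %in% c(0, 1)), collapse = ", "),
            " have degenerate (all-0 or all-1) responses; intercept start clipped")
  }
  remirt_params(
    A = data$Q, B = B,
    Gamma = array(0, c(data$J, data$K, data$G)),
    Beta = matrix(0, data$G, data$J),
    Mu = matrix(0, data$G, data$K),
    Sigma = array(diag(data$K), c(data$K, data$K, data$G))
  )
}

.init_varstate <- function(data) {
  list(mu = matrix(0, data$N, data$K),
       sigma = array(diag(data$K), c(data$K, data$K, data$N)),
       xi = matrix(1, data$N, data$J))
}

## effective slopes/intercepts of group g
.effective <- function(params, g) {
  list(A = params$A + matrix(params$Gamma[, , g], params$J, params$K),
       B = params$B + params$Beta[g, ])
}

#' Rescale parameters onto the identified latent scale
#'
#' Divides each latent dimension by the reference group's latent standard
#' deviation so that `diag(Sigma[,,1]) = 1`, absorbing the scale into the
#' slopes. Response probabilities are unchanged. When a variational state is
#' supplied it is transformed along with the latent scale so that the
#' variational bound is unchanged as well.
#'
#' @param params a [remirt_params] object with positive-definite `Sigma[,,1]`.
#' @param varstate optional variational state (as stored in fit results) to
#'   transform consistently.
#' @return The rescaled `remirt_params`, or `list(params, varstate)` when
#'   `varstate` is supplied.
#' @export
rescale_identify <- function(params, varstate = NULL) {
  d <- diag(matrix(params$Sigma[, , 1], params$K, params$K))
  if (any(d <= 0)) stop("reference covariance has nonpositive diagonal")
  d <- sqrt(d)
  params$A <- sweep(params$A, 2, d, "*")
  for (g in seq_len(params$G)) {
    params$Gamma[, , g] <- sweep(matrix(params$Gamma[, , g], params$J, params$K), 2, d, "*")
    params$Sigma[, , g] <- matrix(params$Sigma[, , g], params$K, params$K) / outer(d, d)
  }
  params$Mu <- sweep(params$Mu, 2, d, "/")
  params$Mu[1, ] <- 0
  if (is.null(varstate)) return(params)
  varstate$mu <- sweep(varstate$mu, 2, d, "/")
  for (i in seq_len(dim(varstate$sigma)[3])) {
    varstate$sigma[, , i] <- matrix(varstate$sigma[, , i], params$K, params$K) / outer(d, d)
  }
  list(params = params, varstate = varstate)
}

#' @export
print.remirt_params <- function(x, ...) {
  cat("re-MIRT parameters:", x$J, "items,", x$K, "dimensions,", x$G, "groups\n")
  ndif <- sum(x$Beta[-1, , drop = FALSE] != 0) +
    sum(x$Gamma[, , -1, drop = FALSE] != 0)
  cat("  nonzero DIF entries:", ndif, "\n")
  invisible(x)
}
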