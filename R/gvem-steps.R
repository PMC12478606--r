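#' Local variational curvature function
#'
#' `eta_xi(xi) = tanh(xi/2) / (4*xi)`, continuously extended to `1/8` at 0.
#' This is the curvature of the quadratic lower bound on the logistic
#' log-likelihood at local variational parameter `xi`; it lies in (0, 1/8]
#' and is nonincreasing.
#'
#' @param xi nonnegative numeric vector.
#' @export
eta_xi <- function(xi) {
  if (any(xi < 0)) stop("xi must be nonnegative")
  out <- rep(0.125, length(xi))
  nz <- xi > 1e-8
  out[nz] <- tanh(xi[nz] / 2) / (4 * xi[nz])
  if (!is.null(dim(xi))) dim(out) <- dim(xi)
  out
}

#' Quadratic lower bound on the Bernoulli-logit log-likelihood
#'
#' The local variational bound
#' `log plogis(xi) + (y - 1/2) x - xi/2 - eta_xi(xi) (x^2 - xi^2)`
#' on `y*x - log(1 + exp(x))`. The bound is tight exactly at `xi = |x|`.
#'
#' @param y response in \{0, 1\}.
#' @param logit linear predictor x.
#' @param xi nonnegative local variational parameter.
#' @export
quadratic_bound_conditional <- function(y, logit, xi) {
  if (any(xi < 0)) stop("xi must be nonnegative")
  -.softplus(-xi) + (y - 0.5) * logit - xi / 2 - eta_xi(xi) * (logit^2 - xi^2)
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - t, 0)`, the proximal operator of the absolute value.
#'
#' @param z numeric.
#' @param t nonnegative threshold.
#' @export
soft_threshold <- function(z, t) {
  if (any(t < 0)) stop("threshold must be nonnegative")
  sign(z) * pmax(abs(z) - t, 0)
}

## E[x_ij^2] under q_i for all items of person i's group:
## a~' (Sigma* + mu* mu*') a~ + 2 b~ a~' mu* + b~^2
.exx_person <- function(eff, mu_i, sigma_i) {
  M <- sigma_i + tcrossprod(mu_i)
  am <- drop(eff$A %*% mu_i)
  aMa <- rowSums((eff$A %*% M) * eff$A)
  aMa + 2 * eff$B * am + eff$B^2
}

#' Closed-form E-step update for one person
#'
#' Maximizes the variational bound over person i's Gaussian variational
#' distribution given the current local parameters `xi_row`:
#' the posterior-like precision is `solve(Sigma_g) + 2 * sum_j eta(xi_ij)
#' a_gj a_gj'` and the mean solves the corresponding linear system.
#'
#' @param params a [remirt_params] object.
#' @param data a [remirt_data] object.
#' @param i person index.
#' @param xi_row length-J nonnegative vector of local variational parameters.
#' @return `list(mu, sigma)`: the updated variational mean and covariance.
#' @export
e_step_person <- function(params, data, i, xi_row) {
  g <- data$group[i]
  eff <- .effective(params, g)
  et <- eta_xi(xi_row)
  Sg <- matrix(params$Sigma[, , g], data$K, data$K)
  Sg_inv <- solve(Sg)
  P <- Sg_inv + 2 * t(eff$A) %*% (et * eff$A)
  h <- drop(Sg_inv %*% params$Mu[g, ]) +
    drop(t(eff$A) %*% (data$Y[i, ] - 0.5 - 2 * et * eff$B))
  sigma <- solve(P)
  sigma <- (sigma + t(sigma)) / 2
  list(mu = drop(sigma %*% h), sigma = sigma)
}

#' Update the local variational parameters
#'
#' Sets `xi_ij^2 = E[x_ij^2]` under the current variational moments (the
#' bound's maximizer in `xi`), returning the positive root. A numerically
#' negative square is clamped at zero with a warning.
#'
#' @inheritParams e_step_person
#' @param varstate list with variational means `mu` (N x K) and covariances
#'   `sigma` (K x K x N).
#' @return N x J matrix of updated `xi`.
#' @export
update_xi <- function(params, varstate, data) {
  xi2 <- matrix(0, data$N, data$J)
  effs <- lapply(seq_len(data$G), .effective, params = params)
  for (i in seq_len(data$N)) {
    xi2[i, ] <- .exx_person(effs[[data$group[i]]], varstate$mu[i, ],
                            matrix(varstate$sigma[, , i], data$K, data$K))
  }
  if (any(xi2 < 0)) {
    if (any(xi2 < -1e-8)) warning("negative xi^2 clamped at 0")
    xi2[xi2 < 0] <- 0
  }
  sqrt(xi2)
}

## sum over items/persons of the bound terms given precomputed pieces
.bound_items_person <- function(y_i, eff, mu_i, sigma_i, xi_i) {
  ex <- drop(eff$A %*% mu_i) + eff$B
  exx <- .exx_person(eff, mu_i, sigma_i)
  sum(-.softplus(-xi_i) + (y_i - 0.5) * ex - xi_i / 2 -
        eta_xi(xi_i) * (exx - xi_i^2))
}

#' Variational evidence lower bound
#'
#' The GVEM objective: the quadratic-bound expected conditional
#' log-likelihood plus the Gaussian prior cross-entropy and the variational
#' entropy. It never exceeds the marginal log-likelihood.
#'
#' @inheritParams update_xi
#' @return The bound value (scalar; 0 for empty data).
#' @export
elbo <- function(params, varstate, data) {
  if (data$N == 0) return(0)
  effs <- lapply(seq_len(data$G), .effective, params = params)
  Sg_inv <- list(); logdetS <- numeric(data$G)
  for (g in seq_len(data$G)) {
    Sg <- matrix(params$Sigma[, , g], data$K, data$K)
    Sg_inv[[g]] <- solve(Sg)
    logdetS[g] <- determinant(Sg, logarithm = TRUE)$modulus
  }
  total <- 0
  for (i in seq_len(data$N)) {
    g <- data$group[i]
    mu_i <- varstate$mu[i, ]
    sig_i <- matrix(varstate$sigma[, , i], data$K, data$K)
    total <- total + .bound_items_person(data$Y[i, ], effs[[g]], mu_i, sig_i,
                                         varstate$xi[i, ])
    r <- mu_i - params$Mu[g, ]
    total <- total + 0.5 * (determinant(sig_i, logarithm = TRUE)$modulus -
                              logdetS[g] - sum(Sg_inv[[g]] * sig_i) -
                              drop(t(r) %*% Sg_inv[[g]] %*% r) + data$K)
  }
  as.numeric(total)
}

## --- M-step pieces (coordinate ascent; each holds the others fixed) ------

.update_B <- function(params, varstate, data, eta_mat) {
  for (j in seq_len(data$J)) {
    am <- numeric(data$N)
    for (g in seq_len(data$G)) {
      rows <- data$group == g
      aeff <- params$A[j, ] + params$Gamma[j, , g]
      am[rows] <- varstate$mu[rows, , drop = FALSE] %*% aeff +
        params$Beta[g, j]
    }
    num <- sum(data$Y[, j] - 0.5 - 2 * eta_mat[, j] * am)
    params$B[j] <- num / (2 * sum(eta_mat[, j]))
  }
  params
}

.update_A <- function(params, varstate, data, eta_mat, Mlist, ridge = 1e-8) {
  for (j in seq_len(data$J)) {
    S <- data$support[[j]]
    lhs <- matrix(0, length(S), length(S))
    rhs <- numeric(length(S))
    for (i in seq_len(data$N)) {
      g <- data$group[i]
      e2 <- 2 * eta_mat[i, j]
      MSS <- Mlist[[i]][S, S, drop = FALSE]
      btil <- params$B[j] + params$Beta[g, j]
      lhs <- lhs + e2 * MSS
      rhs <- rhs + (data$Y[i, j] - 0.5 - e2 * btil) * varstate$mu[i, S] -
        e2 * drop(MSS %*% params$Gamma[j, S, g])
    }
    a <- tryCatch(solve(lhs, rhs), error = function(e) {
      solve(lhs + diag(ridge, length(S)), rhs)
    })
    params$A[j, S] <- a
  }
  params
}

.update_mu_sigma <- function(params, varstate, data) {
  for (g in seq_len(data$G)) {
    rows <- which(data$group == g)
    if (g > 1) params$Mu[g, ] <- colMeans(varstate$mu[rows, , drop = FALSE])
    S <- matrix(0, data$K, data$K)
    for (i in rows) {
      r <- varstate$mu[i, ] - params$Mu[g, ]
      S <- S + matrix(varstate$sigma[, , i], data$K, data$K) + tcrossprod(r)
    }
    params$Sigma[, , g] <- S / length(rows)
  }
  params
}

#' Closed-form M-step for the structural parameters
#'
#' Updates, in order, the intercepts `B`, the on-support slopes `A` (one
#' small linear system per item, pooling all groups with the DIF offsets
#' fixed), the focal-group latent means, and the group latent covariances.
#' Each update maximizes the variational bound in its own block with the
#' other blocks held fixed.
#'
#' @inheritParams update_xi
#' @return The updated [remirt_params].
#' @export
m_step_structural <- function(params, varstate, data) {
  eta_mat <- eta_xi(varstate$xi)
  Mlist <- lapply(seq_len(data$N), function(i) {
    matrix(varstate$sigma[, , i], data$K, data$K) + tcrossprod(varstate$mu[i, ])
  })
  params <- .update_B(params, varstate, data, eta_mat)
  params <- .update_A(params, varstate, data, eta_mat, Mlist)
  params <- .update_mu_sigma(params, varstate, data)
  params
}

#' Penalized coordinate update of the DIF parameters
#'
#' For every free DIF entry (non-reference group, on the Q-matrix support,
#' and not in `fixed_zeros`), replaces the entry by the exact maximizer of
#' the variational bound plus the Lasso penalty `-N * lambda * |x|` in that
#' coordinate: `soft_threshold(curvature * x + gradient, N * lambda) /
#' curvature`. The bound is exactly quadratic in each DIF coordinate, so
#' the update is exact, and the curvature is positive by construction.
#' Entries are visited group by group, item by item, intercept before
#' slopes; entries in `fixed_zeros` stay at zero.
#'
#' @inheritParams update_xi
#' @param lambda nonnegative tuning parameter (`lambda = 0` gives the
#'   unpenalized coordinate update).
#' @param fixed_zeros optional list with logical arrays `Gamma` (J x K x G)
#'   and `Beta` (G x J) marking entries held at zero.
#' @return The updated [remirt_params].
#' @export
update_dif_penalized <- function(params, varstate, data, lambda,
                                 fixed_zeros = NULL) {
  if (lambda < 0) stop("lambda must be nonnegative")
  thr <- data$N * lambda
  eta_mat <- eta_xi(varstate$xi)
  Mlist <- lapply(seq_len(data$N), function(i) {
    matrix(varstate$sigma[, , i], data$K, data$K) + tcrossprod(varstate$mu[i, ])
  })
  for (g in seq_len(params$G)[-1]) {
    rows <- which(data$group == g)
    for (j in seq_len(data$J)) {
      S <- data$support[[j]]
      ## intercept DIF
      if (is.null(fixed_zeros) || !fixed_zeros$Beta[g, j]) {
        aeff <- params$A[j, ] + params$Gamma[j, , g]
        d <- 0; cv <- 0
        for (i in rows) {
          am <- sum(aeff * varstate$mu[i, ])
          d <- d + data$Y[i, j] - 0.5 -
            2 * eta_mat[i, j] * (am + params$B[j] + params$Beta[g, j])
          cv <- cv + 2 * eta_mat[i, j]
        }
        if (cv <= 0) stop("nonpositive curvature in DIF update")
        params$Beta[g, j] <- soft_threshold(cv * params$Beta[g, j] + d, thr) / cv
      }
      ## slope DIF, one support dimension at a time
      for (k in S) {
        if (!is.null(fixed_zeros) && fixed_zeros$Gamma[j, k, g]) next
        aeff <- params$A[j, ] + params$Gamma[j, , g]
        btil <- params$B[j] + params$Beta[g, j]
        d <- 0; cv <- 0
        for (i in rows) {
          Ma <- drop(Mlist[[i]] %*% aeff)
          d <- d + (data$Y[i, j] - 0.5) * varstate$mu[i, k] -
            2 * eta_mat[i, j] * (Ma[k] + btil * varstate$mu[i, k])
          cv <- cv + 2 * eta_mat[i, j] * Mlist[[i]][k, k]
        }
        if (cv <= 0) stop("nonpositive curvature in DIF update")
        params$Gamma[j, k, g] <-
          soft_threshold(cv * params$Gamma[j, k, g] + d, thr) / cv
      }
    }
  }
  params
}

## one full GVEM cycle (E, xi, M, DIF, identify) -- reference R engine
.gvem_cycle_r <- function(params, varstate, data, lambda, fixed_zeros = NULL) {
  for (i in seq_len(data$N)) {
    es <- e_step_person(params, data, i, varstate$xi[i, ])
    varstate$mu[i, ] <- es$mu
    varstate$sigma[, , i] <- es$sigma
  }
  varstate$xi <- update_xi(params, varstate, data)
  params <- m_step_structural(params, varstate, data)
  if (data$G > 1) {
    params <- update_dif_penalized(params, varstate, data, lambda, fixed_zeros)
  }
  res <- rescale_identify(params, varstate)
  res$bound <- elbo(res$params, res$varstate, data)
  if (lambda > 0) {
    res$bound <- res$bound - lambda * data$N *
      (sum(abs(res$params$Beta)) + sum(abs(res$params$Gamma)))
  }
  res
}
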