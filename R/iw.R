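#' Draw latent-trait samples from the variational distributions
#'
#' Draws `M` i.i.d. samples per person from that person's fitted Gaussian
#' variational distribution. The samples are drawn once per dataset and
#' reused, unchanged, for every tuning parameter of the importance-weighted
#' path; the log proposal densities are stored with the draws.
#'
#' @param varstate variational state (means `mu` N x K, covariances `sigma`
#'   K x K x N) from a converged GVEM run.
#' @param M number of samples per person (>= 1).
#' @param seed integer seed; the same seed reproduces identical draws.
#' @return An object of class `remirt_iw_samples`: list with `theta`
#'   ((N*M) x K matrix, person-major), `logq` (log proposal densities),
#'   `M`, and `seed`.
#' @export
draw_iw_samples <- function(varstate, M, seed) {
  if (M < 1) stop("M must be at least 1")
  N <- nrow(varstate$mu); K <- ncol(varstate$mu)
  Z <- .with_seed(seed, matrix(rnorm(N * M * K), N * M, K))
  theta <- matrix(0, N * M, K)
  logq <- numeric(N * M)
  for (i in seq_len(N)) {
    L <- t(chol(matrix(varstate$sigma[, , i], K, K)))
    rows <- (i - 1) * M + seq_len(M)
    theta[rows, ] <- sweep(Z[rows, , drop = FALSE] %*% t(L), 2,
                           varstate$mu[i, ], "+")
    z <- Z[rows, , drop = FALSE]
    logq[rows] <- -0.5 * rowSums(z^2) - sum(log(diag(L))) -
      0.5 * K * log(2 * pi)
  }
  structure(list(theta = theta, logq = logq, M = as.integer(M),
                 seed = as.integer(seed)),
            class = "remirt_iw_samples")
}

#' Importance-weighted evidence lower bound
#'
#' `sum_i log mean_m w_im` with importance weights
#' `w_im = p(Y_i | theta_im) N(theta_im; Mu[g,], Sigma[,,g]) / q_i(theta_im)`,
#' computed in log space. Tighter than the GVEM bound and converging to the
#' marginal log-likelihood as `M` grows.
#'
#' @param params a [remirt_params] object.
#' @param samples a [draw_iw_samples] object drawn from the variational
#'   distributions used as proposal.
#' @param data a [remirt_data] object.
#' @export
iw_elbo <- function(params, samples, data) {
  if (is.unsorted(data$group)) {
    s <- .sort_by_group(data)
    data <- s$data
    samples <- .sort_samples(samples, s$ord)
  }
  Lc <- array(0, c(params$K, params$K, params$G))
  for (g in seq_len(params$G)) {
    Lc[, , g] <- t(chol(matrix(params$Sigma[, , g], params$K, params$K)))
  }
  out <- iw_value_grad_cpp(data$Y, as.integer(data$group - 1L),
                           params$A, params$B, params$Gamma, params$Beta,
                           params$Mu, Lc, samples$theta, samples$logq,
                           samples$M, FALSE)
  if (!is.finite(out$value)) stop("non-finite importance weight encountered")
  out$value
}

## reorder persons so each group is a contiguous block (the compiled kernel
## is blocked per group; the bound and gradient are order-invariant)
.sort_by_group <- function(data) {
  ord <- order(data$group)
  data$Y <- data$Y[ord, , drop = FALSE]
  data$group <- data$group[ord]
  list(data = data, ord = ord)
}

.sort_samples <- function(samples, ord) {
  rows <- rep((ord - 1L) * samples$M, each = samples$M) + seq_len(samples$M)
  samples$theta <- samples$theta[rows, , drop = FALSE]
  samples$logq <- samples$logq[rows]
  samples
}

## value and gradient of iw_elbo with respect to the unconstrained vector u
.iw_value_grad_u <- function(u, meta, samples, data) {
  p <- decode_params(u, meta, want_L = TRUE)
  Lc <- attr(p, "L")
  out <- iw_value_grad_cpp(data$Y, as.integer(data$group - 1L),
                           p$A, p$B, p$Gamma, p$Beta, p$Mu, Lc,
                           samples$theta, samples$logq, samples$M, TRUE)
  list(value = out$value, grad = .chain_grad_u(out, meta, u, Lc))
}

## penalized minimization objective: -iw_elbo + N * lambda * ||DIF||_1
.iw_objective_u <- function(u, meta, samples, data, lambda) {
  p <- decode_params(u, meta)
  -iw_elbo(p, samples, data) +
    data$N * lambda * sum(abs(u[meta$pen_idx]))
}

#' Proximal gradient update for a Lasso-penalized coordinate
#'
#' `soft_threshold(x - s * grad, s * N * lambda)`: a gradient step of size
#' `s` followed by the proximal operator of the penalty `N * lambda * |x|`.
#' With `lambda = 0` this is a plain gradient step. In the IW-GVEMM
#' optimizer `s` is the coordinate's own Adam adaptive step size.
#'
#' @param x current value.
#' @param grad gradient of the smooth part at `x`.
#' @param s positive step size.
#' @param lambda nonnegative tuning parameter.
#' @param N sample size (the penalty is `N * lambda * |x|`).
#' @export
proximal_update <- function(x, grad, s, lambda, N) {
  if (any(s <= 0)) stop("step size must be positive")
  soft_threshold(x - s * grad, s * N * lambda)
}

## Adam with per-coordinate proximal soft-thresholding on the penalized
## coordinates. Coordinates in `fixed_idx` are clamped at zero.
.adam_prox <- function(u, meta, samples, data, lambda, control,
                       pen_idx = meta$pen_idx, fixed_idx = integer(0)) {
  m <- v <- numeric(length(u))
  u[fixed_idx] <- 0
  stable <- 0L
  trace <- numeric(0)
  converged <- FALSE
  npen <- data$N * lambda
  step <- 0L
  for (step in seq_len(control$adam_max_iter)) {
    vg <- .iw_value_grad_u(u, meta, samples, data)
    if (!is.finite(vg$value)) {
      return(list(u = u, trace = trace, converged = FALSE, n_iter = step,
                  diverged = TRUE))
    }
    trace <- c(trace, -vg$value + npen * sum(abs(u[pen_idx])))
    g <- -vg$grad
    g[fixed_idx] <- 0
    m <- control$adam_beta1 * m + (1 - control$adam_beta1) * g
    v <- control$adam_beta2 * v + (1 - control$adam_beta2) * g^2
    mhat <- m / (1 - control$adam_beta1^step)
    vhat <- v / (1 - control$adam_beta2^step)
    lr <- control$adam_lr / (1 + control$adam_decay * step)
    s <- lr / (sqrt(vhat) + control$adam_eps)
    unew <- u - s * mhat
    if (length(pen_idx) > 0 && lambda > 0) {
      unew[pen_idx] <- proximal_update(u[pen_idx], mhat[pen_idx], s[pen_idx],
                                       lambda, data$N)
    }
    unew[fixed_idx] <- 0
    delta <- max(abs(unew - u))
    u <- unew
    stable <- if (delta < control$adam_tol) stable + 1L else 0L
    if (stable >= control$adam_window) { converged <- TRUE; break }
  }
  list(u = u, trace = trace, converged = converged, n_iter = step,
       diverged = FALSE)
}

#' Fit the importance-weighted GVEM (IW-GVEMM) path
#'
#' Runs the unpenalized GVEM algorithm for starting values and proposal
#' distributions, transforms the parameters to an unconstrained scale
#' (Cholesky factors; the reference correlation through partial
#' correlations, so the identification constraints hold at every step),
#' draws the importance samples once, and then for each `lambda` maximizes
#' the penalized importance-weighted bound with Adam plus proximal
#' soft-thresholding on the DIF coordinates, followed by an unpenalized
#' debiasing run holding the zero pattern fixed. Every `lambda` starts from
#' the same GVEM initial state.
#'
#' @inheritParams fit_gvem
#' @param M importance samples per person.
#' @param seed integer seed for the (single) sampling step.
#' @return A `remirt_path` object with `method = "iwgvemm"`; fit bounds are
#'   importance-weighted bound values.
#' @export
fit_iw_gvemm <- function(data, lambda = default_lambda_grid(), M = 10,
                         seed = 1L, control = remirt_control(),
                         fixed_zeros = NULL) {
  stopifnot(length(lambda) > 0, !is.unsorted(lambda), all(lambda >= 0))
  fixed <- .as_fixed(data, fixed_zeros)
  warm <- .gvem_warm_start(data, control, fixed)
  enc <- encode_params(warm$params, data$Q, free_dif = data$G > 1,
                       fixed_zeros = fixed)
  samples <- draw_iw_samples(warm$varstate, M, seed)
  srt <- .sort_by_group(data)
  path <- structure(list(fits = list(), lambda = numeric(0),
                         method = "iwgvemm", N = data$N, warm = warm,
                         fixed = fixed, control = control, enc = enc,
                         samples = samples, sdata = srt$data,
                         ssamples = .sort_samples(samples, srt$ord)),
                    class = "remirt_path")
  for (lam in lambda) path <- .iw_fit_one(path, data, lam)
  path
}

.iw_fit_one <- function(path, data, lam) {
  enc <- path$enc; control <- path$control
  samples <- path$ssamples
  data <- path$sdata
  meta <- enc$meta
  pen <- .adam_prox(enc$u, meta, samples, data, lam, control)
  if (pen$diverged) {
    warning("IW optimizer diverged at lambda = ", signif(lam, 3))
    fit <- list(params = decode_params(pen$u, meta), bound = NA_real_,
                zero_pattern = NULL, df = NA_integer_, trace = pen$trace,
                n_iter = pen$n_iter, converged = FALSE, lambda = lam,
                diverged = TRUE)
  } else {
    if (!pen$converged) {
      warning("penalized IW optimization did not converge at lambda = ",
              signif(lam, 3))
    }
    zero_u <- meta$pen_idx[pen$u[meta$pen_idx] == 0]
    dctrl <- control
    dctrl$adam_lr <- control$adam_lr_debias
    db <- .adam_prox(pen$u, meta, samples, data, 0, dctrl,
                     fixed_idx = zero_u)
    params <- decode_params(db$u, meta)
    zp <- .zero_pattern(params, data, path$fixed)
    fit <- list(params = params, bound = iw_elbo(params, samples, data),
                zero_pattern = zp,
                df = .count_df_params(params, data, path$fixed),
                trace = db$trace, trace_penalized = pen$trace,
                n_iter = pen$n_iter + db$n_iter,
                converged = pen$converged && db$converged, lambda = lam,
                diverged = FALSE)
  }
  path$fits[[length(path$fits) + 1L]] <- fit
  path$lambda <- c(path$lambda, lam)
  path
}
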