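#' Generate re-MIRT parameters for a multi-group DIF study design
#'
#' Emulates the standard three-group DIF study: one reference group and two
#' focal groups, the first with low and the second with high DIF. Items
#' follow a between-item structure (each item loads on exactly one
#' dimension, `J_per_dim` items per dimension). Reference slopes are drawn
#' uniformly from `a_range` on the loading dimension and intercepts
#' uniformly from `b_range`; these generating distributions are stand-in
#' defaults in typical 2PL ranges and are fully configurable. A fraction
#' `dif_proportion` of the items of every dimension receives DIF in both
#' focal groups: uniform DIF perturbs only the intercepts
#' (`Beta = +/- dif_sizes[g-1]`), non-uniform DIF additionally perturbs the
#' loading slope by the same magnitude. With `balanced = TRUE` the DIF
#' signs alternate over the DIF items so positive and negative effects
#' cancel on average, keeping DIF distinguishable from impact even at high
#' DIF proportions.
#'
#' @param K number of latent dimensions.
#' @param J_per_dim items per dimension.
#' @param G number of groups (first is the reference; focal groups get DIF
#'   magnitudes recycled from `dif_sizes`).
#' @param dif_proportion fraction of items with DIF, in `[0, 1]`.
#' @param dif_type `"uniform"` (intercept DIF only) or `"nonuniform"`
#'   (intercept and slope DIF).
#' @param dif_sizes DIF magnitudes for the focal groups (default low 0.5,
#'   high 1.0).
#' @param balanced alternate DIF signs so effects cancel on average.
#' @param a_range,b_range ranges of the generating uniform distributions of
#'   reference slopes and intercepts.
#' @param rho latent correlation between dimensions (compound-symmetric).
#' @param seed integer seed; the same seed reproduces the same truth.
#' @return An object of class `remirt_truth`: list with `params`
#'   (generating [remirt_params]), `Q`, `dif_items` (indices of DIF items),
#'   `dif_sign`, and the design settings.
#' @export
sim_remirt_params <- function(K = 2, J_per_dim = 10, G = 3,
                              dif_proportion = 0.2,
                              dif_type = c("uniform", "nonuniform"),
                              dif_sizes = c(0.5, 1.0), balanced = TRUE,
                              a_range = c(1.0, 2.5), b_range = c(-1, 1),
                              rho = 0.8, seed = 1L) {
  dif_type <- match.arg(dif_type)
  if (dif_proportion < 0 || dif_proportion > 1) {
    stop("dif_proportion must be in [0, 1]")
  }
  J <- K * J_per_dim
  Q <- matrix(0, J, K)
  for (k in seq_len(K)) Q[(k - 1) * J_per_dim + seq_len(J_per_dim), k] <- 1

  draws <- .with_seed(seed, list(a = runif(J, a_range[1], a_range[2]),
                                 b = runif(J, b_range[1], b_range[2])))
  A <- Q * draws$a
  B <- draws$b

  ## DIF items: the leading fraction of each dimension's block, signs
  ## alternating over the sorted item list (deterministic, balanced)
  n_dif_per_dim <- round(dif_proportion * J_per_dim)
  dif_items <- sort(unlist(lapply(seq_len(K), function(k) {
    (k - 1) * J_per_dim + seq_len(n_dif_per_dim)
  })))
  dif_sign <- if (balanced) {
    rep_len(c(1, -1), length(dif_items))
  } else {
    rep(1, length(dif_items))
  }

  Gamma <- array(0, c(J, K, G))
  Beta <- matrix(0, G, J)
  sizes <- rep_len(dif_sizes, max(G - 1, 1))
  if (G > 1 && length(dif_items) > 0) {
    for (g in seq_len(G)[-1]) {
      sz <- sizes[g - 1]
      Beta[g, dif_items] <- dif_sign * sz
      if (dif_type == "nonuniform") {
        for (idx in seq_along(dif_items)) {
          j <- dif_items[idx]
          k <- which(Q[j, ] > 0)
          Gamma[j, k, g] <- dif_sign[idx] * sz
        }
      }
    }
  }
  R <- matrix(rho, K, K); diag(R) <- 1
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("rho = ", rho, " gives a non-positive-definite correlation for K = ", K)
  }
  params <- remirt_params(A, B, Gamma, Beta,
                          Mu = matrix(0, G, K),
                          Sigma = array(R, c(K, K, G)))
  structure(list(params = params, Q = Q, dif_items = dif_items,
                 dif_sign = dif_sign, dif_type = dif_type,
                 dif_sizes = sizes, K = K, J = J, G = G,
                 J_per_dim = J_per_dim, rho = rho, seed = seed),
            class = "remirt_truth")
}

#' Simulate responses from a generating parameter set
#'
#' Latent traits are drawn from each group's multivariate normal (by
#' default all groups share `N(0, R(rho))`: no impact) and responses are
#' Bernoulli draws from the item response probabilities.
#'
#' @param truth a [sim_remirt_params] object.
#' @param n_per_group persons per group (scalar or length-G vector).
#' @param seed integer seed.
#' @param impact optional list with `Mu` (G x K) and `Sigma` (K x K x G) to
#'   override the default no-impact latent distributions.
#' @return list with `data` (a [remirt_data]) and `theta` (N x K latent
#'   traits).
#' @export
sim_remirt_responses <- function(truth, n_per_group = 1000, seed = 1L,
                                 impact = NULL) {
  G <- truth$G
  n_g <- rep_len(n_per_group, G)
  p <- truth$params
  Mu <- if (is.null(impact)) p$Mu else impact$Mu
  Sigma <- if (is.null(impact)) p$Sigma else impact$Sigma
  N <- sum(n_g)
  group <- rep(seq_len(G), n_g)
  out <- .with_seed(seed, {
    theta <- matrix(0, N, truth$K)
    for (g in seq_len(G)) {
      rows <- which(group == g)
      L <- t(chol(matrix(Sigma[, , g], truth$K, truth$K)))
      Z <- matrix(rnorm(n_g[g] * truth$K), n_g[g], truth$K)
      theta[rows, ] <- sweep(Z %*% t(L), 2, Mu[g, ], "+")
    }
    Y <- matrix(0, N, truth$J)
    for (g in seq_len(G)) {
      rows <- which(group == g)
      eff <- .effective(p, g)
      P <- .sigmoid(sweep(theta[rows, , drop = FALSE] %*% t(eff$A), 2,
                          eff$B, "+"))
      Y[rows, ] <- (matrix(runif(length(P)), nrow(P), ncol(P)) < P) * 1
    }
    list(theta = theta, Y = Y)
  })
  list(data = remirt_data(out$Y, group, truth$Q), theta = out$theta)
}

#' One-call simulation of a multi-group DIF dataset
#'
#' Convenience wrapper around [sim_remirt_params] and
#' [sim_remirt_responses] (parameter seed and response seed are derived
#' from `seed`).
#'
#' @inheritParams sim_remirt_params
#' @inheritParams sim_remirt_responses
#' @return list with `data`, `theta`, and `truth`.
#' @export
sim_remirt <- function(n_per_group = 1000, K = 2, J_per_dim = 10, G = 3,
                       dif_proportion = 0.2,
                       dif_type = c("uniform", "nonuniform"),
                       dif_sizes = c(0.5, 1.0), balanced = TRUE,
                       a_range = c(1.0, 2.5), b_range = c(-1, 1), rho = 0.8,
                       impact = NULL, seed = 1L) {
  truth <- sim_remirt_params(K, J_per_dim, G, dif_proportion,
                             match.arg(dif_type), dif_sizes, balanced,
                             a_range, b_range, rho, seed = seed)
  resp <- sim_remirt_responses(truth, n_per_group, seed = seed + 1L,
                               impact = impact)
  list(data = resp$data, theta = resp$theta, truth = truth)
}

#' Weighted area between item response curves (DIF effect size)
#'
#' For a between-item design, the absolute area between the reference and
#' focal group's item response curves on the item's loading dimension,
#' weighted by the focal group's marginal latent density:
#' `integral |P_ref(theta) - P_g(theta)| phi_g(theta) dtheta`, computed by
#' Gauss-Hermite quadrature. Zero exactly when the two curves coincide.
#'
#' @param truth a [sim_remirt_params] object (or any list with `params` and
#'   `Q`).
#' @param j item index; must load on a single dimension.
#' @param g focal group index (>= 2).
#' @param n_quad quadrature nodes.
#' @export
wabc <- function(truth, j, g, n_quad = 49) {
  p <- truth$params
  S <- which(truth$Q[j, ] > 0)
  if (length(S) != 1) {
    stop("wABC requires a between-item design (single loading dimension)")
  }
  mu <- p$Mu[g, S]
  sd_g <- sqrt(p$Sigma[S, S, g])
  gh <- pracma::gaussHermite(n_quad)
  theta <- mu + sqrt(2) * sd_g * gh$x
  w <- gh$w / sqrt(pi)
  pr <- .sigmoid(p$A[j, S] * theta + p$B[j])
  pf <- .sigmoid((p$A[j, S] + p$Gamma[j, S, g]) * theta + p$B[j] + p$Beta[g, j])
  sum(w * abs(pr - pf))
}

#' Score DIF detection against the generating truth
#'
#' An item is flagged for a focal group when any of its DIF slope or
#' intercept entries for that group is nonzero in the (debiased) fit. True
#' and false positive rates are reported per focal group and for "Total"
#' (flagged/true for any focal group).
#'
#' @param fit one element of a `remirt_path`, or a [remirt_params] object.
#' @param truth a [sim_remirt_params] object from the same design.
#' @return data.frame with columns `group` (focal group label or "total"),
#'   `tpr`, `fpr`, and the underlying counts.
#' @export
evaluate_detection <- function(fit, truth) {
  params <- if (inherits(fit, "remirt_params")) fit else fit$params
  if (params$J != truth$J) stop("fit and truth have different numbers of items")
  G <- truth$G
  flag <- true <- matrix(FALSE, truth$J, G - 1)
  for (g in seq_len(G)[-1]) {
    flag[, g - 1] <- params$Beta[g, ] != 0 |
      apply(matrix(params$Gamma[, , g], truth$J, truth$K) != 0, 1, any)
    true[, g - 1] <- truth$params$Beta[g, ] != 0 |
      apply(matrix(truth$params$Gamma[, , g], truth$J, truth$K) != 0, 1, any)
  }
  one <- function(fl, tr, label) {
    tp <- sum(fl & tr); fp <- sum(fl & !tr)
    data.frame(group = label,
               tpr = if (sum(tr) > 0) tp / sum(tr) else NA_real_,
               fpr = if (sum(!tr) > 0) fp / sum(!tr) else NA_real_,
               n_true = sum(tr), n_flagged = sum(fl))
  }
  out <- do.call(rbind, lapply(seq_len(G - 1), function(g) {
    one(flag[, g], true[, g], as.character(g + 1))
  }))
  rbind(out, one(apply(flag, 1, any), apply(true, 1, any), "total"))
}
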