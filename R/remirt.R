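#' Fit a regularized multi-group MIRT model and detect DIF
#'
#' The main fitting function. Fits the re-MIRT model over a grid of Lasso
#' tuning parameters with either the regularized Gaussian variational EM
#' algorithm (`method = "gvem"`) or its importance-weighted refinement
#' (`method = "iwgvemm"`, the default, more accurate especially for slope
#' DIF under correlated traits), selects the tuning parameter by GIC or
#' BIC, extends the grid upward while the boundary value is selected, and
#' returns the debiased selected model. Items whose DIF parameters survive
#' the selected penalty are flagged as showing DIF against the reference
#' group; items shrunk to zero act as implicit anchors.
#'
#' @param Y N x J matrix of 0/1 responses, or a [remirt_data] object (in
#'   which case `group` and `Q` are ignored).
#' @param group length-N group membership vector (1 = reference).
#' @param Q J x K loading indicator matrix.
#' @param method `"iwgvemm"` or `"gvem"`.
#' @param lambda tuning-parameter grid (ascending); default
#'   [default_lambda_grid].
#' @param criterion `"gic"` (default) or `"bic"`.
#' @param c GIC constant (larger selects sparser DIF models).
#' @param M importance samples per person (IW-GVEMM only).
#' @param seed integer seed for the importance-sampling draw.
#' @param control a [remirt_control] list.
#' @param fixed_zeros optional constraint masks passed to the fitters.
#' @param extend logical; extend the grid by factors of 1.5 while the
#'   largest tuning parameter is selected.
#' @param max_extend maximum number of grid extensions.
#' @return An object of class `remirt` with the selected debiased
#'   parameters (`$params`), the full `$path`, criterion values, and a DIF
#'   flag table (`$dif`). Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `simulate`.
#' @examples
#' \donttest{
#' sim <- sim_remirt(n_per_group = 300, J_per_dim = 5, seed = 7)
#' fit <- remirt(sim$data, method = "gvem", lambda = c(0.05, 0.1, 0.2))
#' summary(fit)
#' }
#' @export
remirt <- function(Y, group = NULL, Q = NULL,
                   method = c("iwgvemm", "gvem"),
                   lambda = default_lambda_grid(),
                   criterion = c("gic", "bic"), c = 1, M = 10, seed = 1L,
                   control = remirt_control(), fixed_zeros = NULL,
                   extend = TRUE, max_extend = 8) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  data <- if (inherits(Y, "remirt_data")) Y else remirt_data(Y, group, Q)
  cl <- match.call()

  path <- if (method == "gvem") {
    fit_gvem(data, lambda, control, fixed_zeros)
  } else {
    fit_iw_gvemm(data, lambda, M, seed, control, fixed_zeros)
  }
  path <- select_lambda(path, criterion, c)
  n_ext <- 0
  while (extend && path$extend_needed && n_ext < max_extend) {
    new_lam <- max(path$lambda) * 1.5
    path <- if (method == "gvem") {
      .gvem_fit_one(path, data, new_lam)
    } else {
      .iw_fit_one(path, data, new_lam)
    }
    path <- select_lambda(path, criterion, c)
    n_ext <- n_ext + 1
  }

  sel <- path$fits[[path$selected]]
  structure(list(call = cl, method = method, data = data, path = path,
                 params = sel$params, lambda = sel$lambda,
                 criterion = criterion, c = c,
                 criterion_values = path$criterion_values,
                 selected = path$selected, df = sel$df,
                 bound = sel$bound, converged = sel$converged,
                 dif = .dif_table(sel$params, data),
                 M = if (method == "iwgvemm") M else NULL,
                 seed = seed, n_extend = n_ext),
            class = "remirt")
}

.dif_table <- function(params, data) {
  if (data$G < 2) return(data.frame())
  rows <- list()
  for (g in seq_len(data$G)[-1]) {
    gam <- matrix(params$Gamma[, , g], data$J, data$K)
    rows[[g - 1]] <- data.frame(
      item = seq_len(data$J), group = g,
      beta = params$Beta[g, ],
      gamma = apply(gam, 1, function(x) x[which.max(abs(x))]),
      flagged = params$Beta[g, ] != 0 | apply(gam != 0, 1, any))
  }
  do.call(rbind, rows)
}

#' @export
print.remirt <- function(x, ...) {
  cat("Regularized multi-group MIRT fit (", toupper(x$method), ")\n", sep = "")
  cat("  persons:", x$data$N, " items:", x$data$J,
      " dimensions:", x$data$K, " groups:", x$data$G, "\n")
  cat("  selected lambda:", format(x$lambda, digits = 3),
      " by", toupper(x$criterion),
      if (x$criterion == "gic") paste0("(c = ", x$c, ")") else "", "\n")
  cat("  nonzero DIF parameters:", x$df, "\n")
  nflag <- length(unique(x$dif$item[x$dif$flagged]))
  cat("  items flagged with DIF:", nflag, "of", x$data$J, "\n")
  invisible(x)
}

#' @export
summary.remirt <- function(object, ...) {
  flagged <- object$dif[object$dif$flagged, , drop = FALSE]
  impact <- lapply(seq_len(object$data$G), function(g) {
    list(mu = object$params$Mu[g, ],
         sigma = matrix(object$params$Sigma[, , g], object$data$K,
                        object$data$K))
  })
  structure(list(fit = object, flagged = flagged, impact = impact,
                 path_table = data.frame(
                   lambda = object$path$lambda,
                   bound = vapply(object$path$fits, `[[`, 0, "bound"),
                   df = vapply(object$path$fits, `[[`, 0L, "df"),
                   criterion = object$criterion_values)),
            class = "summary.remirt")
}

#' @export
print.summary.remirt <- function(x, ...) {
  print(x$fit)
  cat("\nTuning-parameter path:\n")
  print(x$path_table, row.names = FALSE, digits = 5)
  cat("\nFlagged DIF parameters (debiased estimates):\n")
  if (nrow(x$flagged) == 0) {
    cat("  none\n")
  } else {
    print(x$flagged, row.names = FALSE, digits = 3)
  }
  cat("\nEstimated impact (focal-group latent means):\n")
  for (g in seq_along(x$impact)[-1]) {
    cat("  group ", g, ": mu = (",
        paste(format(x$impact[[g]]$mu, digits = 3), collapse = ", "),
        ")\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.remirt <- function(object, ...) {
  p <- object$params
  list(A = p$A, B = p$B, Gamma = p$Gamma, Beta = p$Beta,
       Mu = p$Mu, Sigma = p$Sigma)
}

#' Predicted response proportions from a fitted model
#'
#' @param object a [remirt] fit.
#' @param T Monte-Carlo draws per group.
#' @param seed integer seed.
#' @param ... unused.
#' @return G x J matrix of model-implied proportions.
#' @export
predict.remirt <- function(object, T = 1e5, seed = 1L, ...) {
  predicted_proportions(object$params, T = T, seed = seed)
}

#' Simulate response data from a fitted model
#'
#' @param object a [remirt] fit.
#' @param nsim number of replicate response matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of N x J response matrices, with the fitted group sizes.
#' @export
simulate.remirt <- function(object, nsim = 1, seed = 1L, ...) {
  p <- object$params
  data <- object$data
  lapply(seq_len(nsim), function(r) {
    .with_seed(seed + r - 1L, {
      Y <- matrix(0, data$N, data$J)
      for (g in seq_len(data$G)) {
        rows <- which(data$group == g)
        L <- t(chol(matrix(p$Sigma[, , g], data$K, data$K)))
        Z <- matrix(rnorm(length(rows) * data$K), length(rows), data$K)
        theta <- sweep(Z %*% t(L), 2, p$Mu[g, ], "+")
        eff <- .effective(p, g)
        P <- .sigmoid(sweep(theta %*% t(eff$A), 2, eff$B, "+"))
        Y[rows, ] <- (matrix(runif(length(P)), nrow(P), ncol(P)) < P) * 1
      }
      Y
    })
  })
}

#' Plot the criterion path or the scree diagnostic of a fit
#'
#' @param x a [remirt] fit.
#' @param type `"criterion"` (information criterion against log lambda) or
#'   `"scree"` (selected DIF parameter count against the GIC constant).
#' @param c_grid GIC constants for `type = "scree"`.
#' @param ... passed to [plot].
#' @export
plot.remirt <- function(x, type = c("criterion", "scree"),
                        c_grid = c(0.1, 0.2, 0.5, 1, 2, 5), ...) {
  type <- match.arg(type)
  if (type == "criterion") {
    plot(log(x$path$lambda), x$criterion_values, type = "b",
         xlab = expression(log(lambda)),
         ylab = toupper(x$criterion), ...)
    points(log(x$lambda), x$criterion_values[x$selected], pch = 19)
  } else {
    tab <- scree_dif(x$path, c_grid)
    plot(tab$c, tab$df, type = "b", log = "x", xlab = "GIC constant c",
         ylab = "nonzero DIF parameters", ...)
  }
  invisible(x)
}
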