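## nonzero free DIF entries of a parameter set
.count_df_params <- function(params, data, fixed) {
  df <- 0L
  if (data$G > 1) {
    for (g in seq_len(data$G)[-1]) {
      free_g <- data$Q > 0 & !matrix(fixed$Gamma[, , g], data$J, data$K)
      df <- df + sum(matrix(params$Gamma[, , g], data$J, data$K)[free_g] != 0) +
        sum(params$Beta[g, !fixed$Beta[g, ]] != 0)
    }
  }
  as.integer(df)
}

#' Number of nonzero DIF parameters of a fit
#'
#' The model degrees of freedom used by the information criteria: the count
#' of DIF slope and intercept entries (non-reference groups, on-support
#' positions) that were not shrunk to zero. Only the zero/nonzero pattern
#' matters, not the values.
#'
#' @param fit one element of a `remirt_path` (a debiased fit).
#' @export
count_df <- function(fit) {
  fit$df
}

#' Generalized information criterion for a fitted tuning parameter
#'
#' `-2 * bound + a_N * df`, where `bound` is the fit's variational bound
#' (GVEM) or importance-weighted bound (IW-GVEMM), `df` the number of
#' nonzero DIF parameters, and `a_N = log(N)` for BIC or
#' `a_N = c * log(N) * log(log(N))` for GIC.
#'
#' @param fit one element of a `remirt_path`.
#' @param N number of persons.
#' @param criterion `"gic"` or `"bic"`.
#' @param c positive constant scaling the GIC penalty (larger shrinks more).
#' @export
gic <- function(fit, N, criterion = c("gic", "bic"), c = 1) {
  criterion <- match.arg(criterion)
  if (N <= exp(1)) stop("N must exceed e for the GIC penalty")
  a_N <- switch(criterion, bic = log(N), gic = c * log(N) * log(log(N)))
  -2 * fit$bound + a_N * count_df(fit)
}

#' Select the tuning parameter of a fitted path by BIC or GIC
#'
#' Computes the criterion for every fit and selects the minimizer, breaking
#' ties toward the larger tuning parameter. When the selected value is the
#' largest in the grid the result is flagged as needing grid extension
#' (larger values should be fitted until the selection is interior).
#'
#' @param path a `remirt_path` from [fit_gvem] or [fit_iw_gvemm].
#' @inheritParams gic
#' @return The path with elements `criterion_values`, `selected` (index),
#'   `criterion`, `c`, and `extend_needed` added.
#' @export
select_lambda <- function(path, criterion = c("gic", "bic"), c = 1) {
  criterion <- match.arg(criterion)
  vals <- vapply(path$fits, gic, 0, N = path$N, criterion = criterion, c = c)
  ok <- which(is.finite(vals))
  if (length(ok) == 0) stop("no finite criterion value in the path")
  sel <- max(ok[vals[ok] == min(vals[ok])])
  path$criterion_values <- vals
  path$selected <- sel
  path$criterion <- criterion
  path$c <- c
  path$extend_needed <- sel == length(path$fits)
  path
}

#' Model-implied response proportions by Monte-Carlo integration
#'
#' For each group and item, the predicted proportion of positive responses
#' `E[plogis(irf_logit)]` under the group's estimated latent trait
#' distribution, approximated with `T` Monte-Carlo draws.
#'
#' @param params a [remirt_params] object.
#' @param T Monte-Carlo sample size.
#' @param seed integer seed.
#' @return G x J matrix of predicted proportions.
#' @export
predicted_proportions <- function(params, T = 1e5, seed = 1L) {
  if (T < 1) stop("T must be at least 1")
  out <- matrix(0, params$G, params$J)
  for (g in seq_len(params$G)) {
    L <- t(chol(matrix(params$Sigma[, , g], params$K, params$K)))
    Z <- .with_seed(seed + g, matrix(rnorm(T * params$K), T, params$K))
    theta <- sweep(Z %*% t(L), 2, params$Mu[g, ], "+")
    eff <- .effective(params, g)
    X <- sweep(theta %*% t(eff$A), 2, eff$B, "+")
    out[g, ] <- colMeans(.sigmoid(X))
  }
  out
}

#' Predicted-versus-observed proportion RMSE fit index
#'
#' Root mean square error between the model-implied response proportions
#' (Monte-Carlo, per group and item) and the observed sample proportions.
#'
#' @inheritParams predicted_proportions
#' @param data a [remirt_data] object; every group must be non-empty.
#' @return An object of class `remirt_fit_index`: list with `predicted`,
#'   `observed` (G x J matrices), and `rmse`.
#' @export
fit_rmse <- function(params, data, T = 1e5, seed = 1L) {
  predicted <- predicted_proportions(params, T, seed)
  observed <- matrix(0, data$G, data$J)
  for (g in seq_len(data$G)) {
    rows <- which(data$group == g)
    if (length(rows) == 0) stop("group ", g, " is empty")
    observed[g, ] <- colMeans(data$Y[rows, , drop = FALSE])
  }
  structure(list(predicted = predicted, observed = observed,
                 rmse = sqrt(mean((predicted - observed)^2))),
            class = "remirt_fit_index")
}

#' @export
print.remirt_fit_index <- function(x, ...) {
  cat("Predicted-proportion RMSE:", format(x$rmse, digits = 4), "\n")
  invisible(x)
}

#' Scree diagnostic: selected model size against the GIC constant
#'
#' Reselects the tuning parameter by GIC for each constant in `c_grid` and
#' reports the selected model's number of nonzero DIF parameters. Plotted
#' against `c` this resembles a scree plot; elbows suggest reasonable
#' constants.
#'
#' @param path a fitted `remirt_path`.
#' @param c_grid ascending vector of GIC constants.
#' @return data.frame with columns `c`, `lambda`, and `df` (nonincreasing
#'   in `c`).
#' @export
scree_dif <- function(path, c_grid = c(0.1, 0.2, 0.5, 1, 2, 5)) {
  stopifnot(!is.unsorted(c_grid))
  rows <- lapply(c_grid, function(cc) {
    sel <- select_lambda(path, "gic", cc)
    data.frame(c = cc, lambda = path$lambda[sel$selected],
               df = count_df(path$fits[[sel$selected]]))
  })
  do.call(rbind, rows)
}
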