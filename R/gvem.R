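#' Control parameters for re-MIRT estimation
#'
#' @param tol EM convergence tolerance: the maximum absolute change of any
#'   structural parameter entry between consecutive iterations.
#' @param max_iter maximum EM iterations per run.
#' @param warm_iter iteration cap for the shared unpenalized warm-start run
#'   (step 2). With all DIF parameters free and no penalty that run is not
#'   identified, so it can drift slowly along a likelihood ridge; it only
#'   supplies starting values, and capping it does not affect the penalized
#'   and debiased runs' convergence criteria.
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (reference
#'   implementation composed of the exported per-step functions; identical
#'   results, much slower).
#' @param ridge diagonal jitter used if an item's slope system is singular.
#' @param adam_lr,adam_beta1,adam_beta2,adam_eps Adam hyperparameters for
#'   the importance-weighted refinement.
#' @param adam_lr_debias Adam learning rate for the debiasing run. The
#'   debias optimization starts at the penalized optimum, where restarting
#'   the adaptive optimizer with a large step causes a long transient; a
#'   smaller step reaches the same optimum (parameter agreement ~1e-4) in
#'   far fewer iterations.
#' @param adam_decay step-size decay: the base rate at step t is
#'   `adam_lr / (1 + adam_decay * t)`. With a constant step, Adam can
#'   enter a persistent small-amplitude limit cycle on a deterministic
#'   objective and never satisfy the parameter-stability stopping rule;
#'   a gentle decay damps the cycle without freezing the optimization
#'   (the same optimum is reached, to ~1e-4, in a fraction of the steps).
#'   Set to 0 for a constant rate.
#' @param adam_max_iter maximum Adam steps per optimization.
#' @param adam_tol,adam_window Adam stops once the maximum absolute
#'   parameter change stays below `adam_tol` for `adam_window` consecutive
#'   steps.
#' @export
remirt_control <- function(tol = 1e-4, max_iter = 2000, warm_iter = 300,
                           engine = c("cpp", "r"),
                           ridge = 1e-8, adam_lr = 0.1,
                           adam_lr_debias = 0.05, adam_decay = 0.002,
                           adam_beta1 = 0.9,
                           adam_beta2 = 0.999, adam_eps = 1e-8,
                           adam_max_iter = 5000, adam_tol = 1e-4,
                           adam_window = 10) {
  list(tol = tol, max_iter = max_iter, warm_iter = warm_iter,
       engine = match.arg(engine),
       ridge = ridge, adam_lr = adam_lr, adam_lr_debias = adam_lr_debias,
       adam_decay = adam_decay, adam_beta1 = adam_beta1,
       adam_beta2 = adam_beta2, adam_eps = adam_eps,
       adam_max_iter = adam_max_iter, adam_tol = adam_tol,
       adam_window = adam_window)
}

.empty_fixed <- function(data) {
  list(Gamma = array(FALSE, c(data$J, data$K, data$G)),
       Beta = matrix(FALSE, data$G, data$J))
}

.as_fixed <- function(data, fixed_zeros) {
  if (is.null(fixed_zeros)) return(.empty_fixed(data))
  stopifnot(identical(dim(fixed_zeros$Gamma), c(data$J, data$K, data$G)),
            identical(dim(fixed_zeros$Beta), c(data$G, data$J)))
  fixed_zeros
}

## one EM run to convergence; returns params/varstate/bound/trace
.em_run <- function(params, varstate, data, lambda, control, fixed,
                    update_dif = TRUE) {
  if (control$engine == "cpp") {
    out <- gvem_em_cpp(data$Y, as.integer(data$group - 1L), data$Q,
                       params$A, params$B, params$Gamma, params$Beta,
                       params$Mu, params$Sigma,
                       varstate$mu, varstate$sigma, varstate$xi,
                       lambda,
                       array(as.double(fixed$Gamma), dim(fixed$Gamma)),
                       matrix(as.double(fixed$Beta), data$G, data$J),
                       control$tol, control$max_iter, update_dif,
                       control$ridge)
    params$A <- out$A; params$B <- drop(out$B)
    params$Gamma <- array(out$Gamma, c(data$J, data$K, data$G))
    params$Beta <- out$Beta; params$Mu <- out$Mu
    params$Sigma <- array(out$Sigma, c(data$K, data$K, data$G))
    varstate <- list(mu = out$MuStar,
                     sigma = array(out$SigmaStar, c(data$K, data$K, data$N)),
                     xi = out$Xi)
    list(params = params, varstate = varstate, trace = drop(out$trace),
         bound = out$trace[length(out$trace)], n_iter = out$n_iter,
         converged = out$converged)
  } else {
    trace <- numeric(0)
    converged <- FALSE
    it <- 0
    for (it in seq_len(control$max_iter)) {
      old <- params
      res <- .gvem_cycle_r(params, varstate, data, if (update_dif) lambda else 0,
                           if (update_dif) fixed else .all_fixed(data))
      params <- res$params; varstate <- res$varstate
      trace <- c(trace, res$bound)
      diff <- max(abs(params$A - old$A), abs(params$B - old$B),
                  abs(params$Gamma - old$Gamma), abs(params$Beta - old$Beta),
                  abs(params$Mu - old$Mu), abs(params$Sigma - old$Sigma))
      if (diff < control$tol) { converged <- TRUE; break }
    }
    list(params = params, varstate = varstate, trace = trace,
         bound = trace[length(trace)], n_iter = it, converged = converged)
  }
}

.all_fixed <- function(data) {
  list(Gamma = array(TRUE, c(data$J, data$K, data$G)),
       Beta = matrix(TRUE, data$G, data$J))
}

## zero pattern of the free DIF entries (exact zeros after shrinkage)
.zero_pattern <- function(params, data, fixed) {
  free_g <- array(FALSE, c(data$J, data$K, data$G))
  free_b <- matrix(FALSE, data$G, data$J)
  if (data$G > 1) {
    for (g in seq_len(data$G)[-1]) {
      free_g[, , g] <- data$Q > 0 & !matrix(fixed$Gamma[, , g], data$J, data$K)
      free_b[g, ] <- !fixed$Beta[g, ]
    }
  }
  list(Gamma = free_g & params$Gamma == 0,
       Beta = free_b & params$Beta == 0)
}

## Steps 1-2 of the fitting algorithm: deterministic starting values, then
## unpenalized EM to convergence (warm start shared by every lambda)
.gvem_warm_start <- function(data, control, fixed) {
  params <- .init_params(data)
  varstate <- .init_varstate(data)
  warm_control <- control
  warm_control$max_iter <- min(control$warm_iter, control$max_iter)
  .em_run(params, varstate, data, 0, warm_control, fixed)
}

#' Fit the regularized GVEM path over a grid of tuning parameters
#'
#' Runs the three-step regularized GVEM algorithm: deterministic starting
#' values, an unpenalized EM run shared as warm start, then for each
#' `lambda` a penalized EM run (recording which DIF entries are shrunk to
#' exactly zero) followed by a debiasing EM run without penalty that holds
#' the zero pattern fixed. Each EM iteration performs the closed-form
#' E-step, the local-parameter update, the closed-form M-step, the
#' soft-thresholded DIF coordinate updates, and the identification
#' rescaling.
#'
#' @param data a [remirt_data] object.
#' @param lambda ascending vector of nonnegative tuning parameters.
#' @param control a [remirt_control] list.
#' @param fixed_zeros optional list of logical arrays (`Gamma` J x K x G,
#'   `Beta` G x J) of DIF entries constrained to zero throughout.
#' @return A `remirt_path` object: a list of debiased fits (one per
#'   `lambda`, each with elements `params`, `bound`, `zero_pattern`, `df`,
#'   `trace`, `n_iter`, `converged`, `lambda`), plus the shared warm start.
#' @export
fit_gvem <- function(data, lambda = default_lambda_grid(),
                     control = remirt_control(), fixed_zeros = NULL) {
  stopifnot(length(lambda) > 0, !is.unsorted(lambda), all(lambda >= 0))
  fixed <- .as_fixed(data, fixed_zeros)
  warm <- .gvem_warm_start(data, control, fixed)
  path <- structure(list(fits = list(), lambda = numeric(0), method = "gvem",
                         N = data$N, warm = warm, fixed = fixed,
                         control = control),
                    class = "remirt_path")
  for (lam in lambda) path <- .gvem_fit_one(path, data, lam)
  path
}

.gvem_fit_one <- function(path, data, lam) {
  control <- path$control; fixed <- path$fixed; warm <- path$warm
  pen <- .em_run(warm$params, warm$varstate, data, lam, control, fixed)
  if (!pen$converged) {
    warning("penalized EM did not converge at lambda = ", signif(lam, 3))
  }
  zp <- .zero_pattern(pen$params, data, fixed)
  fixed_db <- list(Gamma = fixed$Gamma | zp$Gamma, Beta = fixed$Beta | zp$Beta)
  db <- .em_run(pen$params, pen$varstate, data, 0, control, fixed_db)
  fit <- list(params = db$params, varstate = db$varstate, bound = db$bound,
              zero_pattern = zp, df = .count_df_params(db$params, data, fixed),
              trace = db$trace, trace_penalized = pen$trace,
              n_iter = db$n_iter + pen$n_iter,
              converged = pen$converged && db$converged, lambda = lam)
  path$fits[[length(path$fits) + 1L]] <- fit
  path$lambda <- c(path$lambda, lam)
  path
}

#' Default tuning-parameter grid
#'
#' Eight log-spaced values in `[0.0025, 0.04]`; the selection step extends
#' the grid upward by factors of 1.5 when the largest value is selected.
#' Because the penalty is `N * lambda * |x|` and each DIF coordinate's
#' bound curvature grows with its group's sample size, the per-coordinate
#' soft threshold in parameter units is roughly `G * lambda / (2 * etabar)`
#' with `etabar ~ 0.1`; this range therefore spans thresholds from below
#' the sampling noise of a DIF estimate up to shrinkage of order one for
#' typical multi-group designs, and the extension rule covers anything
#' larger.
#' @param n number of grid points.
#' @param range endpoints.
#' @export
default_lambda_grid <- function(n = 8, range = c(0.0025, 0.04)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' @export
print.remirt_path <- function(x, ...) {
  cat("re-MIRT ", toupper(x$method), " path: ", length(x$fits),
      " tuning parameter(s)\n", sep = "")
  tab <- data.frame(lambda = x$lambda,
                    bound = vapply(x$fits, `[[`, 0, "bound"),
                    df = vapply(x$fits, `[[`, 0L, "df"),
                    converged = vapply(x$fits, `[[`, TRUE, "converged"))
  print(tab, row.names = FALSE)
  invisible(x)
}
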