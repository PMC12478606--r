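test_that("local variational curvature eta has the right values and shape", {
  expect_equal(eta_xi(0), 0.125)
  expect_equal(eta_xi(1), tanh(0.5) / 4)
  expect_equal(eta_xi(1), 0.1155292893, tolerance = 1e-9)
  grid <- seq(0, 10, length.out = 400)
  v <- eta_xi(grid)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v > 0 & v <= 0.125))
  expect_error(eta_xi(-0.1), "nonnegative")
})

test_that("quadratic bound is tight at xi = |logit| and never exceeds the exact loglik", {
  exact <- function(y, x) y * x - log(1 + exp(x))
  for (y in c(0, 1)) {
    for (x in c(-4, -1, 0, 0.3, 2.5)) {
      expect_equal(quadratic_bound_conditional(y, x, abs(x)), exact(y, x),
                   tolerance = 1e-12)
    }
  }
  expect_equal(quadratic_bound_conditional(1, 0, 0), log(0.5))
  grid <- expand.grid(x = seq(-5, 5, length.out = 10),
                      xi = seq(0, 6, length.out = 10))
  for (y in c(0, 1)) {
    b <- quadratic_bound_conditional(y, grid$x, grid$xi)
    expect_true(all(b <= exact(y, grid$x) + 1e-12))
  }
})

test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(0.2, 0), 0.2)
  expect_error(soft_threshold(1, -1), "nonnegative")
})

test_that("E-step closed form matches hand computation and a numeric optimizer", {
  ## K=1 hand example: one item, a=1, b=0, xi=0, y=1, N(0,1) prior
  d <- remirt_data(matrix(1, 1, 1), 1, matrix(1, 1, 1))
  p <- remirt_params(matrix(1, 1, 1), 0, array(0, c(1, 1, 1)),
                     matrix(0, 1, 1), matrix(0, 1, 1), array(1, c(1, 1, 1)))
  es <- e_step_person(p, d, 1, 0)
  expect_equal(drop(es$sigma), 0.8)
  expect_equal(es$mu, 0.4)

  ## no likelihood contribution (all slopes and intercepts zero, so the
  ## item terms cancel): the variational optimum is the group prior
  inst0 <- rand_instance(N = 4, J = 3, K = 2, G = 2, seed = 99)
  pz <- inst0$params
  pz$A[] <- 0; pz$B[] <- 0; pz$Gamma[] <- 0; pz$Beta[] <- 0
  es0 <- e_step_person(pz, inst0$data, 4, rep(0, 3))
  g0 <- inst0$data$group[4]
  expect_equal(es0$mu, pz$Mu[g0, ], tolerance = 1e-10)
  expect_equal(es0$sigma, matrix(pz$Sigma[, , g0], 2, 2), tolerance = 1e-10)

  ## numeric-optimizer oracle over (mu*, Sigma*) on random instances
  for (s in 1:6) {
    inst <- rand_instance(N = 6, J = 4, K = 2, G = 2, seed = s)
    vs <- rand_varstate(inst$data, seed = s + 50)
    i <- 1 + (s %% inst$data$N)
    es <- e_step_person(inst$params, inst$data, i, vs$xi[i, ])
    obj <- function(par) {
      L <- matrix(0, 2, 2); diag(L) <- exp(par[3:4]); L[2, 1] <- par[5]
      v2 <- vs; v2$mu[i, ] <- par[1:2]; v2$sigma[, , i] <- tcrossprod(L)
      -elbo(inst$params, v2, inst$data)
    }
    o <- optim(c(0, 0, 0, 0, 0), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
    L <- matrix(0, 2, 2); diag(L) <- exp(o$par[3:4]); L[2, 1] <- o$par[5]
    expect_equal(es$mu, o$par[1:2], tolerance = 1e-5)
    expect_equal(es$sigma, tcrossprod(L), tolerance = 1e-5)
  }
})

test_that("xi update equals the bound-optimal second moment", {
  ## mu*=0, Sigma*=I, a=e1, b=0 -> xi = 1
  inst <- rand_instance(N = 3, J = 3, K = 2, G = 1, seed = 7)
  p <- inst$params
  p$A[1, ] <- c(1, 0); p$B[1] <- 0
  p$A[2, ] <- 0; p$B[2] <- -2.5   # pure intercept: xi = |b|
  vs <- list(mu = matrix(0, 3, 2), sigma = array(diag(2), c(2, 2, 3)),
             xi = matrix(1, 3, 3))
  xi <- update_xi(p, vs, inst$data)
  expect_equal(xi[1, 1], 1)
  expect_equal(xi[1, 2], 2.5)

  ## the bound does not decrease after the xi update
  for (s in 1:5) {
    inst <- rand_instance(N = 8, J = 5, K = 2, G = 2, seed = s + 20)
    vs <- rand_varstate(inst$data, seed = s)
    before <- elbo(inst$params, vs, inst$data)
    vs$xi <- update_xi(inst$params, vs, inst$data)
    expect_gte(elbo(inst$params, vs, inst$data), before - 1e-10)
  }
})

test_that("M-step closed forms match hand formulas and numeric maximizers", {
  ## b update with eta = 1/8 (xi = 0), no DIF, mu* = 0:
  ## b_j = 4 * mean(y_j - 1/2)
  inst <- rand_instance(N = 12, J = 4, K = 2, G = 1, seed = 8)
  d <- inst$data
  vs <- list(mu = matrix(0, d$N, 2), sigma = array(diag(2), c(2, 2, d$N)),
             xi = matrix(0, d$N, d$J))
  p <- inst$params
  pb <- remirt:::.update_B(p, vs, d, eta_xi(vs$xi))
  expect_equal(pb$B, 4 * colMeans(d$Y - 0.5))

  ## single group, no DIF, mu*=0, Sigma*=I: Sigma update returns I
  pm <- remirt:::.update_mu_sigma(p, vs, d)
  expect_equal(matrix(pm$Sigma[, , 1], 2, 2), diag(2))

  ## coordinate updates maximize the bound (numeric 1-D oracles)
  for (s in 1:5) {
    inst <- rand_instance(N = 10, J = 4, K = 2, G = 2, seed = s + 30)
    d <- inst$data
    vs <- rand_varstate(d, seed = s + 3)
    p <- inst$params
    eta_mat <- eta_xi(vs$xi)
    Mlist <- lapply(seq_len(d$N), function(i) {
      matrix(vs$sigma[, , i], 2, 2) + tcrossprod(vs$mu[i, ])
    })
    pb <- remirt:::.update_B(p, vs, d, eta_mat)
    j <- 1 + (s %% d$J)
    num <- optimize(elbo_coord(p, vs, d, "b", g = NULL, j = j),
                    c(-6, 6), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(pb$B[j], num, tolerance = 1e-5)

    pa <- remirt:::.update_A(p, vs, d, eta_mat, Mlist)
    k <- d$support[[j]]
    ## the slope update solves its block with B at pre-update values
    num_a <- optimize(elbo_coord(p, vs, d, "a", g = NULL, j = j, k = k),
                      c(-6, 6), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(pa$A[j, k], num_a, tolerance = 1e-5)
  }
})

test_that("penalized DIF coordinate update solves the 1-D penalized problem", {
  inst <- rand_instance(N = 15, J = 4, K = 2, G = 2, seed = 9)
  d <- inst$data
  vs <- rand_varstate(d, seed = 4)
  p <- inst$params

  ## lambda = 0 coincides with the unpenalized coordinate maximizer; the
  ## first visited coordinate (group 2, item 1, intercept) is comparable
  p0 <- update_dif_penalized(p, vs, d, 0)
  num <- optimize(elbo_coord(p, vs, d, "beta", g = 2, j = 1),
                  c(-6, 6), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(p0$Beta[2, 1], num, tolerance = 1e-5)

  ## penalized: matches numeric maximization of bound - N*lambda*|x|
  lam <- 0.02
  pl <- update_dif_penalized(p, vs, d, lam)
  f <- elbo_coord(p, vs, d, "beta", g = 2, j = 1)
  fp <- function(x) f(x) - d$N * lam * abs(x)
  nump <- optimize(fp, c(-6, 6), maximum = TRUE, tol = 1e-12)$maximum
  if (abs(nump) < 1e-7) nump <- 0
  expect_equal(pl$Beta[2, 1], nump, tolerance = 1e-5)

  ## large lambda shrinks every free entry to exactly zero
  pbig <- update_dif_penalized(p, vs, d, 50)
  expect_true(all(pbig$Beta[-1, ] == 0))
  expect_true(all(pbig$Gamma[, , -1] == 0))

  ## the closed-form scalar rule equals the numeric prox on random triples
  set.seed(10)
  for (r in 1:100) {
    cv <- runif(1, 0.2, 5); gr <- rnorm(1, sd = 2); x0 <- rnorm(1)
    t <- runif(1, 0, 2)
    closed <- soft_threshold(cv * x0 + gr, t) / cv
    quad <- function(x) gr * (x - x0) - 0.5 * cv * (x - x0)^2 - t * abs(x)
    num <- optimize(quad, c(-20, 20), maximum = TRUE, tol = 1e-12)$maximum
    expect_lt(abs(closed - num), 1e-6)
  }
})

test_that("elbo is a true lower bound and is invariant to person order", {
  expect_equal(elbo(rand_params(3, 2, 1, 1), NULL, empty_data(3, 2)), 0)
  for (s in 1:10) {
    inst <- rand_instance(N = 8, J = 5, K = 2, G = 2, seed = s + 40)
    vs <- rand_varstate(inst$data, seed = s)
    vs$xi <- update_xi(inst$params, vs, inst$data)
    b <- elbo(inst$params, vs, inst$data)
    expect_lte(b, marginal_loglik_gh(inst$params, inst$data) + 1e-8)
    pi_p <- sample(inst$data$N)
    d2 <- remirt_data(inst$data$Y[pi_p, ], inst$data$group[pi_p], inst$data$Q)
    vs2 <- list(mu = vs$mu[pi_p, ], sigma = vs$sigma[, , pi_p],
                xi = vs$xi[pi_p, ])
    expect_equal(elbo(inst$params, vs2, d2), b, tolerance = 1e-10)
  }
})

test_that("identification rescaling fixes the reference scale without changing the model", {
  p <- rand_params(J = 5, K = 2, G = 3, seed = 12)
  expect_equal(rescale_identify(p), p)   # already identified

  ## hand example: Sigma_ref = diag(4, 1) scales the first slope column by 2
  q <- p
  q$Sigma[, , 1] <- diag(c(4, 1))
  r <- rescale_identify(q)
  expect_equal(diag(matrix(r$Sigma[, , 1], 2, 2)), c(1, 1))
  expect_equal(r$A[, 1], q$A[, 1] * 2)
  expect_equal(r$A[, 2], q$A[, 2])

  ## the marginal likelihood is invariant under the rescaling
  inst <- rand_instance(N = 15, J = 5, K = 2, G = 2, seed = 13)
  q <- inst$params
  q$Sigma[, , 1] <- matrix(c(2.5, 0.7, 0.7, 0.9), 2, 2)
  r <- rescale_identify(q)
  expect_equal(marginal_loglik_gh(r, inst$data),
               marginal_loglik_gh(q, inst$data), tolerance = 1e-8)
  bad <- q
  bad$Sigma[1, 1, 1] <- -1
  expect_error(rescale_identify(bad), "nonpositive")
})
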