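test_that("importance samples are reproducible and match the proposal moments", {
  inst <- rand_instance(N = 3, J = 4, K = 2, G = 2, seed = 1)
  vs <- rand_varstate(inst$data, seed = 2)
  s1 <- draw_iw_samples(vs, M = 200, seed = 7)
  s2 <- draw_iw_samples(vs, M = 200, seed = 7)
  expect_identical(s1$theta, s2$theta)
  expect_identical(s1$logq, s2$logq)

  big <- draw_iw_samples(vs, M = 1e5, seed = 8)
  for (i in 1:3) {
    rows <- (i - 1) * 1e5 + seq_len(1e5)
    th <- big$theta[rows, ]
    se <- sqrt(diag(matrix(vs$sigma[, , i], 2, 2)) / 1e5)
    expect_true(all(abs(colMeans(th) - vs$mu[i, ]) < 3.5 * se))
    S <- cov(th)
    ref <- matrix(vs$sigma[, , i], 2, 2)
    expect_lt(norm(S - ref, "F") / norm(ref, "F"), 0.05)
  }
  expect_error(draw_iw_samples(vs, M = 0, seed = 1), "at least 1")
})

test_that("the IW bound approaches the marginal log-likelihood as M grows", {
  inst <- rand_instance(N = 12, J = 5, K = 2, G = 2, seed = 3)
  ## a converged variational state gives a sensible proposal
  w <- remirt:::.gvem_warm_start(inst$data, remirt_control(max_iter = 60),
                                 remirt:::.empty_fixed(inst$data))
  quad <- marginal_loglik_gh(w$params, inst$data)
  s <- draw_iw_samples(w$varstate, M = 10000, seed = 5)
  iw <- iw_elbo(w$params, s, inst$data)
  expect_lt(abs(iw - quad), 0.05)
  expect_lte(iw, quad + 0.02)

  ## expected value is nondecreasing in M
  means <- sapply(c(1, 5, 25), function(M) {
    mean(sapply(1:200, function(r) {
      iw_elbo(w$params, draw_iw_samples(w$varstate, M, seed = 1000 + r),
              inst$data)
    }))
  })
  expect_true(all(diff(means) > 0))
  ## and the M=1 average equals the ELBO's role as the loosest bound
  expect_lt(means[1], means[3])
  expect_lte(means[3], quad + 0.02)
})

test_that("a perfect proposal gives zero-variance importance weights", {
  ## with no informative items the posterior equals the prior; using the
  ## prior as proposal makes every weight exactly 1, so the bound is exact
  ## (here: zero) for any M
  inst <- rand_instance(N = 6, J = 3, K = 2, G = 2, seed = 4)
  p <- inst$params
  p$A[] <- 0; p$B[] <- 0; p$Gamma[] <- 0; p$Beta[] <- 0
  d <- inst$data
  d$Y[] <- 0   # p(Y | theta) = 1/2^J per item pattern... keep items but zero slopes
  vs <- list(mu = p$Mu[d$group, , drop = FALSE],
             sigma = array(0, c(2, 2, d$N)), xi = matrix(1, d$N, d$J))
  for (i in seq_len(d$N)) vs$sigma[, , i] <- p$Sigma[, , d$group[i]]
  exact <- d$N * d$J * log(0.5)   # constant Bernoulli(1/2) likelihood
  for (M in c(1, 7)) {
    s <- draw_iw_samples(vs, M, seed = 11)
    expect_equal(iw_elbo(p, s, d), exact, tolerance = 1e-7)
  }
})

test_that("analytic IW gradient matches central finite differences", {
  sim <- sim_remirt(n_per_group = 15, K = 2, J_per_dim = 3,
                    dif_proportion = 0.4, seed = 5)
  d <- sim$data
  ctrl <- remirt_control(max_iter = 40)
  w <- remirt:::.gvem_warm_start(d, ctrl, remirt:::.empty_fixed(d))
  enc <- remirt:::encode_params(w$params, d$Q, TRUE,
                                remirt:::.empty_fixed(d))
  s <- draw_iw_samples(w$varstate, M = 4, seed = 6)
  srt <- remirt:::.sort_by_group(d)
  ss <- remirt:::.sort_samples(s, srt$ord)
  u <- enc$u + 0.04
  vg <- remirt:::.iw_value_grad_u(u, enc$meta, ss, srt$data)
  h <- 1e-5
  for (i in seq_along(u)) {
    up <- u; up[i] <- up[i] + h
    um <- u; um[i] <- um[i] - h
    fd <- (remirt:::.iw_value_grad_u(up, enc$meta, ss, srt$data)$value -
             remirt:::.iw_value_grad_u(um, enc$meta, ss, srt$data)$value) /
      (2 * h)
    expect_lt(abs(vg$grad[i] - fd) / max(abs(fd), 1e-4), 1e-4)
  }
  ## order invariance: shuffled persons give the same value
  expect_equal(remirt:::.iw_value_grad_u(u, enc$meta, ss, srt$data)$value,
               iw_elbo(remirt:::decode_params(u, enc$meta), s, d),
               tolerance = 1e-10)
})

test_that("proximal update solves the 1-D penalized quadratic model", {
  expect_equal(proximal_update(1.3, 0, 0.1, 0, 100), 1.3)
  expect_equal(proximal_update(1, 0, 1, 0.02, 100), 0)   # s*N*lam = 2 >= |x|
  set.seed(7)
  for (r in 1:100) {
    x <- rnorm(1); g <- rnorm(1); s <- runif(1, 0.01, 1)
    lam <- runif(1, 0, 0.1); N <- sample(10:500, 1)
    upd <- proximal_update(x, g, s, lam, N)
    f <- function(z) g * (z - x) + (z - x)^2 / (2 * s) + N * lam * abs(z)
    num <- optimize(f, c(-30, 30), tol = 1e-12)$minimum
    expect_lt(abs(upd - num), 1e-6)
  }
  expect_error(proximal_update(1, 0, -1, 0, 10), "positive")
})

test_that("the IW objective decreases over early optimizer steps", {
  sim <- sim_remirt(n_per_group = 40, K = 2, J_per_dim = 3,
                    dif_proportion = 0.3, seed = 8)
  d <- sim$data
  ctrl <- remirt_control(max_iter = 60, adam_max_iter = 50, adam_window = 1e9)
  w <- remirt:::.gvem_warm_start(d, ctrl, remirt:::.empty_fixed(d))
  enc <- remirt:::encode_params(w$params, d$Q, TRUE, remirt:::.empty_fixed(d))
  s <- draw_iw_samples(w$varstate, M = 5, seed = 9)
  srt <- remirt:::.sort_by_group(d)
  ss <- remirt:::.sort_samples(s, srt$ord)
  res <- remirt:::.adam_prox(enc$u + 0.3, enc$meta, ss, srt$data, 0.01, ctrl)
  expect_lt(res$trace[50], res$trace[1])
})

test_that("IW-GVEMM fits are deterministic and reuse one sample draw", {
  sim <- sim_remirt(n_per_group = 50, K = 2, J_per_dim = 3,
                    dif_proportion = 0.3, seed = 10)
  ctrl <- remirt_control(adam_max_iter = 300)
  p1 <- fit_iw_gvemm(sim$data, lambda = c(0.005, 0.02), M = 5, seed = 3,
                     control = ctrl)
  p2 <- fit_iw_gvemm(sim$data, lambda = c(0.005, 0.02), M = 5, seed = 3,
                     control = ctrl)
  expect_identical(p1$samples$theta, p2$samples$theta)
  expect_identical(lapply(p1$fits, `[[`, "params"),
                   lapply(p2$fits, `[[`, "params"))
  expect_identical(p1$fits[[1]]$bound, p2$fits[[1]]$bound)
  ## the sampling happened once: both lambdas saw the same draws
  expect_identical(p1$samples$seed, 3L)
})

test_that("the IW bound improves on the GVEM bound at lambda = 0", {
  wins <- 0
  for (s in 1:6) {
    sim <- sim_remirt(n_per_group = 80, K = 2, J_per_dim = 3,
                      dif_proportion = 0, rho = 0.8, seed = 100 + s)
    d <- sim$data
    fx <- list(Gamma = array(TRUE, c(d$J, d$K, d$G)),
               Beta = matrix(TRUE, d$G, d$J))
    g <- fit_gvem(d, lambda = 0, fixed_zeros = fx)
    iw <- fit_iw_gvemm(d, lambda = 0, M = 10, seed = s, fixed_zeros = fx)
    if (iw$fits[[1]]$bound >= g$fits[[1]]$bound - 0.5) wins <- wins + 1
  }
  expect_gte(wins, 5)
})
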