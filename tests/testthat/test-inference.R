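# Variational Laplace, Bayesian model reduction and model comparison.

test_that("VL matches the conjugate posterior on the scalar linear model", {
  # y = theta + e, theta ~ N(0,1), noise variance fixed at 1, y = 1
  vl <- variational_laplace(function(th) th, 1, 0, 1,
                            hyper = list(mean = 0, var = 0))
  expect_equal(as.numeric(vl$mean), 0.5, tolerance = 1e-6)
  expect_equal(as.numeric(vl$cov), 0.5, tolerance = 1e-6)
  expect_equal(vl$free_energy, dnorm(1, 0, sqrt(2), log = TRUE),
               tolerance = 1e-6)
})

test_that("VL matches conjugate posteriors on a multivariate linear model", {
  set.seed(3)
  n <- 40; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  mu0 <- c(0.2, -0.1, 0)
  C0 <- diag(c(1, 0.5, 2))
  s2 <- 0.25
  th_true <- c(1, -0.5, 0.3)
  y <- as.numeric(X %*% th_true) + rnorm(n, sd = sqrt(s2))
  vl <- variational_laplace(function(th) as.numeric(X %*% th), y, mu0,
                            diag(C0), hyper = list(mean = -log(s2), var = 0))
  ref <- linear_gaussian_posterior(y, X, mu0, C0, s2)
  expect_equal(as.numeric(vl$mean), ref$mean, tolerance = 1e-6)
  expect_equal(unname(vl$cov), unname(ref$cov), tolerance = 1e-6)
  expect_equal(vl$free_energy,
               linear_gaussian_evidence(y, X, mu0, C0, s2),
               tolerance = 1e-6)
  expect_true(all(diff(vl$trace) >= -1e-8))
})

test_that("VL with zero free parameters returns the log likelihood", {
  y <- c(0.3, -0.2, 0.1)
  vl <- variational_laplace(function(th) rep(0, 3), y,
                            numeric(0), numeric(0),
                            hyper = list(mean = 0, var = 0))
  expect_equal(vl$free_energy, sum(dnorm(y, 0, 1, log = TRUE)),
               tolerance = 1e-9)
})

test_that("VL estimates the noise precision when it is free", {
  set.seed(7)
  n <- 400
  s_true <- 0.1
  y <- 2 + rnorm(n, sd = s_true)
  vl <- variational_laplace(function(th) rep(th, n), y, 0, 4,
                            hyper = list(mean = 0, var = 16))
  expect_equal(as.numeric(vl$mean), 2, tolerance = 0.05)
  expect_equal(vl$lambda, -2 * log(s_true), tolerance = 0.5)
})

test_that("BMR reproduces direct-inversion evidence differences", {
  set.seed(11)
  n <- 30; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  C0 <- diag(p)
  mu0 <- rep(0, p)
  s2 <- 0.5
  y <- as.numeric(X %*% c(1, 0.5, 0, 0)) + rnorm(n, sd = sqrt(s2))
  post <- linear_gaussian_posterior(y, X, mu0, C0, s2)
  F_full <- linear_gaussian_evidence(y, X, mu0, C0, s2)
  # identical reduced prior: no change
  same <- bayesian_model_reduction(list(mean = mu0, cov = C0), post,
                                   list(mean = mu0, cov = C0))
  expect_equal(same$dF, 0, tolerance = 1e-10)
  expect_equal(same$mean, post$mean, ignore_attr = TRUE, tolerance = 1e-10)
  # shrink parameters 3 and 4: compare with a direct reduced inversion
  vr <- 1e-8
  C0r <- C0; C0r[3, 3] <- vr; C0r[4, 4] <- vr
  red <- bayesian_model_reduction(list(mean = mu0, cov = C0), post,
                                  list(mean = mu0, cov = C0r))
  F_red <- linear_gaussian_evidence(y, X, mu0, C0r, s2)
  expect_equal(red$dF, F_red - F_full, tolerance = 1e-6)
  ref_red <- linear_gaussian_posterior(y, X, mu0, C0r, s2)
  expect_equal(red$mean, ref_red$mean, ignore_attr = TRUE,
               tolerance = 1e-6)
  # near-zero prior variance pins the parameter at (near) zero
  expect_lt(abs(red$mean[3]), 1e-4)
})

test_that("model comparison follows the closed-form softmax", {
  cmp <- compare_models(c(5, 5, 5, 5))
  expect_equal(as.numeric(cmp$probabilities), rep(0.25, 4))
  cmp2 <- compare_models(c(0, 3))
  expect_equal(as.numeric(cmp2$probabilities),
               c(1 / (1 + exp(3)), exp(3) / (1 + exp(3))),
               tolerance = 1e-12)
  cmp3 <- compare_models(c(0, 3) + 100)
  expect_equal(cmp2$probabilities, cmp3$probabilities, tolerance = 1e-12)
  expect_equal(sum(cmp2$probabilities), 1, tolerance = 1e-12)
})

test_that("family posteriors correct for family size", {
  Fs <- rep(1.234, 16)
  fam <- family_posterior(Fs, list(a = 1:8, b = 9:16))
  expect_equal(as.numeric(fam), c(0.5, 0.5), tolerance = 1e-12)
  # unequal sizes (8, 4, 4) with equal evidence: uniform over families
  fam3 <- family_posterior(Fs, list(a = 1:8, b = 9:12, c = 13:16))
  expect_equal(as.numeric(fam3), rep(1 / 3, 3), tolerance = 1e-12)
  # a dominating model carries its family
  Fs2 <- rep(0, 16); Fs2[10] <- 20
  fam2 <- family_posterior(Fs2, list(a = 1:8, b = 9:16))
  expect_gt(fam2[["b"]], 0.999)
  expect_error(family_posterior(Fs, list(1:9, 9:16)), "disjoint")
})

test_that("greedy pruning removes null parameters and is order-stable", {
  set.seed(19)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  s2 <- 0.04
  th_true <- c(1, -0.8, 0.6, 0, 0)   # two null parameters
  removed_34 <- 0
  for (rep in 1:10) {
    y <- as.numeric(X %*% th_true) + rnorm(n, sd = sqrt(s2))
    vl <- variational_laplace(function(th) as.numeric(X %*% th), y,
                              rep(0, p), rep(1, p),
                              hyper = list(mean = -log(s2), var = 0))
    pr <- prune_parameters(vl)
    removed_34 <- removed_34 + all(c(4, 5) %in% pr$pruned)
    expect_true(all(!(1:3 %in% pr$pruned)))
  }
  expect_gte(removed_34, 9)
  # final evidence is invariant to candidate ordering
  y <- as.numeric(X %*% th_true) + rnorm(n, sd = sqrt(s2))
  vl <- variational_laplace(function(th) as.numeric(X %*% th), y,
                            rep(0, p), rep(1, p),
                            hyper = list(mean = -log(s2), var = 0))
  pa <- prune_parameters(vl, candidates = 1:5)
  pb <- prune_parameters(vl, candidates = 5:1)
  expect_equal(pa$dF, pb$dF, tolerance = 1e-3)
  # all three parameters carry strong evidence: nothing pruned
  X3 <- X[, 1:3]
  vl3 <- variational_laplace(function(th) as.numeric(X3 %*% th), y,
                             rep(0, 3), rep(1, 3),
                             hyper = list(mean = -log(s2), var = 0))
  pr3 <- prune_parameters(vl3)
  expect_length(pr3$pruned, 0)
  expect_equal(pr3$posterior$mean, vl3$mean, tolerance = 1e-6)
})

test_that("the generating model wins in the reduced fMRI model space", {
  # pre/post x direct/delay, shared weights, drives from ground truth
  truth <- synthetic_truth()
  sched <- generate_schedule(n_blocks = 4, seed = 2)
  z_pre <- build_drives(truth$params, sched, reduced_model_space()$pre_direct,
                        arch = truth$arch, design = truth$design)
  z_post <- build_drives(truth$params, sched,
                         reduced_model_space()$post_direct,
                         arch = truth$arch, design = truth$design)
  wins <- 0
  n_rep <- 8
  for (rep in seq_len(n_rep)) {
    sim <- simulate_bold_dataset(truth, sched, snr = 20, seed = 500 + rep)
    Fs <- fit_reduced_space(sim$bold, z_pre, z_post, sched)
    wins <- wins + (which.max(Fs) == 1L)   # truth generated from pre_direct
  }
  expect_gte(wins, ceiling(0.9 * n_rep))
})
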