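test_that("hyperparameter grids reproduce the study sequences", {
  a <- build_grid(0.1, 1, 0.05)
  expect_length(a, 19)
  expect_equal(a[1], 0.1)
  expect_equal(a[19], 1.0)
  l <- build_grid(0.001, 0.15, 0.009)
  expect_length(l, 17)
  expect_equal(l[17], 0.145)  # 0.15 is off-grid
  expect_equal(build_grid(0.3, 0.3, 0.1), 0.3)
  g <- default_grids()
  expect_length(g$alpha, 19)
  expect_length(g$lambda, 17)
})

test_that("penalty evaluates the mixed L1/L2 form", {
  expect_equal(penalty(c(0, 0), 0.5, 1), 0)
  expect_equal(penalty(c(1, -2), 1, 1), 3)
  expect_equal(penalty(c(1, -2), 0, 2), 5)
  expect_equal(penalty(c(1, -2), 0.4, 2),
               2 * (0.4 * 3 + 0.3 * 5))
})

test_that("a huge penalty saturates to the intercept-only model", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, 0.4)
  f <- fit_elastic_net(X, y, alpha = 0.5, lambda = 50)
  expect_true(all(f$beta == 0))
  expect_equal(f$intercept, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("the solver matches unpenalized logistic regression as lambda -> 0", {
  set.seed(2)
  X <- matrix(rnorm(400), 200, 2)
  colnames(X) <- c("a", "b")
  y <- rbinom(200, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  f <- fit_elastic_net(X, y, alpha = 0.5, lambda = 1e-9)
  g <- glm(y ~ X, family = binomial)
  expect_equal(unname(f$beta), unname(coef(g)[-1]), tolerance = 1e-3)
  expect_equal(f$intercept, unname(coef(g)[1]), tolerance = 1e-3)
})

test_that("the solution is at least as good as a generic optimizer's", {
  set.seed(3)
  X <- matrix(rnorm(120), 40, 3)
  y <- rbinom(40, 1, 0.5)
  for (hp in list(c(0.7, 0.05), c(1, 0.02), c(0.1, 0.1))) {
    f <- fit_elastic_net(X, y, hp[1], hp[2])
    oracle <- optim(rep(0, 4), function(p)
      enet_objective(X, y, p[-1], p[1], hp[1], hp[2]),
      method = "Nelder-Mead",
      control = list(maxit = 8000, reltol = 1e-13))
    expect_lte(f$objective, oracle$value + 1e-6)
  }
})

test_that("the objective trace is monotone non-increasing", {
  set.seed(4)
  X <- matrix(rnorm(600), 100, 6)
  y <- rbinom(100, 1, plogis(X[, 1]))
  f <- fit_elastic_net(X, y, 0.5, 0.01)
  expect_true(all(diff(f$trace) <= 1e-12))
})

test_that("the lasso active set shrinks as lambda grows", {
  set.seed(5)
  X <- matrix(rnorm(100 * 12), 100, 12)
  y <- rbinom(100, 1, plogis(X[, 1] + 0.5 * X[, 2] - X[, 3]))
  Xs <- scale(X)
  nz <- vapply(default_grids()$lambda, function(l) {
    sum(fit_elastic_net(Xs, y, 1, l)$beta != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("coefficients agree with glmnet as an independent cross-check", {
  set.seed(6)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.6 * X[, 2]))
  Xs <- scale(X) * sqrt(n / (n - 1))  # glmnet standardizes with 1/n variance
  for (hp in list(c(1, 0.02), c(0.5, 0.05))) {
    f <- fit_elastic_net(Xs, y, hp[1], hp[2], tol = 1e-9, maxit = 200)
    g <- glmnet::glmnet(Xs, y, family = "binomial", alpha = hp[1],
                        lambda = hp[2], standardize = FALSE,
                        thresh = 1e-12)
    expect_equal(unname(f$beta), as.numeric(g$beta), tolerance = 5e-3)
  }
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_elastic_net(X, rep(1, 20), 0.5, 0.1), "both classes")
  expect_error(fit_elastic_net(X, rep(c(0, 1), 10), 1.5, 0.1))
})
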