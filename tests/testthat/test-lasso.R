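test_that("soft-threshold algebra", {
  expect_equal(soft_threshold(2, 1), 1)
  expect_equal(soft_threshold(-2, 1), -1)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(c(3, -0.2, 0), 0.5), c(2.5, 0, 0))
  # shrinkage properties on a grid of cases
  z <- seq(-3, 3, by = 0.25)
  for (lam in c(0, 0.3, 1.5)) {
    s <- soft_threshold(z, lam)
    expect_true(all(abs(s) == pmax(abs(z) - lam, 0)))
    expect_true(all(s * z >= 0)) # never flips sign
  }
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("lambda_max matches the per-column inner-product oracle", {
  inst <- make_instance(n = 120, p = 60, seed = 200)
  y <- inst$ph$y
  S <- inst$g$std
  brute <- max(vapply(seq_len(ncol(S)), function(j) abs(sum(S[, j] * y)),
                      numeric(1))) / nrow(S)
  expect_equal(lambda_max(inst$g, y), brute)

  # a single standardized column used as its own phenotype: (1/n)||y||^2 = 1
  g1 <- simulate_genotypes(500, 1, maf = 0.4, seed = 201)
  expect_equal(lambda_max(g1, as.vector(g1$std)), 1, tolerance = 1e-12)

  # orthogonal phenotype
  A <- cbind(c(1, 1, -1, -1))
  expect_equal(lambda_max(A, c(1, -1, 1, -1)), 0)
})

test_that("theoretical penalty floor follows the half-normal median at p=1", {
  g <- simulate_genotypes(400, 1, maf = 0.3, seed = 202)
  sigma_e2 <- 0.5
  lmin <- lambda_min_theoretical(g, sigma_e2, n_draws = 2000, seed = 203)
  # |A'e| ~ half-normal with scale sqrt(n); median = qnorm(0.75) sqrt(n)
  expected <- sqrt(sigma_e2 + 1 / 400) * qnorm(0.75) / sqrt(400)
  expect_equal(lmin, expected, tolerance = 0.05)

  expect_identical(lambda_min_theoretical(g, 0.5, 200, seed = 7),
                   lambda_min_theoretical(g, 0.5, 200, seed = 7))
  # noiseless floor shrinks with n through sigma* = sqrt(1/n)
  g2 <- simulate_genotypes(1600, 1, maf = 0.3, seed = 204)
  expect_lt(lambda_min_theoretical(g2, 0, 500, seed = 1),
            lambda_min_theoretical(g, 0, 500, seed = 1))
})

test_that("penalties at or above lambda_max give the exact zero solution", {
  inst <- make_instance(seed = 210)
  lmax <- lambda_max(inst$g, inst$ph$y)
  for (lam in c(lmax, 1.5 * lmax)) {
    fit <- coordinate_descent(inst$g, inst$ph$y, lam)
    expect_identical(fit$x, numeric(inst$g$p))
  }
})

test_that("unpenalized coordinate descent reproduces OLS when n > p", {
  inst <- make_instance(n = 150, p = 40, s = 5, seed = 220)
  S <- inst$g$std
  y <- inst$ph$y
  ols <- solve(crossprod(S), crossprod(S, y))
  fit <- coordinate_descent(S, y, 0, tol = 1e-12, max_sweeps = 50000)
  expect_equal(fit$x, as.vector(ols), tolerance = 1e-6)
})

test_that("single-column problem solves in closed form", {
  g <- simulate_genotypes(300, 1, maf = 0.25, seed = 230)
  y <- rnorm(300)
  lam <- 0.01
  fit <- coordinate_descent(g, y, lam)
  expect_equal(fit$x, soft_threshold(sum(g$std * y) / 300, lam),
               tolerance = 1e-12)
})

test_that("KKT conditions hold at convergence, on and off the support", {
  inst <- make_instance(n = 250, p = 120, s = 8, h2 = 0.7, seed = 240)
  tol <- 1e-6
  lam <- 0.3 * lambda_max(inst$g, inst$ph$y)
  fit <- coordinate_descent(inst$g, inst$ph$y, lam, tol = tol)
  g <- as.vector(crossprod(inst$g$std, inst$ph$y - inst$g$std %*% fit$x)) /
    inst$g$n
  on_sup <- which(fit$x != 0)
  expect_true(all(abs(g[on_sup] - lam * sign(fit$x[on_sup])) < 10 * tol))
  expect_true(all(abs(g[-on_sup]) <= lam + 10 * tol))
})

test_that("each solve can only improve the objective of its warm start", {
  inst <- make_instance(seed = 250)
  y <- inst$ph$y
  lam <- 0.2 * lambda_max(inst$g, y)
  starts <- list(numeric(inst$g$p), rnorm(inst$g$p, sd = 0.05))
  for (x0 in starts) {
    fit <- coordinate_descent(inst$g, y, lam, x_init = x0)
    expect_lte(fit$objective, lasso_objective(inst$g, y, x0, lam) + 1e-12)
  }
})

test_that("active-set and plain cyclic sweeps agree", {
  inst <- make_instance(n = 150, p = 200, s = 10, seed = 260)
  lam <- 0.1 * lambda_max(inst$g, inst$ph$y)
  a <- coordinate_descent(inst$g, inst$ph$y, lam, tol = 1e-12,
                          active_set = TRUE)
  b <- coordinate_descent(inst$g, inst$ph$y, lam, tol = 1e-12,
                          active_set = FALSE)
  expect_identical(which(a$x != 0), which(b$x != 0))
  expect_lt(max(abs(a$x - b$x)), 1e-6)
})

test_that("warm-started path equals cold starts at matching penalties", {
  inst <- make_instance(n = 200, p = 400, s = 10, h2 = 0.8, seed = 270)
  cfg <- lasso_config(n_lambda_steps = 20, tol = 1e-8)
  path <- lasso_path(inst$g, inst$ph$y, cfg, lambda_min = 0.05)
  for (k in c(5, 12, 20)) {
    cold <- coordinate_descent(inst$g, inst$ph$y, path$lambdas[k],
                               tol = 1e-8)
    denom <- max(sqrt(sum(cold$x^2)), 1)
    expect_lt(sqrt(sum((path$coefficients[, k] - cold$x)^2)) / denom, 1e-4)
  }
})

test_that("path solutions match an independent solver (glmnet) oracle", {
  skip_if_not_installed("glmnet")
  inst <- make_instance(n = 200, p = 400, s = 12, h2 = 0.8, seed = 280)
  S <- inst$g$std
  y <- inst$ph$y
  cfg <- lasso_config(n_lambda_steps = 10, tol = 1e-9)
  path <- lasso_path(S, y, cfg, lambda_min = 0.1 * lambda_max(S, y))
  gl <- glmnet::glmnet(S, y, lambda = path$lambdas, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-12)
  for (k in c(3, 7, 10)) {
    ours <- path$coefficients[, k]
    theirs <- as.numeric(gl$beta[, k])
    denom <- max(sqrt(sum(theirs^2)), 1e-8)
    expect_lt(sqrt(sum((ours - theirs)^2)) / denom, 1e-4)
  }
})

test_that("path structure: zero head, inclusive endpoints, descent", {
  inst <- make_instance(seed = 290)
  y <- inst$ph$y
  cfg <- lasso_config(n_lambda_steps = 30, sigma_e2 = 0.2, seed = 3)
  path <- lasso_path(inst$g, y, cfg)
  K <- length(path$lambdas)
  expect_identical(path$coefficients[, 1], numeric(inst$g$p))
  expect_equal(path$lambdas[1], path$lambda_max)
  expect_equal(path$lambdas[K], path$lambda_min)
  expect_true(all(diff(path$lambdas) < 0))
  expect_lte(path$objective[K],
             lasso_objective(inst$g, y, numeric(inst$g$p), path$lambdas[K]))

  expect_warning(lasso_path(inst$g, y, cfg, lambda_min = 10), "all-zero")
})

test_that("support selection is the exact nonzero set of the terminal fit", {
  inst <- make_instance(seed = 300)
  path <- lasso_path(inst$g, inst$ph$y, lasso_config(n_lambda_steps = 20),
                     lambda_min = 0.02)
  sel <- lasso_select(path)
  expect_identical(sel$support, which(path$coefficients[, 20] != 0))

  zp <- suppressWarnings(lasso_path(inst$g, inst$ph$y, lasso_config(),
                                    lambda_min = 10))
  expect_length(lasso_select(zp)$support, 0)

  # a stricter terminal penalty selects no more markers on the same data
  loose <- lasso_select(lasso_path(inst$g, inst$ph$y,
                                   lasso_config(n_lambda_steps = 20),
                                   lambda_min = 0.02))
  strict <- lasso_select(lasso_path(inst$g, inst$ph$y,
                                    lasso_config(n_lambda_steps = 20),
                                    lambda_min = 0.1))
  expect_lte(length(strict$support), length(loose$support))
})

test_that("deep-recovery noiseless instance is solved to small error", {
  g <- simulate_genotypes(500, 1000, maf = c(0.05, 0.5), seed = 310)
  spec <- ensemble_spec("signs", s = 10, p = 1000)
  x <- place_support(draw_coefficients(spec, 1000, seed = 311), g, seed = 312)
  ph <- simulate_phenotype(g, true_model(x, 1), seed = 313)
  lmin <- lambda_min_theoretical(g, 0, 500, seed = 314)
  path <- lasso_path(g, ph$y, lasso_config(), lambda_min = lmin)
  expect_lt(normalized_error(ph$x, lasso_select(path)$x_hat), 0.05)
})

test_that("cross-validation picks large penalties for noise, small for signal", {
  cfg <- lasso_config(n_lambda_steps = 25)
  # pure noise: the best penalty sits high on the grid
  picks <- vapply(1:10, function(r) {
    g <- simulate_genotypes(120, 200, maf = c(0.1, 0.5), seed = 400 + r)
    set.seed(500 + r)
    y <- rnorm(120)
    cv <- cv_lambda(g, y, k = 10, cfg, lambda_min = 0.1, seed = 600 + r)
    cv$index
  }, numeric(1))
  expect_lte(median(picks), 25 / 4) # top quartile of the descending grid

  # strong noiseless signal: the best penalty sits in the lower half
  picks2 <- vapply(1:5, function(r) {
    inst <- make_instance(n = 150, p = 100, s = 5, h2 = 1, seed = 700 + r)
    cv <- cv_lambda(inst$g, inst$ph$y, k = 10, cfg,
                    lambda_min = 0.01 * lambda_max(inst$g, inst$ph$y),
                    seed = 800 + r)
    cv$index
  }, numeric(1))
  expect_gte(median(picks2), 25 / 2)

  g <- simulate_genotypes(60, 30, seed = 900)
  y <- rnorm(60)
  a <- cv_lambda(g, y, k = 5, cfg, lambda_min = 0.05, seed = 1)
  b <- cv_lambda(g, y, k = 5, cfg, lambda_min = 0.05, seed = 1)
  expect_identical(a$folds, b$folds)
  expect_error(cv_lambda(g, y, k = 100, cfg, lambda_min = 0.05), "n < k")
})

test_that("non-finite inputs are rejected", {
  inst <- make_instance(n = 50, p = 20, seed = 320)
  y <- inst$ph$y
  y[1] <- NA
  expect_error(coordinate_descent(inst$g, y, 0.1), "non-finite")
  expect_error(lasso_path(inst$g, y, lasso_config(), lambda_min = 0.01),
               "non-finite")
})
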