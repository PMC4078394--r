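test_that("transition detection interpolates, censors, and reports misses", {
  # interpolated largest-rho crossing of the NE criterion
  det <- detect_transition(c(0.02, 0.03, 0.05), c(0.1, 0.2, 0.8), "ne_rho")
  expect_equal(det$critical, 0.04)
  expect_false(det$censored)

  # all below the criterion: censored at the scan edge
  det2 <- detect_transition(c(0.02, 0.03, 0.05), c(0.1, 0.2, 0.3), "ne_rho")
  expect_equal(det2$critical, 0.05)
  expect_true(det2$censored)

  # never met
  det3 <- detect_transition(c(0.02, 0.03, 0.05), c(0.8, 0.9, 0.95), "ne_rho")
  expect_true(is.na(det3$critical))

  # first downward crossing along a sample-size scan, interpolated
  det4 <- detect_transition(c(500, 1000, 1500), c(0.9, 0.3, 0.1), "ne_n")
  expect_equal(det4$critical, 500 + 500 * (0.5 - 0.9) / (0.3 - 0.9))

  expect_error(detect_transition(c(1, 2), c(0.1, 0.2), "ne_rho"), "3 scan")
  expect_error(detect_transition(c(2, 1, 3), c(0.1, 0.2, 0.3), "ne_rho"),
               "increasing")
})

test_that("median-P-value detector uses the last sustained downward crossing", {
  n <- seq(500, 3500, by = 500)
  # characteristic rise then fall across the transition
  mu <- c(0.02, 0.05, 0.08, 0.03, 0.002, 0.0005, 0.0001)
  det <- detect_transition(n, mu, "mu_n", frac = 0.05)
  expect_equal(det$critical, 2500) # 0.002/0.08 = 0.025 < 0.05, sustained

  # an early dip that does not persist is ignored
  mu2 <- c(0.001, 0.05, 0.08, 0.03, 0.002, 0.0005, 0.0001)
  expect_equal(detect_transition(n, mu2, "mu_n")$critical, 2500)

  # never sustained below the fraction
  mu3 <- c(0.02, 0.05, 0.08, 0.06, 0.05, 0.04, 0.05)
  expect_true(is.na(detect_transition(n, mu3, "mu_n")$critical))
})

test_that("convergence detector applies absolute and plateau rules", {
  n <- seq(1000, 5000, by = 1000)
  ppv <- c(0.4, 0.8, 0.96, 0.97, 0.98)
  fpr <- c(0.01, 0.002, 0.0005, 0.0002, 0.0001)
  mu <- c(0.01, 0.02, 0.0005, 0.0002, 0.0001)
  det <- detect_convergence(n, ppv, mu, fpr, rule = "absolute")
  expect_equal(det$critical, 3000)

  det2 <- detect_convergence(n, c(0.4, 0.85, 0.88, 0.9, 0.89), mu,
                             rule = "plateau")
  expect_equal(det2$critical, 3000) # PPV within 0.05 of final from n=2000, mu from 3000

  never <- detect_convergence(n, c(0.2, 0.3, 0.2, 0.3, 0.2), mu,
                              rule = "absolute")
  expect_true(is.na(never$critical))
})

test_that("theoretical recovery boundary is monotone and well-behaved", {
  d <- seq(0.05, 0.95, by = 0.05)
  rho <- theoretical_boundary(d)
  expect_true(all(diff(rho) > 0)) # strictly increasing in delta
  expect_true(all(rho > 0 & rho < 1))
  expect_gt(theoretical_boundary(0.999), 0.9) # approaches 1 with delta
  # the known good-recovery design point sits below the curve
  expect_gt(theoretical_boundary(0.19), 0.08)
  expect_error(theoretical_boundary(0), "delta")
  expect_error(theoretical_boundary(1), "delta")
})

test_that("experiments are exactly reproducible under a fixed seed", {
  g <- simulate_genotypes(300, 400, seed = 90)
  a <- run_experiment(g, 200, 10, 0.8, reps = 2, seed = 91)
  b <- run_experiment(g, 200, 10, 0.8, reps = 2, seed = 91)
  expect_identical(a$replicates, b$replicates)
  expect_equal(a$delta, 200 / 400)
  expect_equal(a$rho, 10 / 200)
  # a different seed gives different phenotype draws
  c3 <- run_experiment(g, 200, 10, 0.8, reps = 2, seed = 92)
  expect_false(identical(a$replicates$ne, c3$replicates$ne))
})

test_that("noiseless recovery succeeds below the boundary, fails above", {
  g <- simulate_genotypes(500, 1000, maf = c(0.05, 0.5), seed = 93)
  lo <- run_experiment(g, 500, 25, 1, reps = 10, seed = 94) # rho 0.05
  hi <- run_experiment(g, 500, 350, 1, reps = 10, seed = 95) # rho 0.70
  expect_lt(lo$aggregates[["ne"]], 0.05)
  expect_gt(hi$aggregates[["ne"]], 0.5)
  # clear recovery at rho = 0.1 as well, if not to the same depth
  mid <- run_experiment(g, 500, 50, 1, reps = 10, seed = 96)
  expect_lt(mid$aggregates[["ne"]], 0.1)
})

test_that("noise can only hurt the coefficient error", {
  g <- simulate_genotypes(400, 800, maf = c(0.05, 0.5), seed = 97)
  for (sdx in 1:3) {
    clean <- run_experiment(g, 400, 20, 1, reps = 5, seed = 200 + sdx)
    noisy <- run_experiment(g, 400, 20, 0.5, reps = 5, seed = 200 + sdx)
    expect_gte(noisy$aggregates[["ne"]], clean$aggregates[["ne"]])
  }
})

test_that("plane sweeps assemble feasible points and skip the rest", {
  g <- simulate_genotypes(300, 400, seed = 98)
  grid <- data.frame(delta = c(0.25, 0.5, 0.25, 0.5),
                     rho = c(0.05, 0.05, 0.2, 0.2))
  pl <- sweep_plane(g, grid, h2 = 0.8, reps = 1, seed = 99)
  expect_equal(nrow(pl$surface), 4)
  expect_equal(pl$surface$n, as.integer(round(grid$delta * 400)))
  expect_true(all(c("ne", "ppv", "fpr", "mu_pvalue") %in%
                    colnames(pl$surface)))
  # distinct seeds -> the two equal-n points differ by their draws
  expect_false(identical(pl$surface$ne[1], pl$surface$ne[3]))

  big <- data.frame(delta = c(0.5, 2), rho = c(0.05, 0.05))
  expect_warning(sweep_plane(g, big, h2 = 0.8, reps = 1, seed = 1),
                 "infeasible")
})

test_that("a fixed-n sparsity scan yields an NE-versus-rho curve object", {
  g <- simulate_genotypes(250, 500, seed = 101)
  sc <- sweep_rho(g, 250, c(0.04, 0.3, 0.7), h2 = 1, reps = 1, seed = 102)
  expect_equal(sc$surface$s, c(10L, 75L, 175L))
  expect_true(all(diff(sc$surface$rho) > 0))
  expect_true(all(diff(sc$surface$ne) > 0)) # recovery degrades with rho
})

test_that("empirical noiseless contour tracks the theoretical boundary", {
  g <- simulate_genotypes(800, 1000, maf = c(0.05, 0.5), seed = 70)
  for (d in c(0.2, 0.5, 0.8)) {
    b <- theoretical_boundary(d)
    rhos <- round(b + seq(-0.12, 0.12, by = 0.06), 3)
    sc <- sweep_rho(g, round(d * 1000), rhos, h2 = 1, reps = 3,
                    seed = round(100 * d))
    det <- detect_transition(sc$surface$rho, sc$surface$ne, "ne_rho")
    expect_false(is.na(det$critical))
    expect_lt(abs(det$critical - b), 0.1)
  }
})

test_that("the rule-of-thumb sample size inverts the critical ratio", {
  expect_equal(min_sample_size(1200, rho_crit = 0.03), 40000)
  expect_gte(min_sample_size(100), 30 * 100)
  expect_error(min_sample_size(10, 0), "> 0")
})
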