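test_that("MBAR gives zero between identical windows", {
  withr::with_seed(1, x <- stats::rnorm(400))
  u <- rbind(0.5 * x^2, 0.5 * x^2)
  tab <- window_table(u, c(200, 200))
  fit <- mbar(tab)
  expect_lt(abs(mbar_dg(fit)), 1e-10)
})

test_that("MBAR recovers the analytic harmonic free energy", {
  # windows k and 4k: dG = (RT/2) ln 4, exact i.i.d. draws
  tab <- exact_harmonic_table(c(2, 8), n_per = 10000, seed = 3)
  est <- free_energy_estimate(tab, "mbar", n_blocks = 10)
  analytic <- RT298 / 2 * log(4)
  expect_lt(abs(est$value - analytic), 3 * est$uncertainty)
  expect_lt(est$uncertainty, 0.05)
})

test_that("MBAR pairwise differences match numerical configuration integrals", {
  k <- c(1, 3, 9)
  centers <- c(0, 0.4, 0.8)
  tab <- exact_harmonic_table(k, centers, n_per = 4000, seed = 11)
  fit <- mbar(tab)
  blocks <- abfekit:::split_table_blocks(tab, 10)
  for (j in 2:3) {
    oracle <- quadrature_dg(
      function(x) 0.5 * k[1] * (x - centers[1])^2,
      function(x) 0.5 * k[j] * (x - centers[j])^2)
    bv <- vapply(blocks, function(b) mbar_dg(mbar(b), 1, j), numeric(1))
    se <- stats::sd(bv) / sqrt(length(bv))
    expect_lt(abs(mbar_dg(fit, 1, j) - oracle), 3 * se)
  }
})

test_that("MBAR free energies are invariant to per-sample shifts and close cycles", {
  tab <- exact_harmonic_table(c(1, 2, 5), c(0, 0.3, -0.2),
                              n_per = 800, seed = 5)
  fit <- mbar(tab)
  # add an arbitrary constant to every column (per-sample shift)
  withr::with_seed(9, shifts <- stats::rnorm(ncol(tab$u), 0, 3))
  tab2 <- window_table(sweep(tab$u, 2, shifts, "+"), tab$n_k)
  fit2 <- mbar(tab2)
  expect_equal(fit2$f_kcal, fit$f_kcal, tolerance = 1e-6)
  # antisymmetry and cycle closure are exact for a single fit
  expect_identical(mbar_dg(fit, 1, 2), -mbar_dg(fit, 2, 1))
  expect_equal(mbar_dg(fit, 1, 2) + mbar_dg(fit, 2, 3) + mbar_dg(fit, 3, 1),
               0, tolerance = 1e-12)
})

test_that("MBAR reports non-convergence with the last residual", {
  tab <- exact_harmonic_table(c(1, 4), n_per = 200, seed = 2)
  expect_error(mbar(tab, tol = 1e-14, max_iter = 2), "converge")
})

test_that("BAR agrees with two-state MBAR and the analytic limit", {
  tab <- exact_harmonic_table(c(2, 8), n_per = 10000, seed = 3)
  expect_lt(abs(bar(tab) - mbar_dg(mbar(tab))), 1e-8)
  est <- free_energy_estimate(tab, "bar", n_blocks = 10)
  expect_lt(abs(est$value - RT298 / 2 * log(4)), 3 * est$uncertainty)

  same <- exact_harmonic_table(c(3, 3), n_per = 500, seed = 8)
  expect_lt(abs(bar(same)), 0.05)
  for (seed in c(4, 6)) {
    t2 <- exact_harmonic_table(c(1.5, 5), c(0, 0.5), n_per = 700,
                               seed = seed)
    expect_lt(abs(bar(t2) - mbar_dg(mbar(t2))), 1e-8)
  }
  three <- exact_harmonic_table(c(1, 2, 3), n_per = 100, seed = 1)
  expect_error(bar(three), "two windows")
})

test_that("Gauss-Legendre schedules have the exact nodes and weights", {
  s1 <- gq_schedule(1)
  expect_equal(s1$lambdas, 0.5)
  expect_equal(s1$weights, 1)
  s2 <- gq_schedule(2)
  expect_equal(s2$lambdas, c(0.5 - 1 / (2 * sqrt(3)), 0.5 + 1 / (2 * sqrt(3))))
  expect_equal(s2$weights, c(0.5, 0.5))
  for (n in c(3, 8, 21, 64)) {
    s <- gq_schedule(n)
    expect_equal(sum(s$weights), 1, tolerance = 1e-12)
    expect_equal(sum(s$weights * s$lambdas), 0.5, tolerance = 1e-12)
    expect_true(all(diff(s$lambdas) > 0))
  }
  expect_error(gq_schedule(0))
  expect_error(gq_schedule(65))
})

test_that("TI-GQ integrates polynomials of degree 2n-1 exactly", {
  expect_equal(ti_gq(rep(2.7, 4), gq_schedule(4)), 2.7)
  expect_equal(ti_gq(rep(0, 6), gq_schedule(6)), 0)
  for (n in c(2, 4, 7)) {
    deg <- 2 * n - 1
    withr::with_seed(n, coef <- stats::runif(deg + 1, -3, 3))
    poly <- function(l) {
      vapply(l, function(li) sum(coef * li^(0:deg)), numeric(1))
    }
    exact <- sum(coef / (1:(deg + 1)))   # integral of sum c_j l^j on [0,1]
    sch <- gq_schedule(n)
    expect_equal(ti_gq(poly(sch$lambdas), sch), exact, tolerance = 1e-10)
  }
  expect_error(ti_gq(rep(1, 3), gq_schedule(4)), "per quadrature node")
})

test_that("finite-difference dU/dlambda is exact for lambda-linear potentials", {
  # U(x, lambda) = 0.5 k (x - c)^2 + lambda * offset: derivative == offset
  p <- toy_potential("lambda_coupled", kA = 4, cA = 0.3, kB = 4, cB = 0.3,
                     offsetB = 2.6)
  sam <- toy_fd_sampler(p, n_samples = 300, seed = 2)
  expect_equal(fd_dudl(sam, 0.5), 2.6, tolerance = 1e-9)
  expect_equal(fd_dudl(sam, 0.2, delta_lambda = 0.05), 2.6,
               tolerance = 1e-9)
  # the documented default bracket width is 0.001
  expect_identical(formals(fd_dudl)$delta_lambda, 0.001)
})

test_that("finite-difference dU/dlambda matches the analytic toy derivative", {
  p <- toy_potential("lambda_coupled", kA = 3, cA = 0.2, kB = 8, cB = -0.1,
                     offsetB = 1.2)
  for (lam in c(0.25, 0.6)) {
    ests <- vapply(1:4, function(seed) {
      fd_dudl(toy_fd_sampler(p, n_samples = 3000, seed = seed), lam)
    }, numeric(1))
    se <- stats::sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - toy_analytic_dudl(p, lam)),
              3 * se + 1e-8)
  }
})

test_that("TI-GQ over analytic toy derivatives reproduces the analytic dG", {
  p <- toy_potential("lambda_coupled", kA = 3, cA = 0.2, kB = 8, cB = -0.1,
                     offsetB = 1.2)
  sch <- gq_schedule(8)
  expect_equal(ti_gq(toy_analytic_dudl(p, sch$lambdas), sch),
               toy_analytic_dg(p), tolerance = 1e-6)
})

test_that("block uncertainty follows the standard-error scaling", {
  expect_equal(block_uncertainty(rep(3.2, 100), 10), 0)
  expect_error(block_uncertainty(1:5, 10), "shorter")
  expect_error(block_uncertainty(1:10, 1), "at least 2")

  # i.i.d. unit variance, length 1e4, 10 blocks: ~ 1/sqrt(1e4) on average
  uncs <- vapply(1:100, function(seed) {
    withr::with_seed(seed, block_uncertainty(stats::rnorm(1e4), 10))
  }, numeric(1))
  expect_lt(abs(mean(uncs) - 0.01), 0.003)

  # doubling the series length halves the squared uncertainty in expectation
  uncs2 <- vapply(1:100, function(seed) {
    withr::with_seed(seed + 500, block_uncertainty(stats::rnorm(2e4), 10))
  }, numeric(1))
  expect_equal(mean(uncs2^2) / mean(uncs^2), 0.5, tolerance = 0.2)
})

test_that("replica statistics use the mean and population SD", {
  r <- replica_stats(c(-7.2, -7.4, -7.4, -7.6, -7.0, -7.4))
  expect_equal(r$mean_1dp, -7.3)
  expect_equal(r$spread_1dp, 0.2)
  r2 <- replica_stats(c(-6.9, -7.2, -4.5, -8.6, -8.1, -6.0))
  expect_equal(r2$mean_1dp, -6.9)
  expect_equal(replica_stats(c(2, 2, 2))$spread, 0)
  expect_error(replica_stats(5), "at least 2")
})

test_that("window tables round-trip through both text formats", {
  tab <- exact_harmonic_table(c(1, 4), n_per = 50, seed = 12)
  for (fmt in c("tidy", "matrix")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_window_table(tab, path, format = fmt)
    back <- read_window_table(path)
    expect_equal(back$u, tab$u, tolerance = 1e-12)
    expect_equal(back$n_k, tab$n_k)
  }
  long <- tidy(tab)
  expect_equal(nrow(long), 2 * 100)
})
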