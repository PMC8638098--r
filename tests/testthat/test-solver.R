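test_that("penalized objective equals loss plus weighted penalty", {
  cv <- random_cov_pair(4, seed = 1)
  withr::with_seed(1, {
    D <- matrix(rnorm(16), 4, 4)
    W <- matrix(runif(16, 0.2, 1), 4, 4)
  })
  expect_equal(wdtrace_objective(matrix(0, 4, 4), cv, W, 0.5), 0)
  expect_equal(wdtrace_objective(D, cv, W, 0), dtrace_loss(D, cv))
  expect_equal(wdtrace_objective(D, cv, W, 0.3),
               oracle_dtrace_loss(D, cv) + 0.3 * sum(W * abs(D)),
               tolerance = 1e-12)
  pen_off <- W * abs(D); diag(pen_off) <- 0
  expect_equal(wdtrace_objective(D, cv, W, 0.3, penalize_diagonal = FALSE),
               oracle_dtrace_loss(D, cv) + 0.3 * sum(pen_off),
               tolerance = 1e-12)
})

test_that("unpenalized solution recovers the precision-matrix difference", {
  sc <- make_precision_pair(5, 4, 2, 0.4, seed = 10)
  X <- sample_expression(sc$theta_X, 1e4, seed = 1)
  Y <- sample_expression(sc$theta_Y, 1e4, seed = 2)
  cv <- cov_pair(X, Y)
  fit <- solve_wdtrace(cv, lam = 0, tol = 1e-12, max_iter = 20000)
  closed <- solve(cv$sigma_Y) - solve(cv$sigma_X)
  expect_true(fit$trace$converged)
  expect_lt(max(abs(fit$network$delta - closed)), 1e-3)
})

test_that("lambda_max is the exact boundary of the all-zero solution", {
  # identical covariances -> zero
  withr::with_seed(3, X <- matrix(rnorm(4 * 30), 4, 30))
  same <- cov_pair(X, X)
  expect_equal(lambda_max(same), 0)

  # all-ones weights -> max abs entry of the covariance difference
  cv <- random_cov_pair(4, seed = 4)
  expect_equal(lambda_max(cv), max(abs(cv$sigma_X - cv$sigma_Y)))

  # a dominant prior-weighted entry raises the ratio
  D <- abs(cv$sigma_X - cv$sigma_Y)
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  W <- matrix(1, 4, 4)
  W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- 0.1
  expect_equal(lambda_max(cv, W), max(D) / 0.1)

  # solution is exactly zero at lambda_max and above, nonzero just below
  for (s in 1:5) {
    cvs <- random_cov_pair(4, n = 40, seed = s)
    lm <- lambda_max(cvs)
    expect_true(all(solve_wdtrace(cvs, lam = lm)$network$delta == 0))
    expect_true(all(solve_wdtrace(cvs, lam = 1.05 * lm)$network$delta == 0))
    expect_gt(sum(solve_wdtrace(cvs, lam = 0.95 * lm,
                                tol = 1e-10)$network$delta != 0), 0)
  }
})

test_that("solver matches an independent convex-programming solution", {
  cases <- expand.grid(p = 3:5, lam = c(0.05, 0.1, 0.3))
  for (r in seq_len(nrow(cases))) {
    p <- cases$p[r]; lam <- cases$lam[r]
    cv <- random_cov_pair(p, n = 30, seed = r)
    withr::with_seed(100 + r, W <- matrix(runif(p * p, 0.3, 1), p, p))
    W <- (W + t(W)) / 2
    fit <- solve_wdtrace(cv, W, lam, tol = 1e-12, max_iter = 20000)
    orac <- oracle_convex_solve(cv, W, lam)
    f_fit <- wdtrace_objective(fit$network$delta, cv, W, lam)
    expect_lt(abs(f_fit - orac$value), 1e-6)
  }
})

test_that("objective decreases monotonically with restart on", {
  cv <- random_cov_pair(6, n = 40, seed = 20)
  fit <- solve_wdtrace(cv, lam = 0.1 * lambda_max(cv), tol = 1e-10)
  obj <- fit$trace$objective_per_iter
  expect_true(all(diff(obj) <= 1e-12))
  expect_true(all(is.finite(obj)))
  expect_lte(obj[length(obj)], 0)  # no worse than the zero start
})

test_that("solution is symmetric and antisymmetric under condition swap", {
  cv <- random_cov_pair(5, n = 40, seed = 21)
  lam <- 0.3 * lambda_max(cv)
  fit <- solve_wdtrace(cv, lam = lam, tol = 1e-10)
  D <- fit$network$delta
  expect_identical(D, t(D))
  swapped <- cv
  swapped$sigma_X <- cv$sigma_Y; swapped$sigma_Y <- cv$sigma_X
  D2 <- solve_wdtrace(swapped, lam = lam, tol = 1e-10)$network$delta
  expect_equal(D2, -D, tolerance = 1e-8)
})

test_that("support grows as the penalty decreases on well-separated instances", {
  sc <- make_precision_pair(15, 10, 5, 0.4, seed = 30)
  X <- sample_expression(sc$theta_X, 300, seed = 31)
  Y <- sample_expression(sc$theta_Y, 300, seed = 32)
  cv <- cov_pair(X, Y)
  grid <- stars_lambda_grid(lambda_max(cv), n_lambda = 8)
  sizes <- sapply(grid, function(l) nrow(solve_wdtrace(cv, lam = l)$network$support))
  # statistical check: non-decreasing in all but at most one step
  expect_lte(sum(diff(sizes) < 0), 1)
})

test_that("non-convergence is reported, never silent", {
  cv <- random_cov_pair(5, n = 40, seed = 22)
  expect_warning(fit <- solve_wdtrace(cv, lam = 0, max_iter = 3, tol = 1e-14),
                 "not converged")
  expect_false(fit$trace$converged)
})
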