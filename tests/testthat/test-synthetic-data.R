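test_that("precision pair plants the requested differential structure", {
  # no differential perturbation -> zero difference
  sc0 <- make_precision_pair(10, 5, 0, magnitude = 0.3, seed = 1)
  expect_equal(sc0$delta_true, matrix(0, 10, 10), ignore_attr = TRUE)
  expect_equal(nrow(sc0$diff_edges), 0)

  # differential edge count is exact by construction
  sc4 <- make_precision_pair(10, 0, 4, magnitude = 0.3, seed = 2)
  expect_equal(nrow(sc4$diff_edges), 4)

  sc <- make_precision_pair(30, 20, 10, magnitude = 0.4, seed = 3)
  for (th in list(sc$theta_X, sc$theta_Y)) {
    expect_true(min(eigen(th, symmetric = TRUE, only.values = TRUE)$values) > 0)
    expect_equal(th, t(th))
  }
  expect_equal(sc$delta_true, t(sc$delta_true))
  expect_equal(sc$delta_true, sc$theta_Y - sc$theta_X)
  # diff_edges is exactly the off-diagonal support of delta_true
  sup <- which(sc$delta_true != 0 & upper.tri(sc$delta_true), arr.ind = TRUE)
  expect_setequal(paste(sup[, 1], sup[, 2]),
                  paste(sc$diff_edges[, 1], sc$diff_edges[, 2]))
})

test_that("positive-definiteness conditioning leaves the off-diagonal difference intact", {
  sc <- make_precision_pair(15, 10, 6, magnitude = 0.5, seed = 7)
  off <- sc$delta_true; diag(off) <- 0
  expect_equal(sort(unique(abs(off[off != 0]))), 0.5)
  expect_equal(diag(sc$delta_true), rep(0, 15), ignore_attr = TRUE)
  # identical diagonal shift: both diagonals are the same constant
  expect_equal(diag(sc$theta_X), diag(sc$theta_Y))
  expect_equal(length(unique(round(diag(sc$theta_X), 12))), 1L)
})

test_that("generators are pure functions of their arguments", {
  expect_identical(make_precision_pair(12, 8, 4, 0.3, seed = 5),
                   make_precision_pair(12, 8, 4, 0.3, seed = 5))
  th <- make_precision_pair(6, 3, 2, 0.3, seed = 1)$theta_X
  expect_identical(sample_expression(th, 50, seed = 9),
                   sample_expression(th, 50, seed = 9))
  expect_identical(make_nb_counts(20, 5, 3, 2, seed = 4),
                   make_nb_counts(20, 5, 3, 2, seed = 4))
  expect_false(identical(sample_expression(th, 50, seed = 9),
                         sample_expression(th, 50, seed = 10)))
})

test_that("expression sampling matches its Gaussian model", {
  # identity precision: sample covariance converges entrywise to I
  X <- sample_expression(diag(5), 1e5, seed = 0)
  S <- sample_covariance(X, center = FALSE)
  expect_lt(max(abs(S - diag(5))), 0.05)

  # general precision: empirical covariance approaches theta^{-1}
  sc <- make_precision_pair(5, 4, 2, 0.4, seed = 2)
  Xg <- sample_expression(sc$theta_X, 1e5, seed = 3)
  expect_lt(max(abs(sample_covariance(Xg) - solve(sc$theta_X))), 0.05)

  # minimal n keeps the shape contract
  expect_equal(dim(sample_expression(diag(5), 2, seed = 1)), c(5, 2))
  # non-positive-definite precision is rejected
  bad <- diag(3); bad[1, 1] <- -1
  expect_error(sample_expression(bad, 10, seed = 1), "positive definite")
})

test_that("synthetic prior networks cover the planted edges as requested", {
  sc <- make_precision_pair(20, 5, 10, 0.4, seed = 11)
  ids <- sc$gene_ids
  true_keys <- paste(ids[sc$diff_edges[, 1]], ids[sc$diff_edges[, 2]])

  full <- make_prior_network(sc, coverage = 1, noise_edges = 0, seed = 1)
  expect_setequal(paste(full$edges$a, full$edges$b), true_keys)

  empty <- make_prior_network(sc, coverage = 0, noise_edges = 0, seed = 1)
  expect_equal(nrow(empty$edges), 0)
  W <- build_weight_matrix(empty, ids, w = 0.1)
  expect_true(all(W$W == 1))

  half <- make_prior_network(sc, coverage = 0.5, noise_edges = 5, seed = 2)
  keys <- paste(half$edges$a, half$edges$b)
  expect_equal(nrow(half$edges), 10)
  expect_equal(sum(keys %in% true_keys), 5)
  expect_equal(sum(!keys %in% true_keys), 5)
})

test_that("NB counts follow the stated mean-dispersion model", {
  # no planted genes -> all true fold changes zero
  sc0 <- make_nb_counts(50, 5, n_de = 0, seed = 1)
  expect_true(all(sc0$true_lfc == 0))
  expect_true(all(sc0$counts >= 0))
  expect_true(is.integer(sc0$counts))

  # Poisson limit below the dispersion floor: variance ~ mean
  scp <- make_nb_counts(1, 5e4, n_de = 0, dispersion = 0, base_mean = 50, seed = 2)
  x <- as.numeric(scp$counts)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)

  # variance/mean relationship v = mu + alpha mu^2 at alpha = 0.1
  scn <- make_nb_counts(1, 1e4, n_de = 0, dispersion = 0.1, base_mean = 100, seed = 3)
  x <- as.numeric(scn$counts)
  expect_lt(abs(var(x) / (100 + 0.1 * 100^2) - 1), 0.1)

  # planted fold change: group-mean ratio near 2^3 at n = 200/group
  scd <- make_nb_counts(5, 200, n_de = 1, lfc = 3, base_mean = 100, seed = 4)
  g <- scd$group_labels
  ratio <- mean(scd$counts[1, g == "B"]) / mean(scd$counts[1, g == "A"])
  expect_lt(abs(ratio - 8) / 8, 0.25)
})

test_that("gene sets include the differential-edge signal set", {
  sc <- make_precision_pair(20, 5, 6, 0.4, seed = 5)
  sets <- make_gene_sets(sc, n_random = 3, set_size = 8, seed = 1)
  expect_true("diff_edge_genes" %in% names(sets))
  expect_setequal(sets$diff_edge_genes,
                  unique(sc$gene_ids[as.vector(sc$diff_edges)]))
  expect_length(sets, 4)
})
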