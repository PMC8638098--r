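test_that("low-expression filter keeps exactly the genes above the row-sum threshold", {
  K <- matrix(c(0, 0, 0, 0,
                5, 3, 1, 1,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("zero", "ten", "eight"), paste0("s", 1:4)))
  expect_equal(rownames(filter_low_expressed(K, 1)), c("ten", "eight"))
  expect_equal(filter_low_expressed(K, 0), K)
  expect_equal(rownames(filter_low_expressed(K, 10)), "ten")
  expect_error(filter_low_expressed(K, 100), "every gene")

  # scenario bookkeeping follows the subset
  sc <- make_nb_counts(20, 5, n_de = 3, lfc = 2, seed = 1)
  sc$counts[2, ] <- 0L  # knock out one planted gene
  f <- filter_low_expressed(sc, 1)
  expect_equal(nrow(f$counts), 19)
  expect_equal(f$de_genes, c(1, 2))  # genes 1 and 3, reindexed
  expect_equal(f$true_lfc[f$de_genes], c(2, 2))
})

test_that("size factors are median-of-ratios with geometric-mean-1 scaling", {
  K <- matrix(rep(c(10, 20, 30), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(K)), rep(1, 4))

  # doubling one sample doubles its factor relative to the others
  K2 <- K; K2[, 4] <- K[, 4] * 2
  sf <- size_factors(K2)
  expect_equal(unname(sf[4] / sf[1]), 2, tolerance = 1e-12)

  # literal hand computation on a random fixture
  withr::with_seed(7, Kr <- matrix(rpois(40, 50) + 1, 8, 5))
  rownames(Kr) <- paste0("g", 1:8); colnames(Kr) <- paste0("s", 1:5)
  gm <- apply(Kr, 1, function(x) exp(mean(log(x))))
  hand <- apply(sweep(Kr, 1, gm, "/"), 2, median)
  hand <- hand / exp(mean(log(hand)))
  expect_equal(unname(size_factors(Kr)), unname(hand))

  # all-zero-containing genes force the library-size fallback
  Kz <- matrix(c(0, 5, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(sfz <- size_factors(Kz), "library-size")
  expect_equal(unname(sfz[1] / sfz[2]), 5 / 3, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  for (s in 1:5) {
    withr::with_seed(s, p <- runif(50))
    expect_equal(bh_adjust(p), oracle_bh(p))
    # order invariance
    perm <- withr::with_seed(s, sample(50))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("NB Wald test behaves on degenerate and null inputs", {
  # identical groups -> zero fold change everywhere
  withr::with_seed(1, K <- matrix(rpois(60, 30), 10, 6))
  rownames(K) <- paste0("g", 1:10); colnames(K) <- paste0("s", 1:6)
  res <- nb_wald_test(cbind(K, K), rep(c("A", "B"), each = 6))
  expect_true(all(res$log2_fold_change == 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # label swap flips the fold-change sign exactly
  sc <- make_nb_counts(50, 10, n_de = 5, lfc = 2, seed = 3)
  r1 <- nb_wald_test(sc$counts, sc$group_labels)
  r2 <- nb_wald_test(sc$counts, factor(sc$group_labels,
                                       levels = c("B", "A")))
  expect_equal(r2$log2_fold_change, -r1$log2_fold_change)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)

  # all-zero gene in both groups -> p = 1
  Kz <- rbind(K, zero = 0L)
  rz <- nb_wald_test(cbind(Kz, Kz), rep(c("A", "B"), each = 6))
  expect_equal(rz$p_value[rz$gene_id == "zero"], 1)

  expect_error(nb_wald_test(K, rep("A", 6)), "two groups")
  expect_error(nb_wald_test(K, c("A", rep("B", 5))), "at least 2")
})

test_that("null p-values are approximately uniform", {
  scn <- make_nb_counts(2000, 40, n_de = 0, seed = 11)
  p <- nb_wald_test(scn)$p_value
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("DE selection applies strict thresholds on both criteria", {
  res <- data.frame(
    gene_id = paste0("g", 1:6),
    base_mean = 100,
    log2_fold_change = c(3, -3, 2.5, 1.9, 4, -2.1),
    p_value = c(1e-5, 1e-5, 1e-5, 1e-5, 0.01, 1e-5),
    p_adjust = c(1e-4, 1e-4, 0.01, 1e-4, 0.02, 0.009),
    stringsAsFactors = FALSE
  )
  # g3 excluded: p_adjust = 0.01 is not < 0.01; g4 excluded: |lfc| <= 2
  expect_equal(select_de_genes(res), c("g1", "g2", "g6"))
  # one-sided variant keeps only up-regulated genes
  expect_equal(select_de_genes(res, two_sided = FALSE), "g1")
  expect_equal(select_de_genes(res[0, ]), character(0))
})

test_that("top-k ranking uses p_adjust with |lfc| then gene id as tie-breaks", {
  res <- data.frame(
    gene_id = c("b", "a", "c", "d"),
    base_mean = 1,
    log2_fold_change = c(1, -2, 2, 5),
    p_value = c(0.001, 0.001, 0.001, 0.05),
    p_adjust = c(0.01, 0.01, 0.01, 0.05),
    stringsAsFactors = FALSE
  )
  # ties on p_adjust: larger |lfc| first ('c' and 'a' tie at 2 -> lexicographic)
  expect_equal(top_k_genes(res, 3), c("a", "c", "b"))
  expect_equal(top_k_genes(res, 10), c("a", "c", "b", "d"))  # k > table

  withr::with_seed(5, big <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    base_mean = 1,
    log2_fold_change = rnorm(200),
    p_value = runif(200),
    p_adjust = round(runif(200), 2),  # force ties
    stringsAsFactors = FALSE
  ))
  ord <- with(big, order(p_adjust, -abs(log2_fold_change), gene_id))
  expect_equal(top_k_genes(big, 100), big$gene_id[ord][1:100])
})

test_that("planted fold changes are recovered with calibrated error control", {
  scn <- make_nb_counts(2000, 40, n_de = 100, lfc = 3, seed = 21)
  res <- nb_wald_test(scn)
  sel <- select_de_genes(res)
  planted <- res$gene_id[scn$de_genes]
  expect_gte(mean(planted %in% sel), 0.9)
  expect_lte(mean(setdiff(res$gene_id, planted) %in% sel), 0.01)
  # estimated lfc concentrates around the planted value
  expect_lt(abs(median(res$log2_fold_change[scn$de_genes]) - 3), 0.2)
})
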