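#' Construct a pair of precision matrices with known differential edges
#'
#' Builds two p x p precision matrices that differ on a known sparse set of
#' off-diagonal entries, so the true differential network is available in
#' closed form. `theta_X` gets `n_common_edges` random off-diagonal entries
#' of +/- `magnitude`; `theta_Y` adds perturbations of +/- `magnitude` at
#' `n_diff_edges` further pairs, drawn disjoint from the common ones so the
#' differential support has exactly the requested size. Both matrices are
#' then made positive definite by adding `c * I` with
#' `c = |smallest eigenvalue across both| + 0.1` — the *same* shift for
#' both, so the off-diagonal difference `delta_true = theta_Y - theta_X` is
#' untouched by the conditioning.
#'
#' @param p number of genes (>= 3).
#' @param n_common_edges edges shared by the two conditions.
#' @param n_diff_edges edges present only in condition Y (the differential
#'   edges); `n_common_edges + n_diff_edges <= p (p - 1) / 2`.
#' @param magnitude absolute value of the planted entries (> 0).
#' @param seed integer seed; the construction is a pure function of its
#'   arguments.
#' @return A list of class `diff_scenario`: `p`, `n_X`, `n_Y` (both `NA`
#'   until expression is drawn), `theta_X`, `theta_Y`, `delta_true`,
#'   `diff_edges` (two-column i < j matrix), `gene_ids`, `seed`.
#' @export
make_precision_pair <- function(p, n_common_edges, n_diff_edges,
                                magnitude = 0.3, seed = 1L) {
  if (p < 3L) stop("p must be at least 3")
  n_pairs <- p * (p - 1L) / 2L
  if (n_common_edges < 0L || n_diff_edges < 0L ||
      n_common_edges + n_diff_edges > n_pairs)
    stop("edge counts must be nonnegative and sum to at most p(p-1)/2")
  if (magnitude <= 0) stop("magnitude must be positive")

  withr::with_seed(seed, {
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    pick <- sample.int(nrow(pairs), n_common_edges + n_diff_edges)
    common <- pairs[pick[seq_len(n_common_edges)], , drop = FALSE]
    diffp  <- pairs[pick[n_common_edges + seq_len(n_diff_edges)], , drop = FALSE]

    theta_X <- matrix(0, p, p)
    if (n_common_edges > 0L) {
      v <- magnitude * sample(c(-1, 1), n_common_edges, replace = TRUE)
      theta_X[common] <- v
      theta_X[common[, c(2, 1), drop = FALSE]] <- v
    }
    theta_Y <- theta_X
    if (n_diff_edges > 0L) {
      v <- magnitude * sample(c(-1, 1), n_diff_edges, replace = TRUE)
      theta_Y[diffp] <- theta_Y[diffp] + v
      theta_Y[diffp[, c(2, 1), drop = FALSE]] <-
        theta_Y[diffp[, c(2, 1), drop = FALSE]] + v
    }
  })

  ev_min <- min(eigen(theta_X, symmetric = TRUE, only.values = TRUE)$values,
                eigen(theta_Y, symmetric = TRUE, only.values = TRUE)$values)
  shift <- abs(min(ev_min, 0)) + 0.1
  diag(theta_X) <- diag(theta_X) + shift
  diag(theta_Y) <- diag(theta_Y) + shift

  for (th in list(theta_X, theta_Y)) {
    if (min(eigen(th, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("internal error: conditioned precision matrix is not positive definite")
  }

  gene_ids <- paste0("g", formatC(seq_len(p), width = nchar(p), flag = "0"))
  dimnames(theta_X) <- dimnames(theta_Y) <- list(gene_ids, gene_ids)
  delta_true <- theta_Y - theta_X
  de <- diffp[order(diffp[, 1], diffp[, 2]), , drop = FALSE]
  dimnames(de) <- list(NULL, c("i", "j"))
  structure(
    list(p = p, n_X = NA_integer_, n_Y = NA_integer_,
         theta_X = theta_X, theta_Y = theta_Y, delta_true = delta_true,
         diff_edges = de, gene_ids = gene_ids, seed = seed),
    class = "diff_scenario"
  )
}

#' Draw expression samples from a zero-mean Gaussian with given precision
#'
#' Samples `n` columns from `N(0, theta^{-1})` using the Cholesky factor of
#' `theta`, giving a genes-by-samples matrix — the layout the rest of the
#' pipeline expects.
#'
#' @param theta symmetric positive-definite precision matrix.
#' @param n number of samples (>= 2).
#' @param seed integer seed.
#' @return A p x n numeric matrix; rownames from `theta` (or g1..gp),
#'   colnames s1..sn.
#' @export
sample_expression <- function(theta, n, seed = 1L) {
  theta <- as.matrix(theta)
  p <- nrow(theta)
  if (ncol(theta) != p || max(abs(theta - t(theta))) > 1e-8)
    stop("theta must be a symmetric square matrix")
  if (n < 2L) stop("n must be at least 2")
  R <- tryCatch(chol((theta + t(theta)) / 2),
                error = function(e) stop("theta is not positive definite: ",
                                         conditionMessage(e)))
  Z <- withr::with_seed(seed, matrix(stats::rnorm(p * n), p, n))
  X <- backsolve(R, Z)  # R^{-1} Z ~ N(0, theta^{-1})
  rn <- rownames(theta)
  if (is.null(rn)) rn <- paste0("g", seq_len(p))
  dimnames(X) <- list(rn, paste0("s", seq_len(n)))
  X
}

#' Synthetic prior regulatory network for a differential scenario
#'
#' Emulates a curated static regulatory network: a `coverage` fraction of
#' the scenario's true differential edges, plus `noise_edges` random pairs
#' that are *not* differential. The result can be written in TRRUST-style
#' format with [write_trrust()] and fed back through [read_trrust()].
#'
#' @param scenario a [make_precision_pair()] result.
#' @param coverage fraction in \[0, 1\] of true differential edges included.
#' @param noise_edges number of non-differential pairs added.
#' @param seed integer seed.
#' @return A `prior_network` (see [prior_network()]).
#' @export
make_prior_network <- function(scenario, coverage = 1, noise_edges = 0L,
                               seed = 1L) {
  stopifnot(inherits(scenario, "diff_scenario"))
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  p <- scenario$p
  de <- scenario$diff_edges
  n_keep <- round(coverage * nrow(de))
  withr::with_seed(seed, {
    keep <- if (n_keep > 0L) sort(sample.int(nrow(de), n_keep)) else integer(0)
    kept <- de[keep, , drop = FALSE]
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    is_diff <- paste(pairs[, 1], pairs[, 2]) %in% paste(de[, 1], de[, 2])
    candidates <- pairs[!is_diff, , drop = FALSE]
    if (noise_edges > nrow(candidates))
      stop("not enough non-differential pairs for the requested noise edges")
    noise <- candidates[sample.int(nrow(candidates), noise_edges), , drop = FALSE]
  })
  ids <- scenario$gene_ids
  edges <- rbind(
    data.frame(a = ids[kept[, 1]], b = ids[kept[, 2]],
               stringsAsFactors = FALSE),
    data.frame(a = ids[noise[, 1]], b = ids[noise[, 2]],
               stringsAsFactors = FALSE)
  )
  prior_network(edges, source = "synthetic")
}

#' Negative-binomial count scenario with planted fold changes
#'
#' Generates a genes-by-samples count matrix for two groups. Every gene has
#' mean `base_mean` in group 1; the first `n_de` genes have mean
#' `base_mean * 2^lfc` in group 2. Counts are negative binomial with the
#' mean/dispersion parameterization `variance = mu + dispersion * mu^2`;
#' dispersions below 1e-8 are treated as the Poisson limit.
#'
#' @param n_genes,n_per_group matrix dimensions (>= 1 sample per group).
#' @param n_de number of genes with a planted fold change.
#' @param lfc planted log2 fold change (group 2 vs group 1).
#' @param dispersion per-gene NB dispersion (> 0; scalar recycled).
#' @param base_mean group-1 mean count.
#' @param seed integer seed.
#' @return A list of class `count_scenario`: `counts` (integer matrix),
#'   `group_labels` (factor of "A"/"B"), `de_genes` (integer indices),
#'   `true_lfc`, `dispersion`, `seed`.
#' @export
make_nb_counts <- function(n_genes, n_per_group, n_de = 0L, lfc = 0,
                           dispersion = 0.1, base_mean = 100, seed = 1L) {
  if (n_per_group < 1L) stop("need at least 1 sample per group")
  if (n_de > n_genes) stop("n_de cannot exceed n_genes")
  if (any(dispersion < 0)) stop("dispersion must be nonnegative")
  alpha <- rep_len(dispersion, n_genes)
  true_lfc <- numeric(n_genes)
  de_genes <- seq_len(n_de)
  true_lfc[de_genes] <- lfc
  mu1 <- rep(base_mean, n_genes)
  mu2 <- base_mean * 2^true_lfc

  draw <- function(mu, alpha, n) {
    # one gene, n draws; Poisson limit below the dispersion floor
    if (alpha < 1e-8) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
  }
  counts <- withr::with_seed(seed, {
    t(vapply(seq_len(n_genes), function(g) {
      c(draw(mu1[g], alpha[g], n_per_group), draw(mu2[g], alpha[g], n_per_group))
    }, numeric(2L * n_per_group)))
  })
  storage.mode(counts) <- "integer"
  rownames(counts) <- paste0("g", formatC(seq_len(n_genes),
                                          width = nchar(n_genes), flag = "0"))
  colnames(counts) <- paste0(rep(c("A", "B"), each = n_per_group),
                             seq_len(n_per_group))
  structure(
    list(counts = counts,
         group_labels = factor(rep(c("A", "B"), each = n_per_group)),
         de_genes = de_genes, true_lfc = true_lfc,
         dispersion = alpha, seed = seed),
    class = "count_scenario"
  )
}

#' Toy gene-set collection for a scenario
#'
#' Builds a handful of gene sets over the scenario's genes: one set holding
#' every gene incident to a true differential edge (the "signal" set) and
#' `n_random` random sets of size `set_size`. Useful for exercising the
#' enrichment stage with a known answer.
#'
#' @param scenario a [make_precision_pair()] result.
#' @param n_random number of random sets.
#' @param set_size size of each random set.
#' @param seed integer seed.
#' @return Named list of character vectors (gene sets).
#' @export
make_gene_sets <- function(scenario, n_random = 5L, set_size = 10L, seed = 1L) {
  stopifnot(inherits(scenario, "diff_scenario"))
  ids <- scenario$gene_ids
  set_size <- min(set_size, length(ids))
  signal <- sort(unique(ids[as.vector(scenario$diff_edges)]))
  sets <- withr::with_seed(seed, {
    rs <- lapply(seq_len(n_random), function(i) sort(sample(ids, set_size)))
    names(rs) <- paste0("random_set_", seq_len(n_random))
    rs
  })
  c(if (length(signal)) list(diff_edge_genes = signal), sets)
}
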