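# Independent oracles and small fixture builders shared across the suite.
# Every oracle here is written against the mathematical definition, not
# against the package's code path.

# random well-conditioned covariance pair built from Gaussian draws
random_cov_pair <- function(p, n = 50, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(p * n), p, n)
    Y <- matrix(rnorm(p * n), p, n)
  })
  cov_pair(X, Y)
}

# D-trace loss evaluated literally, trace by trace, with <A,B> = tr(A B^T)
oracle_dtrace_loss <- function(delta, cov) {
  tr <- function(M) sum(diag(M))
  ip <- function(A, B) tr(A %*% t(B))
  sX <- cov$sigma_X; sY <- cov$sigma_Y
  0.25 * (ip(sX %*% delta, delta %*% sY) + ip(sY %*% delta, delta %*% sX)) -
    ip(delta, sX - sY)
}

# central finite differences of a scalar matrix function
fd_gradient <- function(f, delta, h = 1e-5) {
  G <- matrix(0, nrow(delta), ncol(delta))
  for (i in seq_len(nrow(delta))) for (j in seq_len(ncol(delta))) {
    dp <- delta; dp[i, j] <- dp[i, j] + h
    dm <- delta; dm[i, j] <- dm[i, j] - h
    G[i, j] <- (f(dp) - f(dm)) / (2 * h)
  }
  G
}

# general-purpose convex solver for the penalized D-trace problem:
# split delta = u - v (u, v >= 0) and minimize the smooth objective
# loss(u - v) + lam * sum(Wpen * (u + v)) by box-constrained L-BFGS-B.
oracle_convex_solve <- function(cov, W, lam, penalize_diagonal = TRUE) {
  p <- nrow(cov$sigma_X)
  Wm <- if (is.null(W)) matrix(1, p, p) else if (inherits(W, "weight_matrix")) W$W else W
  Wpen <- Wm
  if (!penalize_diagonal) diag(Wpen) <- 0
  sX <- cov$sigma_X; sY <- cov$sigma_Y
  fn <- function(par) {
    u <- matrix(par[1:(p * p)], p, p)
    v <- matrix(par[-(1:(p * p))], p, p)
    d <- u - v
    t1 <- sum((sX %*% d) * t(sY %*% t(d)))
    t2 <- sum((sY %*% d) * t(sX %*% t(d)))
    0.25 * (t1 + t2) - sum(d * (sX - sY)) + lam * sum(Wpen * (u + v))
  }
  gr <- function(par) {
    u <- matrix(par[1:(p * p)], p, p)
    v <- matrix(par[-(1:(p * p))], p, p)
    d <- u - v
    g <- 0.5 * (sX %*% d %*% sY + sY %*% d %*% sX) - (sX - sY)
    c(as.vector(g + lam * Wpen), as.vector(-g + lam * Wpen))
  }
  fit <- stats::optim(rep(0, 2 * p * p), fn, gr, method = "L-BFGS-B",
                      lower = 0,
                      control = list(maxit = 20000, factr = 10, pgtol = 1e-12))
  u <- matrix(fit$par[1:(p * p)], p, p)
  v <- matrix(fit$par[-(1:(p * p))], p, p)
  list(delta = u - v, value = fit$value)
}

# hypergeometric tail by exact binomial-coefficient ratios (choose() is
# exact in double precision at these sizes)
oracle_hyper_ratio <- function(N, M, n, m) {
  if (m == 0) return(1)
  i <- m:min(M, n)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# hypergeometric tail by full enumeration of all size-n subsets
oracle_hyper_enum <- function(N, M, n, m) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= M)  # first M elements are "in the set"
  mean(hits >= m)
}

# Benjamini-Hochberg step-up written from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# precision/recall/F1 of an estimated support against true i<j edge pairs
edge_f1 <- function(support, true_edges) {
  tk <- paste(true_edges[, 1], true_edges[, 2])
  ek <- paste(support[, 1], support[, 2])
  tp <- length(intersect(ek, tk))
  prec <- if (length(ek)) tp / length(ek) else 0
  rec <- if (length(tk)) tp / length(tk) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, tp = tp)
}
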