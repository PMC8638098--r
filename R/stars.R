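# StARS (Stability Approach to Regularization Selection) for the weighted
# D-trace differential network: fit the network on subsample pairs over a
# decreasing lambda grid, measure per-edge selection instability, and pick
# the least regularization whose (monotonized) instability stays below the
# threshold beta.

#' Paired subsample indices for the two conditions
#'
#' Draws `S` subsamples without replacement, independently for each
#' condition (their sample counts generally differ); subsample `k` of X is
#' paired with subsample `k` of Y for one differential fit.
#'
#' @param n_X,n_Y sample counts per condition.
#' @param b_X,b_Y subsample sizes (each < its n).
#' @param S number of subsample pairs (>= 2).
#' @param seed integer seed.
#' @return List of `S` lists, each with integer vectors `ix` and `iy`.
#' @export
subsample_pair <- function(n_X, n_Y, b_X, b_Y, S = 20L, seed = 1L) {
  if (S < 2L) stop("S must be at least 2")
  if (b_X >= n_X || b_Y >= n_Y || b_X < 1L || b_Y < 1L)
    stop("subsample sizes must satisfy 1 <= b < n for each condition")
  withr::with_seed(seed, {
    lapply(seq_len(S), function(k) {
      list(ix = sort(sample.int(n_X, b_X)), iy = sort(sample.int(n_Y, b_Y)))
    })
  })
}

#' Subsample size rule
#'
#' `b = floor(10 * sqrt(n))` capped at `n - 1`, the recommendation of the
#' original stability-selection work for graphs.
#'
#' @param n sample count.
#' @return Integer subsample size.
#' @export
stars_subsample_size <- function(n) {
  max(1L, min(n - 1L, as.integer(floor(10 * sqrt(n)))))
}

#' Default log-spaced lambda grid
#'
#' `n_lambda` points from `lambda_max` down to `ratio_min * lambda_max`
#' (strictly decreasing).
#'
#' @param lam_max upper grid endpoint (typically [lambda_max()]).
#' @param n_lambda grid size.
#' @param ratio_min lower endpoint as a fraction of `lam_max`.
#' @return Decreasing numeric vector.
#' @export
stars_lambda_grid <- function(lam_max, n_lambda = 20L, ratio_min = 0.01) {
  if (lam_max <= 0) stop("lam_max must be positive to build a grid")
  exp(seq(log(lam_max), log(ratio_min * lam_max), length.out = n_lambda))
}

#' Select the penalty level by StARS stability selection
#'
#' For every lambda in the (decreasing) grid and every subsample pair, the
#' differential network is fit and each off-diagonal pair's selection
#' frequency `xi` across subsamples is recorded. The per-edge instability is
#' `2 * xi * (1 - xi)` and the total instability is its mean over all
#' off-diagonal pairs. The instability curve is monotonized from the
#' most-penalized end (running maximum as lambda decreases), and the
#' *smallest* lambda whose monotonized instability is at most `beta` is
#' selected — the densest graph still deemed stable. If every lambda is
#' stable the grid's smallest lambda is returned; if none is, the largest,
#' with a warning. Subsample fits that fail to converge are excluded with a
#' warning; selection proceeds at a lambda while at least half the fits
#' remain.
#'
#' Fits are warm-started along the lambda path (per subsample) to keep the
#' total work modest.
#'
#' @param X,Y genes-by-samples expression matrices for the two conditions.
#' @param W weight matrix or `NULL`.
#' @param beta instability threshold (default 0.005).
#' @param S number of subsample pairs (default 20).
#' @param lambda_grid decreasing positive grid; by default 20 log-spaced
#'   points from [lambda_max()] of the full-data covariances down to 1% of
#'   it.
#' @param seed integer seed for the subsampling.
#' @param center passed to [cov_pair()].
#' @param penalize_diagonal,max_iter,tol passed to [solve_wdtrace()].
#' @return List of class `stars_result`: `lambda_selected`, `lambda_grid`,
#'   `instability` (raw), `instability_monotone`, `edge_frequency` (list of
#'   p x p matrices, one per lambda), `network` (the full-data fit at the
#'   selected lambda), `n_fits_used` per lambda.
#' @export
stars_select <- function(X, Y, W = NULL, beta = 0.005, S = 20L,
                         lambda_grid = NULL, seed = 1L, center = TRUE,
                         penalize_diagonal = TRUE, max_iter = 2000L,
                         tol = 1e-6) {
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  X <- as.matrix(X); Y <- as.matrix(Y)
  cov_full <- cov_pair(X, Y, center = center)
  p <- nrow(X)
  if (is.null(lambda_grid)) {
    lm <- lambda_max(cov_full, W, penalize_diagonal = penalize_diagonal)
    if (lm <= 0) lm <- 1e-8  # degenerate: identical covariances
    lambda_grid <- stars_lambda_grid(lm)
  }
  if (length(lambda_grid) == 0L) stop("empty lambda grid")
  if (any(diff(lambda_grid) >= 0)) stop("lambda grid must be strictly decreasing")

  n_X <- ncol(X); n_Y <- ncol(Y)
  subs <- subsample_pair(n_X, n_Y,
                         stars_subsample_size(n_X), stars_subsample_size(n_Y),
                         S = S, seed = seed)
  covs <- lapply(subs, function(s)
    cov_pair(X[, s$ix, drop = FALSE], Y[, s$iy, drop = FALSE], center = center))

  nl <- length(lambda_grid)
  off <- upper.tri(diag(p))
  n_pairs <- sum(off)
  instab <- numeric(nl)
  edge_freq <- vector("list", nl)
  n_used <- integer(nl)
  warm <- vector("list", S)
  n_failed <- 0L

  for (li in seq_len(nl)) {
    lam <- lambda_grid[li]
    sel <- matrix(0, p, p)
    used <- 0L
    for (k in seq_len(S)) {
      fit <- solve_wdtrace(covs[[k]], W, lam, delta0 = warm[[k]],
                           max_iter = max_iter, tol = tol,
                           penalize_diagonal = penalize_diagonal)
      if (!fit$trace$converged) {
        n_failed <- n_failed + 1L
        next
      }
      warm[[k]] <- fit$network$delta
      sel <- sel + (fit$network$delta != 0)
      used <- used + 1L
    }
    n_used[li] <- used
    if (used < ceiling(S / 2)) {
      stop("stars_select: fewer than half the subsample fits converged at ",
           "lambda = ", signif(lam, 4))
    }
    xi <- sel / used
    edge_freq[[li]] <- xi
    instab[li] <- sum((2 * xi * (1 - xi))[off]) / n_pairs
  }
  if (n_failed > 0L)
    warning("stars_select: ", n_failed,
            " subsample fit(s) did not converge and were excluded")

  mono <- cummax(instab)  # grid is decreasing in lambda
  stable <- which(mono <= beta)
  if (length(stable) == 0L) {
    warning("stars_select: no lambda on the grid is stable at beta = ", beta,
            "; returning the most penalized")
    sel_idx <- 1L
  } else {
    sel_idx <- max(stable)  # smallest stable lambda = densest stable graph
  }
  lambda_sel <- lambda_grid[sel_idx]
  final <- solve_wdtrace(cov_full, W, lambda_sel, max_iter = max(max_iter, 5000L),
                         tol = tol, penalize_diagonal = penalize_diagonal)

  structure(
    list(lambda_selected = lambda_sel, lambda_grid = lambda_grid,
         instability = instab, instability_monotone = mono,
         edge_frequency = edge_freq, network = final$network,
         converged = final$trace$converged, n_fits_used = n_used,
         beta = beta, S = S, seed = seed),
    class = "stars_result"
  )
}

#' @export
print.stars_result <- function(x, ...) {
  cat("StARS selection: lambda = ", signif(x$lambda_selected, 4),
      " (beta = ", x$beta, ", S = ", x$S, "); ",
      nrow(x$network$support), " edges selected\n", sep = "")
  invisible(x)
}
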