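#' Sample covariance of an expression matrix
#'
#' Computes the scaled cross-product `(1/n) X X^T` in gene space, where `X`
#' is a genes-by-samples matrix. By default each gene is mean-centered
#' across samples first; real expression data are not zero-mean, while the
#' Gaussian differential-network model assumes it. Set `center = FALSE` to
#' obtain the literal uncentered second-moment matrix.
#'
#' @param X numeric matrix, genes in rows, samples in columns (n >= 2).
#' @param center logical; subtract each gene's mean across samples first.
#' @return A p x p exactly-symmetric positive semidefinite matrix with
#'   `dimnames` taken from the rownames of `X`.
#' @export
sample_covariance <- function(X, center = TRUE) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix")
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 samples to estimate a covariance")
  if (center) X <- X - rowMeans(X)
  S <- tcrossprod(X) / n
  S <- (S + t(S)) / 2  # exact symmetry despite float noise
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

#' Pair of sample covariance matrices for two conditions
#'
#' Bundles the two p x p covariance estimates with their provenance. The
#' matrices are symmetrized on construction and checked for approximate
#' positive semidefiniteness.
#'
#' @param X,Y genes-by-samples expression matrices for the two conditions,
#'   with the same genes in the same order.
#' @param center logical, passed to [sample_covariance()].
#' @return An object of class `cov_pair` with elements `sigma_X`, `sigma_Y`,
#'   `n_X`, `n_Y`, `gene_ids`, `centered`.
#' @export
cov_pair <- function(X, Y, center = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same genes (rows)")
  gene_ids <- rownames(X)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(X)))
  if (!is.null(rownames(Y)) && !identical(rownames(X), rownames(Y)))
    stop("X and Y gene identifiers disagree")
  sX <- sample_covariance(X, center = center)
  sY <- sample_covariance(Y, center = center)
  for (S in list(sX, sY)) {
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-10)
      stop("covariance estimate is not positive semidefinite (min eigenvalue ",
           format(ev_min), ")")
  }
  structure(
    list(sigma_X = sX, sigma_Y = sY, n_X = ncol(X), n_Y = ncol(Y),
         gene_ids = gene_ids, centered = center),
    class = "cov_pair"
  )
}

#' @export
print.cov_pair <- function(x, ...) {
  cat("Covariance pair: ", length(x$gene_ids), " genes; n_X = ", x$n_X,
      ", n_Y = ", x$n_Y, if (x$centered) "; centered" else "; uncentered",
      "\n", sep = "")
  invisible(x)
}

as_cov_pair <- function(cov) {
  if (inherits(cov, "cov_pair")) return(cov)
  if (is.list(cov) && all(c("sigma_X", "sigma_Y") %in% names(cov))) return(cov)
  stop("expected a cov_pair (see cov_pair())")
}

check_conformable <- function(delta, cov) {
  p <- nrow(cov$sigma_X)
  if (!is.matrix(delta) || nrow(delta) != p || ncol(delta) != p)
    stop("delta must be a ", p, " x ", p, " matrix to conform with the covariances")
}

#' D-trace loss
#'
#' The convex quadratic loss
#' \deqn{L_D(\Delta) = \frac14\left(\langle \hat\Sigma_X\Delta, \Delta\hat\Sigma_Y\rangle
#'   + \langle \hat\Sigma_Y\Delta, \Delta\hat\Sigma_X\rangle\right)
#'   - \langle \Delta, \hat\Sigma_X - \hat\Sigma_Y \rangle}
#' with \eqn{\langle A,B\rangle = \mathrm{tr}(AB^T)}. Its unpenalized
#' minimizer (when both covariances are invertible) is
#' \eqn{\hat\Sigma_Y^{-1} - \hat\Sigma_X^{-1}}, the difference of precision
#' matrices, so minimizing it estimates the differential network directly
#' without estimating either precision matrix on its own.
#'
#' @param delta p x p matrix (the candidate precision difference).
#' @param cov a [cov_pair()].
#' @return The loss value (scalar).
#' @export
dtrace_loss <- function(delta, cov) {
  cov <- as_cov_pair(cov)
  check_conformable(delta, cov)
  sX <- cov$sigma_X; sY <- cov$sigma_Y
  # <sX delta, delta sY> = tr(sX delta sY t(delta)); trace via elementwise sums
  t1 <- sum((sX %*% delta) * t(sY %*% t(delta)))
  t2 <- sum((sY %*% delta) * t(sX %*% t(delta)))
  0.25 * (t1 + t2) - sum(delta * (sX - sY))
}

#' Gradient of the D-trace loss
#'
#' \deqn{\nabla L_D(\Delta) = \frac12(\hat\Sigma_X \Delta \hat\Sigma_Y +
#'   \hat\Sigma_Y \Delta \hat\Sigma_X) - (\hat\Sigma_X - \hat\Sigma_Y)}
#' Symmetric whenever `delta` is symmetric.
#'
#' @inheritParams dtrace_loss
#' @return A p x p matrix.
#' @export
dtrace_gradient <- function(delta, cov) {
  cov <- as_cov_pair(cov)
  check_conformable(delta, cov)
  sX <- cov$sigma_X; sY <- cov$sigma_Y
  0.5 * (sX %*% delta %*% sY + sY %*% delta %*% sX) - (sX - sY)
}

#' Weighted elementwise soft-thresholding
#'
#' The proximal operator of the weighted lasso penalty
#' \eqn{\lambda \sum_{ij} W_{ij} |\Delta_{ij}|}: each entry becomes
#' `sign(A) * max(|A| - lam * W, 0)`. This is what keeps iterates of the
#' penalized D-trace solver sparse. When `penalize_diagonal` is `FALSE` the
#' diagonal is returned untouched.
#'
#' @param A numeric matrix.
#' @param lam nonnegative threshold scale.
#' @param W weight matrix conformable with `A`, entries in (0, 1]; `NULL`
#'   means all ones.
#' @param penalize_diagonal logical; threshold the diagonal too (default).
#' @return Matrix of the same shape as `A`.
#' @export
weighted_soft_threshold <- function(A, lam, W = NULL, penalize_diagonal = TRUE) {
  if (lam < 0) stop("lam must be nonnegative")
  A <- as.matrix(A)
  if (is.null(W)) W <- matrix(1, nrow(A), ncol(A))
  W <- weight_entries(W)
  if (!all(dim(W) == dim(A))) stop("W must conform with A")
  out <- sign(A) * pmax(abs(A) - lam * W, 0)
  if (!penalize_diagonal) diag(out) <- diag(A)
  out
}

# Accept either a plain matrix or a weight_matrix object (prior-weights module).
weight_entries <- function(W) {
  if (inherits(W, "weight_matrix")) W$W else as.matrix(W)
}

#' Differential network object
#'
#' Wraps an estimated (symmetric, typically sparse) precision-difference
#' matrix with its gene identifiers and the penalty level that produced it.
#' Edges are the exactly-nonzero off-diagonal entries: the proximal operator
#' produces exact zeros, so no magnitude re-thresholding is applied.
#'
#' @param delta p x p symmetric numeric matrix.
#' @param gene_ids character vector of length p (defaults to delta's
#'   rownames, then g1..gp).
#' @param lambda_used penalty at which delta was estimated (NA if unknown).
#' @return An object of class `diff_network` with fields `delta`, `gene_ids`,
#'   `lambda_used`, and `support` (two-column matrix of i < j index pairs).
#' @export
diff_network <- function(delta, gene_ids = NULL, lambda_used = NA_real_) {
  delta <- as.matrix(delta)
  p <- nrow(delta)
  if (ncol(delta) != p) stop("delta must be square")
  if (max(abs(delta - t(delta))) > 1e-8)
    stop("delta must be symmetric")
  delta <- (delta + t(delta)) / 2  # exact symmetry after the averaging
  # the prox yields exact zeros; after the averaging (and its rounding) a
  # 1e-8 tolerance decides what still counts as zero
  delta[abs(delta) < 1e-8] <- 0
  if (is.null(gene_ids)) gene_ids <- rownames(delta)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  dimnames(delta) <- list(gene_ids, gene_ids)
  idx <- which(delta != 0 & upper.tri(delta), arr.ind = TRUE)
  support <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(support) <- list(NULL, c("i", "j"))
  structure(list(delta = delta, gene_ids = gene_ids,
                 lambda_used = lambda_used, support = support),
            class = "diff_network")
}

#' @export
print.diff_network <- function(x, ...) {
  cat("Differential network: ", length(x$gene_ids), " genes, ",
      nrow(x$support), " edges",
      if (!is.na(x$lambda_used)) paste0(" (lambda = ", signif(x$lambda_used, 4), ")"),
      "\n", sep = "")
  invisible(x)
}
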