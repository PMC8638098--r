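#' Penalized D-trace objective
#'
#' `dtrace_loss(delta) + lam * sum(W_ij * |delta_ij|)` over the penalized
#' entries (all entries by default; off-diagonal only when
#' `penalize_diagonal = FALSE`).
#'
#' @inheritParams dtrace_loss
#' @param W weight matrix (entries in (0, 1]) or `NULL` for all ones.
#' @param lam nonnegative penalty level.
#' @param penalize_diagonal logical; include the diagonal in the penalty.
#' @return Scalar objective value.
#' @export
wdtrace_objective <- function(delta, cov, W = NULL, lam = 0,
                              penalize_diagonal = TRUE) {
  if (lam < 0) stop("lam must be nonnegative")
  Wm <- if (is.null(W)) matrix(1, nrow(delta), ncol(delta)) else weight_entries(W)
  pen <- Wm * abs(delta)
  if (!penalize_diagonal) diag(pen) <- 0
  dtrace_loss(delta, cov) + lam * sum(pen)
}

#' Smallest penalty that zeroes the solution
#'
#' The gradient of the D-trace loss at `delta = 0` is
#' `-(sigma_X - sigma_Y)`, so zero is optimal exactly when every penalized
#' entry satisfies `|sigma_X - sigma_Y|_ij <= lam * W_ij`. The returned
#' value is the max of `|sigma_X - sigma_Y|_ij / W_ij` over penalized
#' entries; it is the natural upper endpoint for a regularization grid.
#'
#' @inheritParams wdtrace_objective
#' @return Scalar; 0 when the two covariances coincide on penalized entries.
#' @export
lambda_max <- function(cov, W = NULL, penalize_diagonal = TRUE) {
  cov <- as_cov_pair(cov)
  D <- abs(cov$sigma_X - cov$sigma_Y)
  Wm <- if (is.null(W)) matrix(1, nrow(D), ncol(D)) else weight_entries(W)
  R <- D / Wm
  if (!penalize_diagonal) {
    diag(R) <- 0
    diag(D) <- 0
  }
  lm <- max(R)
  # rounding guard: (D/W)*W can land one ulp short of D, which would leave
  # the argmax entry marginally uncovered by the subgradient at lm itself
  while (lm > 0 && any(D > lm * Wm)) lm <- lm * (1 + .Machine$double.eps)
  lm
}

#' Fit the weighted D-trace differential network at one penalty level
#'
#' Minimizes the weighted-lasso-penalized D-trace objective by FISTA
#' (accelerated proximal gradient descent): gradient step on the smooth
#' loss at an extrapolated point, weighted soft-threshold step on the
#' penalty, Nesterov momentum `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2`, and a
#' function-value restart that drops the momentum whenever the objective
#' would increase, which keeps the objective sequence non-increasing.
#' Iterates are symmetrized (averaged with their transpose) before each
#' prox so the estimate stays exactly symmetric.
#'
#' The default step size is `1 / L` with
#' `L = ||sigma_X||_2 * ||sigma_Y||_2`, an upper bound on the Lipschitz
#' constant of the gradient (the Hessian is the symmetrized Kronecker
#' product of the two covariances).
#'
#' @param cov a [cov_pair()].
#' @param W weight matrix (see [build_weight_matrix()]) or `NULL`.
#' @param lam nonnegative penalty level.
#' @param delta0 optional warm-start matrix (defaults to zero).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the relative objective change.
#' @param penalize_diagonal logical; penalize diagonal entries too (default
#'   `TRUE`, matching the full-penalty model).
#' @param restart logical; enable the function-value restart.
#' @return A list with `network` (a [diff_network()]) and `trace` (list with
#'   `objective_per_iter`, `n_iter`, `converged`).
#' @export
solve_wdtrace <- function(cov, W = NULL, lam = 0, delta0 = NULL,
                          max_iter = 5000L, tol = 1e-6,
                          penalize_diagonal = TRUE, restart = TRUE) {
  cov <- as_cov_pair(cov)
  if (lam < 0) stop("lam must be nonnegative")
  sX <- cov$sigma_X; sY <- cov$sigma_Y
  p <- nrow(sX)
  Wm <- if (is.null(W)) matrix(1, p, p) else weight_entries(W)
  if (!all(dim(Wm) == c(p, p))) stop("W does not conform with the covariances")
  if (!all(Wm > 0 & Wm <= 1)) stop("weight entries must lie in (0, 1]")

  nrm2 <- function(S) {
    # spectral norm of a symmetric matrix
    max(abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  }
  L <- nrm2(sX) * nrm2(sY)
  if (!is.finite(L)) stop("non-finite covariance entries; cannot set a step size")
  if (L < .Machine$double.eps) L <- .Machine$double.eps  # both covariances ~ 0
  step <- 1 / L

  delta <- if (is.null(delta0)) matrix(0, p, p) else (as.matrix(delta0) + t(as.matrix(delta0))) / 2
  z <- delta        # extrapolated point
  tk <- 1
  f_prev <- wdtrace_objective(delta, cov, Wm, lam, penalize_diagonal)
  if (!is.finite(f_prev)) stop("objective is non-finite at the starting point")
  obj <- numeric(max_iter)
  converged <- FALSE
  n_iter <- 0L

  for (k in seq_len(max_iter)) {
    g <- 0.5 * (sX %*% z %*% sY + sY %*% z %*% sX) - (sX - sY)
    a <- z - step * g
    a <- (a + t(a)) / 2
    delta_new <- weighted_soft_threshold(a, lam * step, Wm, penalize_diagonal)
    f_new <- wdtrace_objective(delta_new, cov, Wm, lam, penalize_diagonal)
    if (!is.finite(f_new))
      stop("objective became non-finite during optimization; ",
           "check the scale of the covariance inputs")
    if (restart && f_new > f_prev) {
      # drop momentum: plain proximal step from the last accepted iterate
      tk <- 1
      g <- 0.5 * (sX %*% delta %*% sY + sY %*% delta %*% sX) - (sX - sY)
      a <- delta - step * g
      a <- (a + t(a)) / 2
      delta_new <- weighted_soft_threshold(a, lam * step, Wm, penalize_diagonal)
      f_new <- wdtrace_objective(delta_new, cov, Wm, lam, penalize_diagonal)
      if (f_new > f_prev) {  # fixed step is a majorizer: accept previous point
        delta_new <- delta
        f_new <- f_prev
      }
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- delta_new + ((tk - 1) / t_next) * (delta_new - delta)
    tk <- t_next
    obj[k] <- f_new
    n_iter <- k
    rel_change <- abs(f_prev - f_new) / max(1, abs(f_prev))
    delta <- delta_new
    f_prev <- f_new
    if (k > 1L && rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("solve_wdtrace: not converged after ", max_iter,
            " iterations (relative objective tolerance ", tol, ")")
  net <- diff_network(delta, gene_ids = cov$gene_ids, lambda_used = lam)
  list(network = net,
       trace = list(objective_per_iter = obj[seq_len(n_iter)],
                    n_iter = n_iter, converged = converged))
}
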