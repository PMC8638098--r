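# Simplified negative-binomial differential-expression stage: median-of-ratios
# size factors, per-gene method-of-moments dispersion, Wald test on the
# log-linked fold change, BH adjustment. Deliberately lighter than a full
# DESeq2-style analysis — no dispersion shrinkage, no outlier refitting, no
# independent filtering — so results on real data will differ from DESeq2's.

#' Filter non-expressed and low-expressed genes
#'
#' Keeps genes whose total count across all samples is at least `min_total`,
#' preserving gene order. Low-count genes carry almost no information for
#' the NB test and inflate the multiple-testing burden.
#'
#' @param counts integer matrix (genes x samples) or a `count_scenario`.
#' @param min_total minimum row sum (>= 0).
#' @return Same type as the input, with low-count genes removed (for a
#'   `count_scenario`, `de_genes`/`true_lfc`/`dispersion` are subset too).
#' @export
filter_low_expressed <- function(counts, min_total = 10L) {
  if (min_total < 0) stop("min_total must be nonnegative")
  is_scen <- inherits(counts, "count_scenario")
  K <- if (is_scen) counts$counts else as.matrix(counts)
  keep <- rowSums(K) >= min_total
  if (!any(keep)) stop("filter removed every gene (min_total = ", min_total, ")")
  if (!is_scen) return(K[keep, , drop = FALSE])
  idx <- which(keep)
  old_de <- counts$de_genes
  counts$counts <- K[idx, , drop = FALSE]
  counts$de_genes <- match(intersect(old_de, idx), idx)
  counts$true_lfc <- counts$true_lfc[idx]
  counts$dispersion <- counts$dispersion[idx]
  counts
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio between its count and
#' the gene's geometric mean across samples, using only genes with strictly
#' positive counts everywhere; factors are then rescaled to geometric mean
#' 1. If no gene is everywhere-positive, falls back to library-size
#' (total-count) normalization with a warning.
#'
#' @param counts integer matrix (genes x samples) or a `count_scenario`.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  K <- if (inherits(counts, "count_scenario")) counts$counts else as.matrix(counts)
  if (any(colSums(K) == 0)) stop("every sample needs at least one nonzero count")
  pos <- rowSums(K > 0) == ncol(K)
  if (!any(pos)) {
    warning("size_factors: no gene has positive counts in every sample; ",
            "falling back to library-size normalization")
    sf <- colSums(K)
  } else {
    Kp <- K[pos, , drop = FALSE]
    gm <- exp(rowMeans(log(Kp)))
    sf <- apply(sweep(Kp, 1, gm, "/"), 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(K))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; thin validated wrapper over the standard
#' implementation so the pipeline has a single multiple-testing surface.
#'
#' @param p_values numeric vector in \[0, 1\] (NAs propagated).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  pv <- p_values[!is.na(p_values)]
  if (length(pv) && (any(pv < 0) || any(pv > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Per gene: counts are normalized by [size_factors()]; group means of the
#' normalized counts give `log2_fold_change = log2((mean_2 + pc) / (mean_1 +
#' pc))` with pseudocount `pc = 0.5`; the dispersion `alpha` is estimated by
#' method of moments within groups, `alpha = (s^2 - mu) / mu^2` pooled
#' across the two groups with degrees-of-freedom weights and floored at
#' 1e-8 (the Poisson limit); the Wald statistic divides the natural-log
#' fold change by its delta-method standard error under the NB variance
#' `mu + alpha mu^2`, and a two-sided normal p-value is taken. P-values are
#' BH-adjusted across all tested genes. Genes with zero counts in both
#' groups get p = 1.
#'
#' @param counts integer matrix (genes x samples) or a `count_scenario`.
#' @param group_labels two-level factor over samples (ignored if `counts`
#'   is a `count_scenario`, which carries its own labels).
#' @param pseudocount added to each group mean in the fold change.
#' @return data.frame of class `de_result`: `gene_id`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `p_adjust`.
#' @export
nb_wald_test <- function(counts, group_labels = NULL, pseudocount = 0.5) {
  if (inherits(counts, "count_scenario")) {
    group_labels <- counts$group_labels
    counts <- counts$counts
  }
  K <- as.matrix(counts)
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2L)
    stop("exactly two groups are required")
  if (length(group_labels) != ncol(K))
    stop("one group label per sample is required")
  if (any(table(group_labels) < 2L))
    stop("each group needs at least 2 samples")

  sf <- size_factors(K)
  Q <- sweep(K, 2, sf, "/")
  g1 <- group_labels == levels(group_labels)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(Q[, g1, drop = FALSE])
  m2 <- rowMeans(Q[, g2, drop = FALSE])
  v1 <- apply(Q[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(Q[, g2, drop = FALSE], 1, stats::var)

  mom <- function(s2, mu) ifelse(mu > 0, (s2 - mu) / mu^2, 0)
  alpha <- ((n1 - 1) * mom(v1, m1) + (n2 - 1) * mom(v2, m2)) / (n1 + n2 - 2)
  alpha <- pmax(alpha, 1e-8)

  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  beta <- lfc * log(2)  # natural-log scale for the Wald statistic
  mu1 <- m1 + pseudocount; mu2 <- m2 + pseudocount
  # var(log mean_k) ~ (mu + alpha mu^2) / (n_k mu^2) by the delta method
  se <- sqrt((1 / mu1 + alpha) / n1 + (1 / mu2 + alpha) / n2)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p[m1 == 0 & m2 == 0] <- 1

  res <- data.frame(
    gene_id = if (!is.null(rownames(K))) rownames(K) else paste0("g", seq_len(nrow(K))),
    base_mean = rowMeans(Q),
    log2_fold_change = lfc,
    p_value = p,
    p_adjust = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select differentially expressed genes by significance and effect size
#'
#' Genes with `p_adjust < p_adjust_max` and `|log2_fold_change| > lfc_min`
#' (both strict). `two_sided = FALSE` restores a one-sided
#' `log2_fold_change > lfc_min` filter for up-regulated genes only.
#'
#' @param res a [nb_wald_test()] result.
#' @param p_adjust_max adjusted-p threshold (default 0.01).
#' @param lfc_min absolute log2-fold-change threshold (default 2).
#' @param two_sided logical; use `|lfc|` (default) or signed lfc.
#' @return Character vector of gene identifiers.
#' @export
select_de_genes <- function(res, p_adjust_max = 0.01, lfc_min = 2,
                            two_sided = TRUE) {
  effect <- if (two_sided) abs(res$log2_fold_change) else res$log2_fold_change
  res$gene_id[!is.na(res$p_adjust) & res$p_adjust < p_adjust_max &
                effect > lfc_min]
}

#' Top differential genes by adjusted p-value
#'
#' The `k` genes with smallest `p_adjust`; ties broken by larger
#' `|log2_fold_change|`, then lexicographic gene identifier. Returns all
#' genes when fewer than `k` exist.
#'
#' @param res a [nb_wald_test()] result.
#' @param k number of genes (default 100).
#' @return Character vector of gene identifiers, best first.
#' @export
top_k_genes <- function(res, k = 100L) {
  if (k < 1L) stop("k must be at least 1")
  ord <- order(res$p_adjust, -abs(res$log2_fold_change), res$gene_id)
  res$gene_id[ord][seq_len(min(k, nrow(res)))]
}
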