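#' Hypergeometric upper-tail probability for gene-set overlap
#'
#' The probability of observing `m` or more genes from a set of size `M`
#' when drawing `n` genes from a universe of `N`:
#' \deqn{\sum_{i=m}^{\min(M,n)} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}}
#' Computed in log space via `lchoose` for numerical stability and clamped
#' to \[0, 1\].
#'
#' @param N universe size; `M` genes of which belong to the set; `n` genes
#'   drawn (the differential list); `m` observed overlap.
#' @param M,n,m see above.
#' @return The tail probability; 1 when `m = 0`.
#' @export
hypergeom_tail <- function(N, M, n, m) {
  if (any(c(N, M, n, m) < 0) || M > N || n > N || m > min(M, n))
    stop("inconsistent hypergeometric arguments")
  if (m == 0) return(1)
  i <- m:min(M, n)
  lp <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  min(1, max(0, sum(exp(lp))))
}

#' Over-representation analysis of a gene list against gene sets
#'
#' For each set, counts the overlap with `de_genes` relative to the
#' `universe`, computes the hypergeometric tail p-value, and BH-adjusts
#' across all tested sets (those with overlap >= 1). Differential genes
#' absent from the universe are dropped with a message before `n` is
#' computed; set members outside the universe do not count toward `M`.
#'
#' @param de_genes character vector of differential gene identifiers.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe background gene identifiers (e.g. all genes surviving
#'   the expression filter).
#' @return data.frame with columns `set_name`, `N`, `M`, `n`, `count`,
#'   `p_value`, `p_adjust`, `overlap_genes` (comma-separated), sorted by
#'   `p_adjust` then `set_name`; zero rows when nothing overlaps.
#' @export
enrich <- function(de_genes, sets, universe) {
  if (length(sets) == 0L) stop("empty gene-set collection")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  universe <- unique(as.character(universe))
  de <- unique(as.character(de_genes))
  outside <- setdiff(de, universe)
  if (length(outside))
    message("enrich: dropped ", length(outside),
            " differential gene(s) absent from the universe")
  de <- intersect(de, universe)
  N <- length(universe)
  n <- length(de)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    ov <- intersect(de, members)
    m <- length(ov)
    if (m == 0L) return(NULL)
    data.frame(set_name = nm, N = N, M = length(members), n = n, count = m,
               p_value = hypergeom_tail(N, length(members), n, m),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(set_name = character(), N = integer(), M = integer(),
                      n = integer(), count = integer(), p_value = numeric(),
                      p_adjust = numeric(), overlap_genes = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_adjust <- bh_adjust(out$p_value)
  out <- out[order(out$p_adjust, out$set_name),
             c("set_name", "N", "M", "n", "count", "p_value", "p_adjust",
               "overlap_genes")]
  rownames(out) <- NULL
  out
}
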