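#' Prior regulatory network as an undirected edge set
#'
#' Directionality and regulation mode are deliberately dropped: the
#' estimated precision-matrix difference is symmetric, so the prior enters
#' only as a binary indicator of whether a gene pair is linked.
#'
#' @param edges data.frame (or 2-column matrix) whose first two columns are
#'   gene identifiers; self-pairs are removed, duplicates collapsed.
#' @param source short description of where the edges came from.
#' @return Object of class `prior_network` with `edges` (data.frame with
#'   columns `a`, `b`, `a < b` lexicographically) and `source`.
#' @export
prior_network <- function(edges, source = "unspecified") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have at least two columns")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a != b
  n_self <- sum(!keep)
  if (n_self > 0L)
    message("prior_network: dropped ", n_self, " self-loop(s)")
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(a = lo[!dup], b = hi[!dup], stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(edges = out, source = source), class = "prior_network")
}

#' @export
print.prior_network <- function(x, ...) {
  cat("Prior network (", x$source, "): ", nrow(x$edges),
      " undirected edges\n", sep = "")
  invisible(x)
}

#' Read a TRRUST-style regulatory edge list
#'
#' Expects tab-separated lines with at least two fields: regulator and
#' target (the third and fourth TRRUST columns — regulation mode and the
#' literature reference — are ignored). Directed records are collapsed to
#' unordered pairs, duplicates are removed, and self-loops are dropped with
#' a message. Lines with fewer than two fields are skipped with a warning
#' naming the line number.
#'
#' @param path path to the file.
#' @return A [prior_network()] (possibly empty).
#' @export
read_trrust <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(prior_network(data.frame(a = character(), b = character()),
                         source = path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    warning("read_trrust: skipped ", length(bad), " malformed line(s): ",
            paste(utils::head(bad, 5L), collapse = ", "))
  ok <- fields[lengths(fields) >= 2L]
  edges <- data.frame(a = vapply(ok, `[[`, "", 1L),
                      b = vapply(ok, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  prior_network(edges, source = path)
}

#' Build the penalty weight matrix from a prior network
#'
#' Gene pairs present in the prior get the reduced weight `w` (making those
#' edges cheaper for the lasso to include); all other entries, including the
#' diagonal, get weight 1. Prior edges touching genes outside `gene_ids`
#' are ignored with a message.
#'
#' @param prior a [prior_network()], or `NULL` for an all-ones matrix.
#' @param gene_ids character vector of unique gene identifiers defining the
#'   matrix order.
#' @param w reduced weight in (0, 1); 0.1 by default.
#' @return Object of class `weight_matrix` with fields `W` (p x p numeric),
#'   `w`, `gene_ids`, `n_prior_edges_used`.
#' @export
build_weight_matrix <- function(prior, gene_ids, w = 0.1) {
  if (w <= 0 || w >= 1) stop("w must lie strictly between 0 and 1")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  p <- length(gene_ids)
  W <- matrix(1, p, p, dimnames = list(gene_ids, gene_ids))
  used <- 0L
  if (!is.null(prior)) {
    stopifnot(inherits(prior, "prior_network"))
    e <- prior$edges
    ia <- match(e$a, gene_ids); ib <- match(e$b, gene_ids)
    ok <- !is.na(ia) & !is.na(ib)
    n_out <- sum(!ok)
    if (n_out > 0L)
      message("build_weight_matrix: ignored ", n_out,
              " prior edge(s) outside the gene list")
    W[cbind(ia[ok], ib[ok])] <- w
    W[cbind(ib[ok], ia[ok])] <- w
    used <- sum(ok)
  }
  structure(list(W = W, w = w, gene_ids = gene_ids,
                 n_prior_edges_used = used),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("Weight matrix: ", length(x$gene_ids), " genes, ",
      x$n_prior_edges_used, " prior edges at w = ", x$w, "\n", sep = "")
  invisible(x)
}
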