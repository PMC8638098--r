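#' Gene degrees in a differential network
#'
#' A gene's degree — the number of nonzero off-diagonal partners — counts
#' how many of its regulatory relationships differ between the two
#' conditions.
#'
#' @param net a [diff_network()].
#' @return data.frame with columns `gene_id`, `degree` (network order).
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "diff_network"))
  A <- net$delta != 0
  diag(A) <- FALSE
  out <- data.frame(gene_id = net$gene_ids, degree = as.integer(rowSums(A)),
                    stringsAsFactors = FALSE)
  # handshake identity: every edge contributes to exactly two degrees
  stopifnot(sum(out$degree) == 2L * nrow(net$support))
  out
}

#' Hub genes of a differential network
#'
#' The `k` genes with the highest degree, ties broken lexicographically by
#' gene identifier. Genes of degree zero are never hubs, so fewer than `k`
#' genes may be returned.
#'
#' @param net a [diff_network()].
#' @param k number of hubs (default 10).
#' @return Character vector of gene identifiers, highest degree first.
#' @export
hub_genes <- function(net, k = 10L) {
  if (k < 1L) stop("k must be at least 1")
  d <- network_degrees(net)
  d <- d[d$degree > 0L, , drop = FALSE]
  d <- d[order(-d$degree, d$gene_id), , drop = FALSE]
  utils::head(d$gene_id, k)
}

#' Export the differential edge list as TSV
#'
#' One row per unordered pair with a nonzero difference: columns `gene_a`,
#' `gene_b` (`gene_a < gene_b` lexicographically), `delta_value`,
#' `abs_delta`, sorted by `abs_delta` descending. An empty network yields a
#' header-only file.
#'
#' @param net a [diff_network()].
#' @param path output path.
#' @return The edge table, invisibly.
#' @export
export_edges <- function(net, path) {
  stopifnot(inherits(net, "diff_network"))
  s <- net$support
  if (nrow(s)) {
    ga <- net$gene_ids[s[, 1]]; gb <- net$gene_ids[s[, 2]]
    swap <- ga > gb
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
    val <- net$delta[s]
    df <- data.frame(gene_a = ga, gene_b = gb, delta_value = val,
                     abs_delta = abs(val), stringsAsFactors = FALSE)
    df <- df[order(-df$abs_delta, df$gene_a, df$gene_b), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(gene_a = character(), gene_b = character(),
                     delta_value = numeric(), abs_delta = numeric(),
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read an edge list written by [export_edges()]
#' @param path input path.
#' @return data.frame with the exported columns.
#' @export
read_edges <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric", "numeric"))
}
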