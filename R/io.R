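# Readers and writers for the plain-text formats the pipeline exchanges:
# genes-by-samples TSV matrices, 2-column sample/group tables, TRRUST-style
# edge lists and GMT gene-set files.

#' Write a genes-by-samples matrix as TSV
#'
#' First column `gene_id`, then one column per sample (header row of sample
#' identifiers). Works for expression values and for counts.
#'
#' @param X numeric matrix with rownames (genes) and colnames (samples).
#' @param path output path.
#' @export
write_expression_tsv <- function(X, path) {
  X <- as.matrix(X)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("matrix must carry gene rownames and sample colnames")
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples TSV matrix
#'
#' Inverse of [write_expression_tsv()]: first column gene identifiers,
#' remaining columns numeric sample values.
#'
#' @param path input path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}

#' Write group labels as a two-column TSV
#' @param labels factor or character vector of group labels.
#' @param sample_ids sample identifiers, same length.
#' @param path output path.
#' @export
write_group_labels <- function(labels, sample_ids, path) {
  utils::write.table(
    data.frame(sample_id = sample_ids, group = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read group labels written by [write_group_labels()]
#' @param path input path.
#' @return Named factor (names = sample ids).
#' @export
read_group_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(factor(df$group), df$sample_id)
}

#' Write a prior network in TRRUST-style four-column format
#'
#' Columns: regulator, target, mode, reference. Synthetic networks carry
#' mode "Unknown" and reference "synthetic", so the same [read_trrust()]
#' reader handles real TRRUST downloads and these files alike.
#'
#' @param prior a [prior_network()].
#' @param path output path.
#' @export
write_trrust <- function(prior, path) {
  stopifnot(inherits(prior, "prior_network"))
  e <- prior$edges
  lines <- if (nrow(e)) paste(e$a, e$b, "Unknown", "synthetic", sep = "\t")
           else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: set name, description, then tab-separated member genes.
#' Duplicate members within a set are removed; lines with fewer than three
#' fields are skipped with a warning.
#'
#' @param path input path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    warning("read_gmt: skipped ", length(bad), " line(s) with fewer than 3 fields")
  ok <- fields[lengths(fields) >= 3L]
  sets <- lapply(ok, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(ok, `[[`, "", 1L)
  sets
}
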