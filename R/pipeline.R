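# Orchestration of the two analysis tracks:
#   (A) counts -> DE -> top-k genes -> differential network -> hubs/enrichment
#   (B) expression pair restricted to one gene set -> differential network
# Every run writes plain-text tables plus a JSON manifest; outputs are a pure
# function of inputs + seed (no timestamps), so reruns are byte-identical.

#' Pipeline configuration
#'
#' Collects the tunable parameters of both pipeline modes with their
#' defaults: DE thresholds `p_adjust_max = 0.01`, `lfc_min = 2`, top
#' `k = 100` genes; prior weight `w = 0.1`; StARS `beta = 0.005`, `S = 20`
#' with a 20-point log-spaced lambda grid down to 1% of `lambda_max`;
#' counts entering the network stage are transformed as
#' `log2(normalized count + 1)` (`transform = "log1p-normalized"`; `"none"`
#' honors pre-normalized input).
#'
#' @param out_dir directory for output files.
#' @param p_adjust_max,lfc_min,k DE selection thresholds and top-k size.
#' @param min_total low-expression filter threshold (row-sum of counts).
#' @param w prior penalty weight in (0, 1).
#' @param beta,S StARS instability threshold and subsample count.
#' @param n_lambda,lambda_ratio_min lambda-grid shape.
#' @param penalize_diagonal penalize diagonal entries of the difference.
#' @param transform `"log1p-normalized"` or `"none"`.
#' @param seed integer seed for all stochastic steps.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("wdtrace_run_"),
                            p_adjust_max = 0.01, lfc_min = 2, k = 100L,
                            min_total = 10L, w = 0.1, beta = 0.005, S = 20L,
                            n_lambda = 20L, lambda_ratio_min = 0.01,
                            penalize_diagonal = TRUE,
                            transform = c("log1p-normalized", "none"),
                            seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(p_adjust_max > 0, lfc_min >= 0, k >= 1, w > 0, w < 1,
            beta > 0, beta < 1, S >= 2, n_lambda >= 2)
  structure(list(out_dir = out_dir, p_adjust_max = p_adjust_max,
                 lfc_min = lfc_min, k = as.integer(k),
                 min_total = as.integer(min_total), w = w, beta = beta,
                 S = as.integer(S), n_lambda = as.integer(n_lambda),
                 lambda_ratio_min = lambda_ratio_min,
                 penalize_diagonal = penalize_diagonal,
                 transform = transform, seed = as.integer(seed)),
            class = "pipeline_config")
}

log2_normalized <- function(K) {
  sf <- size_factors(K)
  log2(sweep(K, 2, sf, "/") + 1)
}

write_pipeline_outputs <- function(out_dir, config, de_table = NULL,
                                   selected_genes = NULL, stars = NULL,
                                   enrich_table = NULL, extra_manifest = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  if (!is.null(de_table)) {
    de_out <- data.frame(gene = de_table$gene_id, baseMean = de_table$base_mean,
                         log2FoldChange = de_table$log2_fold_change,
                         pvalue = de_table$p_value, padj = de_table$p_adjust)
    utils::write.table(de_out, pth("de_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(selected_genes))
    writeLines(selected_genes, pth("selected_genes.txt"))
  if (!is.null(stars)) {
    net <- stars$network
    export_edges(net, pth("edges.tsv"))
    utils::write.table(network_degrees(net), pth("degrees.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(hub_genes(net), pth("hubs.txt"))
    utils::write.table(
      data.frame(lambda = stars$lambda_grid,
                 instability = stars$instability,
                 instability_monotone = stars$instability_monotone,
                 n_fits_used = stars$n_fits_used),
      pth("stars_instability.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(enrich_table))
    utils::write.table(enrich_table, pth("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("wdtrace")),
    config = unclass(config),
    lambda_selected = if (!is.null(stars)) stars$lambda_selected,
    n_edges = if (!is.null(stars)) nrow(stars$network$support),
    network_converged = if (!is.null(stars)) stars$converged,
    network_genes = if (!is.null(stars)) stars$network$gene_ids
  ), extra_manifest)
  manifest <- manifest[!vapply(manifest, is.null, TRUE)]
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  yaml::write_yaml(unclass(config), pth("config.yaml"))
  invisible(out_dir)
}

#' Run the top-k-genes differential-network pipeline
#'
#' Track A of the analysis: differential expression on the counts, then a
#' prior-weighted differential network over the top `k` genes by adjusted
#' p-value, with StARS-selected regularization, plus over-representation
#' analysis of the significant genes when gene sets are supplied. Writes
#' `de_results.tsv`, `selected_genes.txt`, `edges.tsv`, `degrees.tsv`,
#' `hubs.txt`, `stars_instability.tsv`, `enrichment.tsv` (if sets given),
#' `manifest.json` and `config.yaml` under `config$out_dir`.
#'
#' @param counts integer genes-by-samples matrix or a `count_scenario`.
#' @param group_labels two-level factor (taken from the scenario if omitted).
#' @param prior optional [prior_network()] for the penalty weights.
#' @param gene_sets optional named list of gene sets for enrichment.
#' @param config a [pipeline_config()].
#' @return List with `de`, `selected_genes`, `network_genes`, `stars`,
#'   `network`, `hubs`, `degrees`, `enrichment`, `out_dir`.
#' @export
run_topk_pipeline <- function(counts, group_labels = NULL, prior = NULL,
                              gene_sets = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(counts, "count_scenario")) {
    group_labels <- counts$group_labels
    counts <- counts$counts
  }
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2L || any(table(group_labels) < 2L))
    stop("two groups with at least 2 samples each are required")

  K <- filter_low_expressed(counts, config$min_total)
  de <- nb_wald_test(K, group_labels)
  sig_genes <- select_de_genes(de, config$p_adjust_max, config$lfc_min)
  net_genes <- top_k_genes(de, config$k)

  E <- if (config$transform == "log1p-normalized") log2_normalized(K) else K
  g1 <- group_labels == levels(group_labels)[1]
  Xe <- E[net_genes, g1, drop = FALSE]
  Ye <- E[net_genes, !g1, drop = FALSE]
  W <- build_weight_matrix(prior, net_genes, config$w)

  stars <- stars_select(Xe, Ye, W, beta = config$beta, S = config$S,
                        lambda_grid = NULL, seed = config$seed,
                        penalize_diagonal = config$penalize_diagonal)
  net <- stars$network
  enr <- if (!is.null(gene_sets) && length(sig_genes))
    enrich(sig_genes, gene_sets, universe = rownames(K)) else NULL

  write_pipeline_outputs(
    config$out_dir, config, de_table = de, selected_genes = sig_genes,
    stars = stars, enrich_table = enr,
    extra_manifest = list(mode = "top-k-genes",
                          n_genes_filtered = nrow(K),
                          n_samples = ncol(K),
                          n_significant_genes = length(sig_genes),
                          prior_edges_used = W$n_prior_edges_used))

  list(de = de, selected_genes = sig_genes, network_genes = net_genes,
       stars = stars, network = net, hubs = hub_genes(net),
       degrees = network_degrees(net), enrichment = enr,
       out_dir = config$out_dir)
}

#' Run the gene-set-restricted differential-network pipeline
#'
#' Track B of the analysis: restrict both expression matrices to the genes
#' of one named set (those present in the data), then estimate the
#' prior-weighted differential network with StARS-selected regularization.
#' Inputs are taken as already on a Gaussian-appropriate scale (use
#' `log2(normalized + 1)` counts, or simulated Gaussian expression).
#'
#' @param X,Y genes-by-samples expression matrices for the two conditions.
#' @param set_name name of the set in `gene_sets`.
#' @param gene_sets named list of gene sets.
#' @param prior optional [prior_network()].
#' @param config a [pipeline_config()].
#' @return List with `genes_used`, `gene_report`, `stars`, `network`,
#'   `hubs`, `degrees`, `out_dir`.
#' @export
run_geneset_pipeline <- function(X, Y, set_name, gene_sets, prior = NULL,
                                 config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!set_name %in% names(gene_sets))
    stop("gene set '", set_name, "' not found in the collection")
  X <- as.matrix(X); Y <- as.matrix(Y)
  members <- unique(gene_sets[[set_name]])
  usable <- intersect(members, intersect(rownames(X), rownames(Y)))
  report <- list(set_name = set_name, set_size = length(members),
                 usable = length(usable),
                 missing = setdiff(members, usable))
  if (length(usable) < 3L)
    stop("gene set '", set_name, "' has ", length(usable),
         " usable gene(s) in the data; at least 3 are required")

  Xs <- X[usable, , drop = FALSE]
  Ys <- Y[usable, , drop = FALSE]
  W <- build_weight_matrix(prior, usable, config$w)
  stars <- stars_select(Xs, Ys, W, beta = config$beta, S = config$S,
                        lambda_grid = NULL, seed = config$seed,
                        penalize_diagonal = config$penalize_diagonal)
  net <- stars$network

  write_pipeline_outputs(
    config$out_dir, config, stars = stars,
    extra_manifest = list(mode = "gene-set", set_name = set_name,
                          set_size = length(members),
                          n_genes_used = length(usable),
                          prior_edges_used = W$n_prior_edges_used))

  list(genes_used = usable, gene_report = report, stars = stars,
       network = net, hubs = hub_genes(net), degrees = network_degrees(net),
       out_dir = config$out_dir)
}
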