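#!/usr/bin/env Rscript
# Simulate every input the downstream analyses need and write them as
# plain-text files under results/data/:
#   - an NB count matrix (2000 genes, 40 samples per subtype) with 100
#     planted fold-change genes, plus its group labels
#   - paired Gaussian expression (p = 40 genes, 400 samples per condition)
#     from two precision matrices differing on 10 known edges
#   - a TRRUST-style prior edge list covering the true differential edges
#   - toy gene sets (GMT), including the set of differential-edge genes

suppressPackageStartupMessages(library(wdtrace))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260928L

scn_counts <- make_nb_counts(2000, 40, n_de = 100, lfc = 3, base_mean = 100,
                             dispersion = 0.1, seed = seed)
write_expression_tsv(scn_counts$counts, file.path(out, "counts.tsv"))
write_group_labels(scn_counts$group_labels, colnames(scn_counts$counts),
                   file.path(out, "group_labels.tsv"))
writeLines(rownames(scn_counts$counts)[scn_counts$de_genes],
           file.path(out, "planted_de_genes.txt"))
message("counts: ", nrow(scn_counts$counts), " genes x ",
        ncol(scn_counts$counts), " samples; ",
        length(scn_counts$de_genes), " planted DE genes (lfc = 3)")

scn_net <- make_precision_pair(40, 20, 10, magnitude = 0.4, seed = seed + 1L)
X <- sample_expression(scn_net$theta_X, 400, seed = seed + 2L)
Y <- sample_expression(scn_net$theta_Y, 400, seed = seed + 3L)
write_expression_tsv(X, file.path(out, "expression_condition_X.tsv"))
write_expression_tsv(Y, file.path(out, "expression_condition_Y.tsv"))
true_edges <- data.frame(
  gene_a = scn_net$gene_ids[scn_net$diff_edges[, 1]],
  gene_b = scn_net$gene_ids[scn_net$diff_edges[, 2]])
write.table(true_edges, file.path(out, "true_differential_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("expression: p = ", scn_net$p, ", ", nrow(scn_net$diff_edges),
        " true differential edges")

prior <- make_prior_network(scn_net, coverage = 1, noise_edges = 5,
                            seed = seed + 4L)
write_trrust(prior, file.path(out, "prior_network.tsv"))
message("prior: ", nrow(prior$edges), " undirected edges (synthetic TRRUST dialect)")

sets <- make_gene_sets(scn_net, n_random = 5, set_size = 10, seed = seed + 5L)
write_gmt(sets, file.path(out, "gene_sets.gmt"))
message("gene sets: ", length(sets), " sets written to GMT")
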