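#!/usr/bin/env Rscript
# Differential network between the two simulated conditions: weighted
# D-trace estimation with the TRRUST-style prior (w = 0.1) and StARS
# (beta = 0.005, S = 20) regularization selection, followed by degrees and
# hub genes, and a comparison of the recovered edges with the planted truth.

suppressPackageStartupMessages(library(wdtrace))
dat <- "results/data"
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

X <- read_expression_tsv(file.path(dat, "expression_condition_X.tsv"))
Y <- read_expression_tsv(file.path(dat, "expression_condition_Y.tsv"))
prior <- read_trrust(file.path(dat, "prior_network.tsv"))
truth <- read.delim(file.path(dat, "true_differential_edges.tsv"))

W <- build_weight_matrix(prior, rownames(X), w = 0.1)
message("prior: ", W$n_prior_edges_used, " usable edges at weight 0.1")

res <- stars_select(X, Y, W, beta = 0.005, S = 20, seed = 7L)
message("StARS selected lambda = ", signif(res$lambda_selected, 4),
        " -> ", nrow(res$network$support), " edges")

edges <- export_edges(res$network, file.path(out, "edges.tsv"))
deg <- network_degrees(res$network)
write.table(deg, file.path(out, "degrees.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
hubs <- hub_genes(res$network, k = 10)
writeLines(hubs, file.path(out, "hub_genes.txt"))
write.table(
  data.frame(lambda = res$lambda_grid, instability = res$instability,
             instability_monotone = res$instability_monotone),
  file.path(out, "stars_instability.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

jsonlite::write_json(list(lambda = res$lambda_selected,
                          n_edges = nrow(res$network$support)),
                     "results/network_manifest.json", auto_unbox = TRUE)

true_keys <- with(truth, paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b)))
est_keys <- with(edges, paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b)))
tp <- length(intersect(est_keys, true_keys))
message("edge recovery: ", tp, "/", length(true_keys), " true edges found, ",
        length(est_keys) - tp, " extra; hubs: ", paste(hubs, collapse = ", "))
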