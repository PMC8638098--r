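#!/usr/bin/env Rscript
# Differential expression on the simulated counts: low-count filter,
# NB Wald test, selection at p_adjust < 0.01 & |log2FC| > 2, and the
# top-100 gene list that seeds the differential-network stage.

suppressPackageStartupMessages(library(wdtrace))
dat <- "results/data"
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_expression_tsv(file.path(dat, "counts.tsv"))
labels <- read_group_labels(file.path(dat, "group_labels.tsv"))
planted <- readLines(file.path(dat, "planted_de_genes.txt"))

K <- filter_low_expressed(counts, min_total = 10)
message("filter: ", nrow(counts) - nrow(K), " low-count genes removed, ",
        nrow(K), " kept")

res <- nb_wald_test(K, labels[colnames(K)])
write.table(
  data.frame(gene = res$gene_id, baseMean = res$base_mean,
             log2FoldChange = res$log2_fold_change,
             pvalue = res$p_value, padj = res$p_adjust),
  file.path(out, "de_results.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

sel <- select_de_genes(res, p_adjust_max = 0.01, lfc_min = 2)
top100 <- top_k_genes(res, k = 100)
writeLines(sel, file.path(out, "selected_genes.txt"))
writeLines(top100, file.path(out, "top100_genes.txt"))

message("selected ", length(sel), " genes at padj<0.01 & |lfc|>2; ",
        "recovered ", sum(planted %in% sel), "/", length(planted),
        " planted genes; ", sum(!sel %in% planted), " false selections")
message("top-100 list contains ", sum(top100 %in% planted), " planted genes")
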