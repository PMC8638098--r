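#!/usr/bin/env Rscript
# Over-representation analysis: are the genes touched by the recovered
# differential edges enriched in any of the bundled gene sets? The
# "diff_edge_genes" set (genes incident to a true differential edge) should
# surface at the top; the random sets should not.

suppressPackageStartupMessages(library(wdtrace))
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sets <- read_gmt("results/data/gene_sets.gmt")
deg <- read.delim("results/network/degrees.tsv")
universe <- deg$gene_id
hit_genes <- deg$gene_id[deg$degree > 0]
message(length(hit_genes), " genes carry at least one differential edge")

tab <- enrich(hit_genes, sets, universe)
write.table(tab, file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top sets by adjusted p-value:")
for (i in seq_len(min(3, nrow(tab))))
  message(sprintf("  %-18s count %d/%d  p_adjust %.3g",
                  tab$set_name[i], tab$count[i], tab$M[i], tab$p_adjust[i]))
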