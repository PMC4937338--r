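#!/usr/bin/env Rscript
# Stage 3 — Spearman co-expression network.
#
# TMM-only normalization (the within-sample step cannot change ranks),
# per-gene Tukey-fence outlier masking, pairwise SCC over shared unmasked
# samples, thresholding at SCC > 0.85.

library(retinet)

ds <- readRDS("scratch/dataset.rds")
pipe <- coexpression_pipeline(ds$counts, threshold = 0.85, signed = TRUE)

net <- pipe$network
print(net)
cat(sprintf("Edges are %.2f%% of the %s possible pairs among %d filtered genes.\n",
            edge_percentage(net),
            format(count_gene_pairs(net$n_genes_tested), big.mark = ","),
            net$n_genes_tested))
deg <- degree_stats(net, k = 100)
cat(sprintf("%.0f%% of network nodes have more than 100 edges.\n",
            100 * deg$fraction_above_k))

write_edges_tsv(net$edges, "results/network_edges.tsv")
writeLines(net$nodes, "results/network_nodes.txt")
saveRDS(pipe, "scratch/pipeline.rds") # scratch for stages 4-5
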