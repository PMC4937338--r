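#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study dataset.
#
# Emulates the shape of the 50-donor retina cohort: 18 female / 32 male
# samples, sequencing depths of 40-110 million reads, negative-binomial
# counts for 2000 genes of which 100 form one tightly co-expressed module
# (a shared latent factor per sample), 13 highly expressed mitochondrial
# genes, a 30-gene seed list drawn from the module, and a toy transcript
# fixture for the transcript-level utilities.

library(retinet)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(rng_seed = 1L)
ds <- simulate_dataset(cfg)

write_counts_tsv(ds$counts, file.path(out, "counts.tsv"))
write_annotation_tsv(ds$annotation, file.path(out, "annotation.tsv"))
write_seed_list(ds$seed_genes, file.path(out, "seed_genes.txt"))
write.table(data.frame(sample_id = names(ds$sample_sex), sex = ds$sample_sex),
            file.path(out, "samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_edges_tsv(make_gold_standard(ds, fraction = 1),
                file.path(out, "gold_edges.tsv"))
write_transcripts_gtf(ds$fixture$observed, file.path(out, "observed.gtf"))
write_transcripts_gtf(ds$fixture$reference, file.path(out, "reference.gtf"))
dir.create("scratch", showWarnings = FALSE)
saveRDS(ds, "scratch/dataset.rds") # binary scratch shared by later stages

mito <- ds$annotation$gene_id[ds$annotation$chromosome == "MT"]
cat(sprintf("Simulated %d genes x %d samples (%dF/%dM).\n",
            nrow(ds$counts), ncol(ds$counts),
            sum(ds$sample_sex == "F"), sum(ds$sample_sex == "M")))
cat(sprintf("Mitochondrial genes carry %.1f%% of all reads.\n",
            100 * sum(ds$counts[mito, ]) / sum(ds$counts)))
cat(sprintf("Planted module: %d genes, %d designated seeds.\n",
            sum(!is.na(ds$true_modules)), length(ds$seed_genes)))
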