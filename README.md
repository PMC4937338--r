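# retinet

Gene co-expression network inference and guilt-by-association candidate gene
discovery for bulk RNA-seq — designed around multi-donor tissue cohorts such
as post-mortem human retina, where inter-individual variability in gene
expression is the signal: genes that rise and fall together across donors
are either co-regulated or mark the same cell type.

For a gene × sample count matrix the pipeline is

1. **Filter** — a gene is expressed only with ≥ 1 CPM in *every* sample
   (CPM = count · 10⁶ / library size).
2. **Normalize** — length-stratified full-quantile normalization within
   samples; trimmed-mean-of-M-values (TMM) scaling between samples. The
   network stage uses TMM only, since Spearman correlation is invariant to
   gene-wise transforms.
3. **Correlate** — per gene, mask samples outside the Tukey fences
   [Q1 − 1.5·IQR, Q3 + 1.5·IQR]; compute the Spearman correlation ρ of every
   gene pair on the samples both genes retain; keep pairs with ρ > 0.85.
4. **Guilt-by-association** — for each network gene g with (capped, top-200)
   neighbourhood N(g) and seed set S in universe U, a one-sided Fisher's
   exact test of the 2×2 table {N∩S, N∖S, S∖(N∪{g}), rest of U∖{g}};
   Benjamini–Hochberg FDR over all network genes; candidates at q < 0.05.
5. **Validate** — ROC of the unsigned-ρ pair ranking against a gold-standard
   edge set, with a random-ranking baseline (tie-aware trapezoid AUC ≡
   Mann–Whitney U).

A seeded synthetic-data generator (negative-binomial counts, planted
latent-factor modules, sexed samples, mitochondrial over-expression, seed
lists, gold standards, toy transcript fixtures) makes every stage testable
offline, and transcript-level utilities cover ensemble presence filtering,
junction-chain classification against a reference annotation, longest-ORF
prediction and 100-bp average-coverage tracks.

## Worked example

```r
library(retinet)
ds  <- simulate_dataset(simulation_config(rng_seed = 1L))
rec <- gba_recovery(ds)          # counts -> network -> candidates
rec$pipeline$network
#> coexpression_network: 97 nodes, 4656 edges (signed SCC > 0.85; 1994 genes tested)
round(100 * rec$sensitivity, 1)
#> [1] 97.1
100 * rec$background_rate
#> [1] 0
head(rec$enrichment[, 1:5], 3)
#>     gene_id n_neighbors_used n_seed_neighbors      p_value      q_value
#> 1 gene00002               96               29 6.880281e-41 9.814519e-41
#> 2 gene00004               96               29 6.880281e-41 9.814519e-41
#> 3 gene00005               96               29 6.880281e-41 9.814519e-41
```

97.1% of the planted module's non-seed genes are recovered as candidates at
FDR < 0.05 and no background gene is falsely called: the neighbourhoods of
module genes contain essentially the whole module (≈96 genes, all 30 seeds),
which a 2×2 table over the ~2000-gene universe turns into vanishing
p-values, while background genes never enter the network.

The same computation runs as a narrative workflow:

```sh
Rscript analysis/01_simulate.R      # writes results/data/ (TSV/GTF inputs)
Rscript analysis/02_normalize.R     # filter + normalization + gene summary
Rscript analysis/03_network.R       # SCC network, edge/degree statistics
Rscript analysis/04_gba.R           # candidate ranking + seed overlap
Rscript analysis/05_evaluate_roc.R  # ROC vs planted gold standard
Rscript analysis/06_transcripts.R   # transcript utilities + coverage track
```

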