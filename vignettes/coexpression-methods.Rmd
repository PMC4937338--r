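---
title: "From bulk RNA-seq counts to candidate genes: methods and design notes"
author: "retinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bulk RNA-seq counts to candidate genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinet)
```

## The problem

Bulk RNA-seq of a tissue collected from many donors carries two kinds of
signal. The average expression per gene describes the tissue's reference
transcriptome; the *inter-individual variability* around that average can be
exploited to find genes that rise and fall together across donors — typically
because they are co-regulated, or because they mark the same cell type whose
abundance varies from donor to donor. `retinet` implements the second idea as
a complete pipeline: normalize counts, correlate genes with Spearman's rank
correlation, threshold into a co-expression network, and nominate candidate
cell-type-specific or disease genes by *guilt-by-association* — a gene whose
network neighbours are enriched for known photoreceptor (or disease) genes is
itself a candidate.

The pipeline was designed around a 50-donor retina cohort (18 female, 32
male donors; 40–110 million reads per sample), and those numbers are the
defaults of the built-in synthetic-data generator, so every stage can be
exercised and tested without any external download.

## Normalization model

**Expression filter.** A gene counts as expressed only with at least
`min_cpm = 1` count per million mapped reads in *every* sample; the boundary
is inclusive. CPM uses the raw library sizes (column sums before filtering),
matching the filter's position at the head of the pipeline.

**Within-sample normalization.** Counts depend non-linearly on gene length.
The correction stratifies genes into `n_bins` equal-size bins by length rank
and full-quantile normalizes the strata against each other, per sample, onto
a common target distribution — the mean of the strata's order statistics.
The number of bins is a free parameter (default 10, the common choice for
this family of methods); the result is insensitive to it within a factor of
two either way because the map is monotone within every stratum. With unequal
stratum sizes the target is evaluated on a common probability grid with
type-7 (linear-interpolation) quantiles — the one quantile convention used
everywhere in the package, including Tukey fences and the TMM reference
choice. Ties map to the average rank, so tied counts stay tied and
within-stratum order is never disturbed.

**Between-sample normalization** is the published trimmed-mean-of-M-values
(TMM) procedure with its standard constants: reference sample = upper-quartile
CPM closest to the mean upper-quartile, log-ratios trimmed 30% per tail,
log-abundances trimmed 5% per tail, inverse-variance weighting, factors
rescaled to geometric mean one. The implementation is written against the
published definition and is cross-checked in the test suite, to 1e-10,
against an independent implementation (edgeR's `calcNormFactors`).

**Per-gene summaries** are the median normalized count across samples (the
single expression value per gene) and the coefficient of variation
(sd/mean), used to rank genes by expression and by variability.

## Network model

The network stage deliberately skips the within-sample step: Spearman
correlation is invariant under any gene-wise monotone transform, so only the
TMM scaling matters. Per gene, samples outside the Tukey fences
[Q1 − 1.5·IQR, Q3 + 1.5·IQR] (bounds inclusive; a constant gene keeps all
samples) are masked, and each pair's SCC is computed on the samples retained
by *both* genes, with average ranks for ties re-computed on the shared
samples. Pairs sharing fewer than `min_overlap = 20` samples are undefined
and can never become edges — the cohort has 50 samples, and correlations on
fewer than ~20 points at a 0.85 threshold would be dominated by small-sample
noise; the choice is exposed as a parameter.

Edges are pairs with SCC strictly above the threshold (default 0.85; the
value that selects roughly the top 1.5% of all pairs in the cohort the
pipeline was designed for). Signed mode (the default, used for
guilt-by-association) keeps positive exceedances only; unsigned mode, used
for ROC ranking, thresholds |SCC|. Genes without any edge are excluded from
the node set.

## Guilt-by-association

For every network gene the `cap = 200` most-correlated neighbours (ties at
the boundary broken by gene id, for determinism) form the test set of a
one-sided Fisher's exact test against the seed list, over a gene universe
with the focal gene removed — so a seed gene cannot count itself as
evidence. Benjamini–Hochberg FDR is controlled over all network genes and
candidates are called at q < `alpha = 0.05`; the published analysis ranked
candidates by FDR without stating its cut-off, and 0.05 is the conventional
default. Ranking is by q, then p, then gene id — fully deterministic.

The default universe is the network node set: only network genes have
neighbourhoods, and in a real cohort nearly every expressed gene retains
some edge. The synthetic recovery analysis (`gba_recovery()`) overrides the
universe to the full filtered gene set, because simulated background genes
are exactly uncorrelated, form no edges at all, and would otherwise collapse
the universe onto the planted module and strip the 2×2 tables of any
contrast. This is a property of idealised null genes, not of the method.

## ROC validation

Gene pairs are ranked by unsigned SCC and compared with a gold-standard edge
set; ties form groups that contribute diagonal ROC segments, making the
trapezoid AUC identical to the Mann–Whitney U statistic with half credit for
ties (the suite checks this against a brute-force pairwise-comparison
oracle). The random baseline permutes the ranking and summarises the AUC
distribution. The universe of scored pairs defaults to all pairs among
network nodes. For the synthetic validation the dataset plants *three*
modules and takes all within-module pairs as gold: with a single module and
a subsampled gold standard, positives and negatives would both be
within-module pairs — equally correlated by construction — and no ranking
could separate them; between-module pairs supply genuine negatives.

## Synthetic-data generator

The generator emulates the features of the cohort the analysis assumes:

* 50 samples (18 F / 32 M), depths uniform on 40–110 million reads;
* gene baselines log-normal (sdlog 1.5), lengths log-uniform on 0.3–20 kb;
* 13 mitochondrial genes on chromosome "MT" with a 17× expression multiplier,
  which puts close to 10% of all reads on the mitochondrial genome;
* one 100-gene module whose genes share a per-sample standard-normal latent
  factor z with log-scale loading 1: gene g's mean in sample s is
  `depth_s · w_gs / Σ_g w_gs` with `w_gs = base_g · exp(b_g z_m(s))`;
* negative-binomial counts with shared dispersion 40 (variance
  μ + μ²/40, i.e. ~16% residual coefficient of variation once the module
  factor is modelled separately — a typical residual noise level for bulk
  RNA-seq of one tissue). Together with loading 1 this places the median
  within-module SCC near 0.94, so the planted module sits clearly above the
  0.85 threshold — the regime the guilt-by-association method targets —
  while background pairs at n = 50 essentially never cross it;
* a 30-gene seed list sampled from the module, and a gold standard sampled
  from within-module pairs (never crossing modules);
* a toy transcript fixture: reference models plus derived variants (exact
  copy, shared first junction, disjoint novel), per-transcript×sample
  expression confidence intervals with a configurable fraction of zero lower
  bounds, and per-sample read intervals for coverage binning.

All randomness flows through one integer seed with fixed per-component
offsets, so any component regenerates identically on its own. What the
generator does **not** emulate: correlated library-preparation batches,
GC-content trends, gene–gene correlation outside planted modules, realistic
transcript sequences (ORFs arise by chance), or read-level errors. Passing
tests therefore demonstrate correctness of the computations and
recoverability under the stated statistical structure — not robustness to
every artefact of real data.

## Transcript-level utilities

**Ensemble presence filter.** A transcript is present in a sample when the
lower bound of its expression confidence interval is strictly positive, and
retained when present in a *strict* majority (>50%) of female samples and a
strict majority of male samples. Strictness at exactly 50% is the one open
reading of the rule; the removal phrasing ("confidence interval including 0
in more than 50% of male or female samples") and the retention phrasing
("majority of both sexes") agree under the strict convention, which is the
one implemented and truth-table-tested.

**Junction classification** compares ordered junction chains (exact
coordinates, no fuzz window) on the same chromosome and strand:
`exact_junction_match`, `shared_junction` (≥1 common junction), else
`novel`. Mono-exonic transcripts are classified by interval identity
(strand-aware) or ≥1 bp overlap (strand-agnostic — an unspliced fragment
carries no splice-based strand evidence): `exact_overlap`,
`partial_overlap`, `no_overlap`. Coordinates are 0-based half-open
internally; GTF I/O converts to and from 1-based inclusive.

**Longest ORF**: sense strand only (transcripts are oriented mRNA), all
three frames, ATG to the *first* in-frame stop fully inside the sequence,
longest by nucleotide length including the stop, ties to the smallest start
offset; `NULL` when no complete ORF exists.

**Coverage track**: fixed 100-nt bins from coordinate 0; a read counts in
every bin it overlaps by ≥1 bp (the simplest convention consistent with
"reads falling in the bin"; per-base apportionment would change values by
<1 bin width). Bins with fewer than 100 summed reads across samples are
set to 0; bins at exactly 100 keep their value (mean across samples of
reads-in-bin over total aligned reads of the sample).

## Problem sizes and numerical choices

The packaged analyses and tests run at deliberately modest sizes chosen as
representative rather than exhaustive: the default recovery dataset is 2 000
genes × 50 samples (one 100-gene module, 30 seeds), the ROC dataset 1 200
genes with three 60-gene modules, and the oracle sweeps enumerate all 2×2
tables up to total 60, a thousand random ORF sequences, and a few hundred
random rankings. Degenerate inputs are handled explicitly: zero library
sizes, empty filters, constant genes (CV 0, all samples inside the fences),
zero-mean genes (CV undefined, flagged NA), networks with isolated genes,
ROC inputs lacking positives or negatives, and hypergeometric tables at the
support boundary (a = 0 gives p = 1 exactly).

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(simulation_config(rng_seed = 1L))
rec <- gba_recovery(ds)
rec$sensitivity      # fraction of non-seed module genes recovered
rec$background_rate  # fraction of background genes falsely called
head(rec$enrichment) # the ranked candidate table
```

The `analysis/` directory runs the same computation as a six-stage narrative
workflow and writes its tables under `results/`.

## Known limitations

* The guilt-by-association universe question (network nodes vs all filtered
  genes) genuinely changes p-values; both are exposed, and the synthetic
  analysis documents why it widens the universe.
* The generator's single-factor module is the minimal mechanism producing
  rank-correlated counts; real co-expression has hierarchical and
  overlapping structure the recovery numbers do not speak to.
* Odds ratios of candidate/seed overlap are sample odds ratios; with empty
  off-diagonal cells they are reported as infinite rather than estimated by
  a conditional MLE.
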