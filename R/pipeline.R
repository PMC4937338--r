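#' Counts-to-network co-expression pipeline
#'
#' Chains the stages used for network inference: expression filter (>= 1 CPM
#' in every sample), TMM-only between-sample normalization (no within-sample
#' step — rank correlations are unaffected by gene-wise transforms),
#' per-gene Tukey-fence outlier masking, pairwise Spearman correlation on
#' shared unmasked samples, and thresholding into a network.
#'
#' @param counts raw gene x sample count matrix.
#' @param min_cpm expression filter floor (default 1).
#' @param threshold SCC threshold (default 0.85).
#' @param signed signed thresholding (default TRUE).
#' @param min_overlap minimum shared unmasked samples per pair (default 20).
#' @return list with `filtered` (count matrix), `norm` (TMM-scaled matrix),
#'   `mask`, `scc` (full matrix), `network` (a `coexpression_network`).
#' @export
coexpression_pipeline <- function(counts, min_cpm = 1, threshold = 0.85,
                                  signed = TRUE, min_overlap = 20) {
  filtered <- filter_expressed(counts, min_cpm = min_cpm)
  norm <- normalize_counts(filtered, within = FALSE,
                           lib_size = attr(filtered, "lib_size"))
  mask <- mask_outliers(norm)
  scc <- spearman_matrix(norm, mask, min_overlap = min_overlap)
  net <- build_network(scc, threshold = threshold, signed = signed)
  list(filtered = filtered, norm = norm, mask = mask, scc = scc,
       network = net)
}

#' Planted-module recovery of the guilt-by-association pipeline
#'
#' Runs the full counts-to-candidates pipeline on a synthetic dataset and
#' scores recovery of the planted module: sensitivity is the fraction of
#' non-seed module genes called candidates; the background rate is the
#' fraction of background (no-module) genes called candidates. Genes the
#' expression filter removed, or that never enter the network, count as not
#' called. The enrichment universe is the full filtered gene set rather than
#' the network node set: on synthetic data uncorrelated background genes
#' form no edges at all, so the node set collapses onto the planted module
#' and would leave the 2x2 tables without the background contrast that real
#' networks (where nearly every gene keeps some edge) provide.
#'
#' @param dataset a `synthetic_dataset` with at least one module and a seed
#'   list.
#' @param threshold,cap,alpha network and GBA parameters.
#' @return list with `sensitivity`, `background_rate`, `enrichment` (the
#'   full record table), `pipeline` (the network pipeline stages), and the
#'   gene sets used.
#' @export
gba_recovery <- function(dataset, threshold = 0.85, cap = 200,
                         alpha = 0.05) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            length(dataset$seed_genes) > 0)
  pipe <- coexpression_pipeline(dataset$counts, threshold = threshold)
  enr <- neighbor_enrichment(pipe$network, dataset$seed_genes,
                             universe = rownames(pipe$filtered),
                             cap = cap, alpha = alpha)
  candidates <- enr$gene_id[enr$is_candidate]

  mods <- dataset$true_modules
  module_genes <- names(mods)[!is.na(mods)]
  target <- setdiff(names(mods)[which(mods == 1L)], dataset$seed_genes)
  background <- setdiff(rownames(dataset$counts), module_genes)
  list(
    sensitivity = mean(target %in% candidates),
    background_rate = mean(background %in% candidates),
    enrichment = enr, pipeline = pipe, candidates = candidates,
    target_genes = target, background_genes = background
  )
}
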