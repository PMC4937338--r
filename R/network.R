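#' Per-gene Tukey-fence outlier mask
#'
#' For every gene, samples whose normalized value falls outside
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] (quartiles by the package-wide type-7
#' convention, bounds inclusive) are masked out before correlation. A
#' constant gene has IQR 0 and keeps every sample.
#'
#' @param norm numeric gene x sample matrix (>= 4 samples).
#' @return logical matrix, same shape; TRUE = sample retained for that gene.
#' @export
mask_outliers <- function(norm) {
  norm <- as.matrix(norm)
  if (ncol(norm) < 4) stop("outlier masking needs at least 4 samples")
  q <- t(apply(norm, 1, rn_quantile, probs = c(0.25, 0.75)))
  iqr <- q[, 2] - q[, 1]
  lo <- q[, 1] - 1.5 * iqr
  hi <- q[, 2] + 1.5 * iqr
  mask <- norm >= lo & norm <= hi
  dimnames(mask) <- dimnames(norm)
  mask
}

#' Pairwise Spearman correlation under outlier masks
#'
#' Spearman correlation for every gene pair, computed on the samples retained
#' by BOTH genes' masks; values are re-ranked on each pair's shared samples
#' (average ranks for ties). Pairs sharing fewer than `min_overlap` samples
#' are set to `NA` (treated downstream as non-edges). Input should be the
#' TMM-only normalized matrix: the within-sample step is a gene-wise
#' transform that cannot change ranks across samples.
#'
#' @param norm numeric gene x sample matrix.
#' @param mask optional logical matrix from [mask_outliers()]; NULL = keep all.
#' @param min_overlap minimum shared unmasked samples per pair (default 20).
#' @return symmetric numeric matrix of SCC values with unit diagonal.
#' @export
spearman_matrix <- function(norm, mask = NULL, min_overlap = 20) {
  x <- t(as.matrix(norm)) # samples x genes
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(as.matrix(norm))))
    x[!t(mask)] <- NA_real_
  }
  scc <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  )
  overlap <- crossprod(!is.na(x))
  scc[overlap < min_overlap] <- NA_real_
  diag(scc) <- 1
  scc
}

#' Threshold an SCC matrix into a co-expression network
#'
#' Signed mode keeps pairs with SCC strictly above the threshold; unsigned
#' mode keeps pairs with |SCC| strictly above it. Genes left without any
#' edge are excluded from the node set. `NA` correlations (insufficient
#' overlap) never form edges.
#'
#' @param scc symmetric SCC matrix with gene ids as dimnames.
#' @param threshold correlation threshold in (0, 1) (default 0.85).
#' @param signed keep only positive exceedances (default TRUE); FALSE
#'   thresholds on the absolute SCC.
#' @return object of class `coexpression_network`: list with `nodes`
#'   (character), `edges` (data.frame `gene_i`, `gene_j`, `scc`; `gene_i` <
#'   `gene_j` by id order), `threshold`, `signed`, and `n_genes_tested` (the
#'   size of the matrix the network was thresholded from).
#' @export
build_network <- function(scc, threshold = 0.85, signed = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)")
  }
  scc <- as.matrix(scc)
  stopifnot(nrow(scc) == ncol(scc))
  ids <- rownames(scc)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(scc)))

  ut <- upper.tri(scc)
  val <- scc[ut]
  keep <- if (signed) !is.na(val) & val > threshold else !is.na(val) & abs(val) > threshold
  idx <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  gi <- ids[idx[, 1]]
  gj <- ids[idx[, 2]]
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  edges <- data.frame(gene_i = gi, gene_j = gj, scc = val[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = sort(unique(c(edges$gene_i, edges$gene_j))),
         edges = edges, threshold = threshold, signed = signed,
         n_genes_tested = nrow(scc)),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d nodes, %d edges (%s SCC > %g; %d genes tested)\n",
    length(x$nodes), nrow(x$edges),
    if (x$signed) "signed" else "unsigned", x$threshold, x$n_genes_tested))
  invisible(x)
}

#' Node degrees and hub fraction
#'
#' @param net a `coexpression_network`.
#' @param k degree cut for the hub fraction (default 100, reported as the
#'   fraction of network nodes with more than `k` edges).
#' @return list with `degree` (named integer vector over nodes) and
#'   `fraction_above_k`.
#' @export
degree_stats <- function(net, k = 100) {
  stopifnot(inherits(net, "coexpression_network"))
  deg <- table(factor(c(net$edges$gene_i, net$edges$gene_j),
                      levels = net$nodes))
  deg <- stats::setNames(as.integer(deg), names(deg))
  list(degree = deg, fraction_above_k = mean(deg > k))
}

#' Fraction of possible gene pairs present as edges
#'
#' @param net a `coexpression_network`.
#' @param n_genes number of genes whose pairs were tested (defaults to the
#'   matrix size recorded in the network).
#' @return edge count over `count_gene_pairs(n_genes)`, as a percentage.
#' @export
edge_percentage <- function(net, n_genes = net$n_genes_tested) {
  stopifnot(inherits(net, "coexpression_network"))
  100 * nrow(net$edges) / count_gene_pairs(n_genes)
}
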