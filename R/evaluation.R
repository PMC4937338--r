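#' ROC of a pair ranking against a gold-standard edge set
#'
#' Ranks gene pairs by |score| descending, grouping tied scores, and sweeps
#' the threshold over the tie groups; positives are pairs present in the
#' gold standard. The AUC is the trapezoid area, so a tie group containing
#' both positives and negatives contributes a diagonal segment — equivalent
#' to the Mann-Whitney U statistic with half credit for ties.
#'
#' @param scores numeric vector of pair scores (the unsigned value is
#'   ranked), one per universe pair.
#' @param is_gold logical vector parallel to `scores`: pair is in the gold
#'   standard.
#' @return object of class `roc_curve`: list with `points` (data.frame
#'   `fpr`, `tpr`, monotone from (0,0) to (1,1)), `auc`, `n_positive`,
#'   `n_negative`.
#' @export
roc_vs_gold <- function(scores, is_gold) {
  stopifnot(length(scores) == length(is_gold), !anyNA(is_gold))
  is_gold <- as.logical(is_gold)
  n_pos <- sum(is_gold)
  n_neg <- sum(!is_gold)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative pair")
  }
  s <- abs(scores)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  g <- is_gold[ord]
  # collapse tie groups: cumulative counts at the end of each distinct score
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(g)[grp_end]
  fp <- cumsum(!g)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr),
         auc = auc, n_positive = n_pos, n_negative = n_neg),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Random-ranking ROC baseline
#'
#' AUC distribution obtained by ranking the universe pairs randomly
#' (permuting the scores), the null against which the co-expression ranking
#' is judged.
#'
#' @param is_gold logical vector over universe pairs (gold membership).
#' @param n_perm number of random rankings (default 100).
#' @param rng_seed seed for the permutations.
#' @return list with `mean`, `lower`, `upper` (central 95% interval) and
#'   `aucs` (all permutation AUCs).
#' @export
random_baseline <- function(is_gold, n_perm = 100, rng_seed = 1L) {
  stopifnot(n_perm >= 1)
  is_gold <- as.logical(is_gold)
  n <- length(is_gold)
  n_pos <- sum(is_gold)
  n_neg <- n - n_pos
  stopifnot(n_pos > 0, n_neg > 0)
  set.seed(rng_seed)
  aucs <- vapply(seq_len(n_perm), function(i) {
    # random distinct scores = a random total order of the pairs
    r <- sample.int(n)
    # AUC as the normalized U statistic of positive vs negative ranks
    (sum(r[is_gold]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }, numeric(1))
  qs <- rn_quantile(aucs, c(0.025, 0.975))
  list(mean = mean(aucs), lower = qs[1], upper = qs[2], aucs = aucs)
}

#' Score all gene pairs of a network's SCC matrix against a gold standard
#'
#' Convenience assembler for [roc_vs_gold()]: takes the full SCC matrix, a
#' universe of genes (default: network nodes), and a gold edge data.frame,
#' and returns the parallel score / membership vectors over all unordered
#' pairs of universe genes.
#'
#' @param scc symmetric SCC matrix with gene ids as dimnames.
#' @param gold data.frame with columns `gene_i`, `gene_j`.
#' @param genes character vector of universe genes (must index `scc`).
#' @return list with `scores`, `is_gold`, and `keys` (pair keys).
#' @export
pair_scores <- function(scc, gold, genes) {
  genes <- sort(unique(as.character(genes)))
  stopifnot(all(genes %in% rownames(scc)))
  sub <- scc[genes, genes, drop = FALSE]
  ut <- which(upper.tri(sub), arr.ind = TRUE)
  keys <- pair_key(genes[ut[, 1]], genes[ut[, 2]])
  scores <- sub[upper.tri(sub)]
  scores[is.na(scores)] <- 0 # undefined pairs rank last
  gold_keys <- pair_key(gold$gene_i, gold$gene_j)
  list(scores = scores, is_gold = keys %in% gold_keys, keys = keys)
}
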