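#' Capped, correlation-ranked neighbourhood of a network gene
#'
#' Neighbours of `gene` sorted by SCC descending (ties broken by gene id,
#' so truncation at the cap is deterministic) and truncated to the `cap`
#' most correlated. In unsigned networks the ranking uses |SCC|. The focal
#' gene never appears in its own neighbourhood.
#'
#' @param net a `coexpression_network`.
#' @param gene a node id.
#' @param cap maximum neighbourhood size (default 200).
#' @return character vector of neighbour gene ids, most correlated first.
#' @export
neighborhood <- function(net, gene, cap = 200) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!gene %in% net$nodes) stop("gene not in network: ", gene)
  e <- net$edges
  hit <- e$gene_i == gene | e$gene_j == gene
  nb <- ifelse(e$gene_i[hit] == gene, e$gene_j[hit], e$gene_i[hit])
  s <- e$scc[hit]
  if (!net$signed) s <- abs(s)
  ord <- order(-s, nb)
  nb <- nb[ord]
  utils::head(nb, cap)
}

#' One-sided Fisher's exact test for enrichment
#'
#' Hypergeometric upper tail P(X >= a) for a 2x2 table with cells a
#' (neighbourhood and seed), b (neighbourhood only), c (seed only), d
#' (rest of the universe), conditioning on the margins.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return p-value in (0, 1\].
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (monotone, clipped at 1); thin wrapper over
#' [stats::p.adjust()] so the adjustment used across the package is named
#' once.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Guilt-by-association neighbourhood enrichment
#'
#' For every gene in the network, tests whether its (capped) neighbourhood
#' is enriched for seed genes with a one-sided Fisher's exact test, then
#' controls the FDR over all tested genes by Benjamini-Hochberg. The focal
#' gene is excluded from both its neighbourhood and the universe of its own
#' test, so a seed gene cannot count itself as evidence. Candidates are the
#' genes with q below `alpha`; the candidate list may legitimately contain
#' seed genes (a seed recovered by its neighbours).
#'
#' @param net a `coexpression_network`.
#' @param seeds character vector of seed gene ids (intersected with the
#'   universe before testing; empty intersection is an error).
#' @param universe gene universe for the 2x2 tables; defaults to the network
#'   node set (only network genes have neighbourhoods).
#' @param cap neighbourhood cap (default 200).
#' @param alpha FDR level for candidate calls (default 0.05).
#' @return data.frame with one row per network gene, ranked by q then p then
#'   gene id: columns `gene_id`, `n_neighbors_used`, `n_seed_neighbors`,
#'   `p_value`, `q_value`, `is_candidate`, `rank`.
#' @export
neighbor_enrichment <- function(net, seeds, universe = NULL,
                                cap = 200, alpha = 0.05) {
  stopifnot(inherits(net, "coexpression_network"))
  if (is.null(universe)) universe <- net$nodes
  universe <- unique(as.character(universe))
  seeds <- intersect(as.character(seeds), universe)
  if (length(seeds) == 0) stop("no seed gene lies in the universe")

  n_u <- length(universe)
  res <- lapply(net$nodes, function(g) {
    nb <- intersect(neighborhood(net, g, cap), universe)
    a <- sum(nb %in% seeds)
    b <- length(nb) - a
    c <- length(setdiff(seeds, c(nb, g)))
    d <- (n_u - (g %in% universe)) - a - b - c
    data.frame(gene_id = g, n_neighbors_used = length(nb),
               n_seed_neighbors = a,
               p_value = fisher_exact_greater(a, b, c, d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_value <- bh_fdr(res$p_value)
  res$is_candidate <- res$q_value < alpha
  ord <- order(res$q_value, res$p_value, res$gene_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Candidate-seed overlap enrichment
#'
#' 2x2 association between candidate membership and seed membership over a
#' gene universe: sample odds ratio a*d / (b*c) (reported as `Inf` when the
#' off-diagonal product is zero and there is overlap, 0 when the overlap is
#' empty) with a one-sided Fisher p-value.
#'
#' @param candidates,seeds character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe the gene universe.
#' @return list with `odds_ratio`, `p_value` and `table` (2x2 matrix).
#' @export
overlap_enrichment <- function(candidates, seeds, universe) {
  universe <- unique(as.character(universe))
  candidates <- intersect(as.character(candidates), universe)
  seeds <- intersect(as.character(seeds), universe)
  a <- length(intersect(candidates, seeds))
  b <- length(setdiff(candidates, seeds))
  c <- length(setdiff(seeds, candidates))
  d <- length(universe) - a - b - c
  or <- if (a == 0) 0 else if (b * c == 0) Inf else (a * d) / (b * c)
  tab <- matrix(c(a, c, b, d), 2, 2,
                dimnames = list(candidate = c("yes", "no"),
                                seed = c("yes", "no")))
  list(odds_ratio = or, p_value = fisher_exact_greater(a, b, c, d),
       table = tab)
}
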