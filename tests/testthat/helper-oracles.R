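# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the library calls those paths use) so that each check
# compares two independent routes to the same quantity.

# Spearman: average-rank transform then the textbook Pearson formula.
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  n <- length(rx)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# One-sided Fisher: exhaustive hypergeometric enumeration over the support.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + c # seeds
  n <- b + d # non-seeds
  k <- a + b # draws
  support <- max(0, k - n):min(m, k)
  mass <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  sum(mass[support >= a])
}

# Longest ORF: enumerate every ATG, pair it with its first in-frame stop.
oracle_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  codon_at <- function(i) substr(s, i, i + 2)
  best <- NULL
  for (i in seq_len(max(0, n - 2))) {
    if (codon_at(i) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      if (codon_at(j) %in% c("TAA", "TAG", "TGA")) {
        len <- j + 3 - i
        if (is.null(best) || len > best$length_nt) {
          best <- list(start = i - 1L, length_nt = len,
                       protein_length = len / 3 - 1)
        }
        break
      }
      j <- j + 3
    }
  }
  best
}

# AUC: all positive x negative score comparisons, half credit for ties.
oracle_auc <- function(scores, is_gold) {
  s <- abs(scores)
  pos <- s[is_gold]
  neg <- s[!is_gold]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Small, fast synthetic dataset for unit tests.
tiny_dataset <- function(rng_seed = 11L, ...) {
  simulate_dataset(
    simulation_config(
      n_genes = 300, n_samples = 30, n_female = 12,
      module_specs = list(list(size = 30, loading_scale = 2)),
      seed_fraction = 0.3, rng_seed = rng_seed, ...),
    transcripts = FALSE)
}
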