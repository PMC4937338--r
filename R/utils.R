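#' Package-wide quantile convention
#'
#' All quantiles in the package (Tukey fences, upper-quartile reference
#' selection, length-stratum target distributions) use linear interpolation
#' between order statistics, i.e. [stats::quantile()] type 7. Centralised so
#' the convention is stated once and reused everywhere.
#'
#' @param x numeric vector.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles.
#' @keywords internal
rn_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

#' Canonical unordered gene-pair key
#'
#' Encodes an unordered gene pair as "a|b" with the two ids sorted, so edge
#' sets and score maps from different sources can be intersected.
#'
#' @param gene_i,gene_j character vectors of gene ids (recycled).
#' @return character vector of keys.
#' @export
pair_key <- function(gene_i, gene_j) {
  gene_i <- as.character(gene_i)
  gene_j <- as.character(gene_j)
  lo <- pmin(gene_i, gene_j)
  hi <- pmax(gene_i, gene_j)
  paste(lo, hi, sep = "|")
}

#' Number of unordered gene pairs
#'
#' @param n non-negative integer number of genes.
#' @return `n * (n - 1) / 2` as a double (exact for any realistic gene count).
#' @examples
#' count_gene_pairs(13792)
#' @export
count_gene_pairs <- function(n) {
  stopifnot(length(n) == 1, is.finite(n), n >= 0, n == floor(n))
  n <- as.double(n)
  n * (n - 1) / 2
}

#' Rounded percentage of a total
#'
#' Reporting helper: `100 * part / total` rounded to `digits`.
#'
#' @param part,total numeric scalars.
#' @param digits decimal places to keep (default 0, integer percent).
#' @return numeric scalar.
#' @export
pct_of <- function(part, total, digits = 0) {
  stopifnot(total > 0)
  round(100 * part / total, digits)
}

#' Per-base value from a per-bin coverage value
#'
#' Converts a reads-per-bin coverage figure to reads per base pair.
#'
#' @param bin_value coverage value per bin.
#' @param bin_size bin width in nucleotides (default 100).
#' @param digits rounding (default 0).
#' @return numeric scalar.
#' @export
coverage_per_bp <- function(bin_value, bin_size = 100, digits = 0) {
  round(bin_value / bin_size, digits)
}
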