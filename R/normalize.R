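#' Counts per million
#'
#' Scales each count by 10^6 over its sample's library size. Library sizes
#' default to the column sums of the matrix as given; when the matrix has
#' already been filtered, pass the original (pre-filter) sizes to keep the
#' CPM denominator equal to the total mapped reads.
#'
#' @param counts non-negative numeric gene x sample matrix with dimnames.
#' @param lib_size optional per-sample library sizes (positive), named or in
#'   column order. Defaults to `colSums(counts)`.
#' @return numeric matrix of CPM values, same shape as `counts`.
#' @export
cpm <- function(counts, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  lib_size <- check_lib_size(lib_size, counts)
  sweep(counts, 2, lib_size, "/") * 1e6
}

check_lib_size <- function(lib_size, counts) {
  if (!is.null(names(lib_size)) && !is.null(colnames(counts))) {
    stopifnot(all(colnames(counts) %in% names(lib_size)))
    lib_size <- lib_size[colnames(counts)]
  }
  if (length(lib_size) != ncol(counts)) {
    stop("lib_size must have one entry per sample")
  }
  if (any(lib_size <= 0)) stop("library sizes must be positive")
  lib_size
}

#' Filter genes expressed in every sample
#'
#' Keeps exactly the genes with CPM >= `min_cpm` in each sample (the boundary
#' is inclusive: a gene sitting at exactly `min_cpm` everywhere is retained).
#' The sample set is unchanged. The CPM denominator is the raw library size
#' (column sums of the unfiltered matrix, or `lib_size` when supplied), which
#' is where this filter sits in the pipeline: before any normalization.
#'
#' @inheritParams cpm
#' @param min_cpm expression floor in CPM units (default 1).
#' @return the filtered count matrix, with the library sizes used stored in
#'   `attr(, "lib_size")`.
#' @export
filter_expressed <- function(counts, min_cpm = 1, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  lib_size <- check_lib_size(lib_size, counts)
  keep <- rowSums(cpm(counts, lib_size) >= min_cpm) == ncol(counts)
  if (!any(keep)) warning("no gene passes the expression filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "lib_size") <- lib_size
  out
}

#' Length-stratified full-quantile within-sample normalization
#'
#' Corrects gene-specific (length-related) effects within each sample. Genes
#' are stratified into `n_bins` equal-size bins by gene-length rank; within
#' each sample the count distributions of the strata are full-quantile
#' normalized to a common target distribution, the mean of the strata's order
#' statistics (evaluated on a common probability grid by the package-wide
#' type-7 quantile convention when strata sizes differ). Within-stratum rank
#' order is preserved; tied counts stay tied.
#'
#' With `n_bins = 1` there is a single stratum normalized to itself and the
#' matrix is returned unchanged.
#'
#' @param counts non-negative numeric gene x sample matrix with rownames.
#' @param gene_length positive lengths in bp, named by gene id or in row
#'   order (one per gene).
#' @param n_bins number of length strata (default 10).
#' @return numeric matrix, same shape and dimnames as `counts`.
#' @export
within_sample_length_normalize <- function(counts, gene_length, n_bins = 10) {
  counts <- as.matrix(counts)
  n_genes <- nrow(counts)
  if (n_genes < n_bins) stop("fewer genes than length bins")
  if (!is.null(names(gene_length)) && !is.null(rownames(counts))) {
    stopifnot(all(rownames(counts) %in% names(gene_length)))
    gene_length <- gene_length[rownames(counts)]
  }
  stopifnot(length(gene_length) == n_genes, all(gene_length > 0))

  # equal-size strata by length rank; ties broken by row order (deterministic)
  ord <- order(gene_length)
  stratum <- integer(n_genes)
  stratum[ord] <- ceiling(seq_len(n_genes) / (n_genes / n_bins))
  stratum[stratum > n_bins] <- n_bins

  out <- counts
  grid_n <- max(tabulate(stratum, nbins = n_bins))
  probs <- if (grid_n == 1) 0.5 else seq(0, 1, length.out = grid_n)
  for (s in seq_len(ncol(counts))) {
    x <- counts[, s]
    # target distribution: mean of the strata's order statistics
    qmat <- vapply(seq_len(n_bins),
                   function(b) rn_quantile(x[stratum == b], probs),
                   numeric(grid_n))
    target <- rowMeans(qmat)
    for (b in seq_len(n_bins)) {
      idx <- which(stratum == b)
      nb <- length(idx)
      r <- rank(x[idx], ties.method = "average")
      p <- if (nb == 1) 0.5 else (r - 1) / (nb - 1)
      out[idx, s] <- stats::approx(probs, target, xout = p, rule = 2)$y
    }
  }
  out
}

#' TMM between-sample scaling factors
#'
#' Trimmed mean of M-values, as published: unless `ref_sample` is given, the
#' reference is the sample whose upper-quartile CPM is closest to the mean
#' upper-quartile; for each sample, per-gene log2 expression ratios (M) and
#' average log2 abundances (A) versus the reference are computed over genes
#' positive in both; the 30% extreme M and 5% extreme A values are trimmed
#' from each tail; the factor is 2 to the precision-weighted (inverse
#' asymptotic binomial variance) mean of the retained M values. Factors are
#' rescaled to geometric mean 1.
#'
#' @inheritParams cpm
#' @param ref_sample optional reference sample id or column index.
#' @param logratio_trim fraction of M values trimmed from each tail (0.30).
#' @param sum_trim fraction of A values trimmed from each tail (0.05).
#' @param do_weighting precision-weight the trimmed mean (default TRUE).
#' @return named per-sample positive scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, lib_size = NULL,
                        logratio_trim = 0.30, sum_trim = 0.05,
                        do_weighting = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  lib_size <- check_lib_size(lib_size, counts)

  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) rn_quantile(x / sum(x), 0.75))
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts)) else ref_sample
    if (is.na(ref) || ref < 1 || ref > ncol(counts)) stop("unknown reference sample")
  }

  f <- vapply(seq_len(ncol(counts)), function(s) {
    tmm_pair(counts[, s], counts[, ref], lib_size[s], lib_size[ref],
             logratio_trim, sum_trim, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# one-sample-vs-reference TMM factor (Robinson & Oshlack weighted trimmed mean)
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim, sum_trim, do_weighting) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) stop("sample shares no positive gene with the reference")
  obs <- obs[pos]
  ref <- ref[pos]

  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)

  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  w <- if (do_weighting) 1 / v[keep] else rep(1, sum(keep))
  f <- sum(w * m[keep], na.rm = TRUE) / sum(w, na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Filtered-to-normalized expression pipeline step
#'
#' Composes the within-sample length normalization with TMM between-sample
#' scaling: each column is divided by its TMM-adjusted effective library size
#' (`lib_size * factor / 1e6`), putting values on a CPM-like scale. Set
#' `within = FALSE` to skip the length step and obtain TMM-only scaling —
#' the variant the co-expression network uses, since rank correlations are
#' unaffected by within-sample (gene-wise) transforms.
#'
#' @inheritParams within_sample_length_normalize
#' @inheritParams cpm
#' @param within apply the length-stratified step first (default TRUE).
#' @param ... passed on to [tmm_factors()].
#' @return numeric matrix of normalized expression; the steps applied are
#'   recorded in `attr(, "provenance")` and the factors in `attr(, "tmm")`.
#' @export
normalize_counts <- function(counts, gene_length = NULL, n_bins = 10,
                             lib_size = NULL, within = TRUE, ...) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) {
    lib_size <- attr(counts, "lib_size")
    if (is.null(lib_size)) lib_size <- colSums(counts)
  }
  lib_size <- check_lib_size(lib_size, counts)

  prov <- character(0)
  x <- counts
  if (within) {
    if (is.null(gene_length)) stop("gene_length needed for within-sample normalization")
    x <- within_sample_length_normalize(x, gene_length, n_bins)
    prov <- c(prov, sprintf("within:full-quantile length strata (n_bins=%d)", n_bins))
  }
  f <- tmm_factors(counts, lib_size = lib_size, ...)
  eff <- lib_size * f / 1e6
  x <- sweep(x, 2, eff, "/")
  prov <- c(prov, "between:TMM effective library size (CPM-like scale)")
  attr(x, "provenance") <- prov
  attr(x, "tmm") <- f
  x
}

#' Per-gene median normalized expression
#'
#' @param norm numeric gene x sample matrix.
#' @return named numeric vector of per-gene medians across samples (even
#'   sample counts average the central pair).
#' @export
median_expression <- function(norm) {
  stopifnot(ncol(norm) >= 1)
  apply(as.matrix(norm), 1, stats::median)
}

#' Per-gene coefficient of variation
#'
#' Sample standard deviation over mean, per gene. Genes with zero mean have
#' an undefined CV and are returned as `NA` with a warning.
#'
#' @param norm numeric gene x sample matrix.
#' @return named numeric vector of CVs.
#' @export
coefficient_of_variation <- function(norm) {
  norm <- as.matrix(norm)
  mu <- rowMeans(norm)
  s <- apply(norm, 1, stats::sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  if (anyNA(cv)) warning("CV undefined for zero-mean genes (returned NA)")
  names(cv) <- rownames(norm)
  cv
}

#' Per-gene expression summary table
#'
#' Median normalized expression, coefficient of variation and expression
#' rank (1 = most expressed) for every gene of a normalized matrix.
#'
#' @param norm numeric gene x sample matrix.
#' @return data.frame with columns `gene_id`, `median`, `cv`, `rank`.
#' @export
gene_summary <- function(norm) {
  med <- median_expression(norm)
  cv <- suppressWarnings(coefficient_of_variation(norm))
  data.frame(
    gene_id = rownames(norm),
    median = unname(med),
    cv = unname(cv),
    rank = rank(-med, ties.method = "min"),
    stringsAsFactors = FALSE
  )
}
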