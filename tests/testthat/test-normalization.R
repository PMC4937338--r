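test_that("cpm matches its definition", {
  counts <- matrix(c(1, 0, 250, 10), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- cpm(counts, lib_size = c(s1 = 1e6, s2 = 5e7))
  expect_equal(out["g1", "s1"], 1.0)
  expect_equal(out["g2", "s1"], 0.0)
  expect_equal(out["g1", "s2"], 5.0)
  expect_error(cpm(counts, lib_size = c(0, 1e6)), "positive")
})

test_that("expression filter keeps >= min_cpm in every sample, inclusively", {
  lib <- c(a = 2e6, b = 4e6)
  counts <- rbind(
    at_boundary = c(2, 4),     # exactly 1 CPM in both samples
    zero_somewhere = c(0, 400),
    high = c(100, 200))
  colnames(counts) <- names(lib)
  kept <- filter_expressed(counts, min_cpm = 1, lib_size = lib)
  expect_setequal(rownames(kept), c("at_boundary", "high"))
  expect_identical(ncol(kept), 2L)
  # idempotent (lib sizes carried through)
  again <- filter_expressed(kept, lib_size = attr(kept, "lib_size"))
  expect_equal(rownames(again), rownames(kept))
  # identity when everything passes
  all_pass <- filter_expressed(counts[3, , drop = FALSE], lib_size = lib)
  expect_equal(unclass(all_pass)[, ], counts[3, ])
  expect_warning(filter_expressed(counts, min_cpm = 1e9, lib_size = lib),
                 "no gene")
})

test_that("length-stratified full-quantile maps strata to mean order statistics", {
  counts <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 1,
                   dimnames = list(paste0("g", 1:6), "s1"))
  len <- c(g1 = 100, g2 = 110, g3 = 120, g4 = 5000, g5 = 6000, g6 = 7000)
  out <- within_sample_length_normalize(counts, len, n_bins = 2)
  expect_equal(unname(out[, 1]), c(5.5, 11, 16.5, 5.5, 11, 16.5))

  # n_bins = 1 is the identity
  x <- matrix(c(5, 1, 1, 9, 2, 7), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(within_sample_length_normalize(x, c(100, 200, 300), n_bins = 1), x)

  # identical count multisets across strata are unchanged
  y <- matrix(c(1, 2, 3, 3, 1, 2), ncol = 1,
              dimnames = list(paste0("g", 1:6), "s1"))
  out2 <- within_sample_length_normalize(y, len, n_bins = 2)
  expect_equal(unname(out2[, 1]), unname(y[, 1]))

  expect_error(within_sample_length_normalize(y, len, n_bins = 10), "fewer genes")
})

test_that("length normalization preserves within-stratum rank order", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 60
    counts <- matrix(rnbinom(n * 3, mu = 50, size = 2), n, 3,
                     dimnames = list(sprintf("g%02d", 1:n), c("a", "b", "c")))
    len <- setNames(sample(100:10000, n), rownames(counts))
    out <- within_sample_length_normalize(counts, len, n_bins = 4)
    ord <- order(len)
    stratum <- integer(n); stratum[ord] <- rep(1:4, each = 15)
    for (s in 1:3) for (b in 1:4) {
      idx <- stratum == b
      expect_equal(rank(out[idx, s], ties.method = "average"),
                   rank(counts[idx, s], ties.method = "average"))
    }
  }
})

test_that("TMM factors behave as published", {
  set.seed(7)
  m <- matrix(rnbinom(400, mu = 100, size = 5), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  m <- m[rowSums(m == 0) == 0, ]

  # identical samples -> all factors 1
  ident <- m[, c(1, 1, 1)]
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(unname(tmm_factors(ident)), rep(1, 3))

  # doubling every count is a pure depth change: normalized columns match
  doubled <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
  f <- tmm_factors(doubled)
  norm <- sweep(doubled, 2, colSums(doubled) * f / 1e6, "/")
  expect_lt(max(abs(norm[, 1] - norm[, 2]) / norm[, 1]), 0.01)

  # geometric mean 1 by construction
  expect_equal(exp(mean(log(tmm_factors(m)))), 1, tolerance = 1e-12)
})

test_that("TMM matches the independent edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  for (rep in 1:6) {
    m <- matrix(rnbinom(500, mu = runif(50, 5, 500), size = 5), 50, 10)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))), sprintf("s%02d", 1:10))
    f_edger <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
    expect_equal(unname(tmm_factors(m)), f_edger, tolerance = 1e-10)
  }
})

test_that("normalize_counts composes the steps and records provenance", {
  set.seed(9)
  base <- rnbinom(80, mu = 200, size = 5) + 1
  counts <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(counts) <- sprintf("g%02d", 1:80)
  len <- setNames(sample(200:5000, 80), rownames(counts))

  norm <- normalize_counts(counts, gene_length = len, n_bins = 4)
  expect_equal(norm[, 1], norm[, 2]) # identical samples stay identical
  expect_true(all(norm >= 0))
  expect_length(attr(norm, "provenance"), 2)

  # skipping the within step reproduces pure TMM scaling
  tmm_only <- normalize_counts(counts, within = FALSE)
  f <- tmm_factors(counts)
  expect_equal(tmm_only[, 1],
               counts[, 1] / (colSums(counts)[1] * f[1] / 1e6),
               ignore_attr = TRUE)
  expect_error(normalize_counts(counts, within = TRUE), "gene_length")
})

test_that("depth-varied copies of one sample renormalize to near-identical columns", {
  set.seed(31)
  x <- rnbinom(300, mu = 150, size = 8) + 1
  counts <- cbind(s1 = x, s2 = round(1.7 * x), s3 = round(3 * x), s4 = round(0.5 * x))
  rownames(counts) <- sprintf("g%03d", seq_along(x))
  norm <- normalize_counts(counts, within = FALSE)
  cors <- cor(norm)
  expect_true(all(cors[upper.tri(cors)] > 0.999))
})

test_that("median expression and CV follow their definitions", {
  m <- rbind(odd = c(1, 2, 3), spread = c(1, 2, 3))
  expect_equal(unname(median_expression(m)), c(2, 2))
  m4 <- rbind(a = c(1, 2, 3, 10), b = c(7, 7, 7, 7))
  expect_equal(unname(median_expression(m4)), c(2.5, 7))

  cvm <- rbind(const = c(4, 4), zero2 = c(0, 2))
  expect_equal(unname(coefficient_of_variation(cvm)), c(0, sqrt(2)))
  # scale invariance
  expect_equal(coefficient_of_variation(cvm * 13),
               coefficient_of_variation(cvm))
  expect_warning(cv0 <- coefficient_of_variation(rbind(z = c(0, 0))), "zero-mean")
  expect_true(is.na(cv0))

  gs <- gene_summary(m4)
  expect_equal(gs$rank[gs$gene_id == "b"], 1L)
})
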