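make_presence <- function(pattern, sex) {
  # pattern: named logical matrix transcript x sample
  df <- expand.grid(transcript_id = rownames(pattern),
                    sample_id = colnames(pattern),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$ci_low <- ifelse(pattern[cbind(df$transcript_id, df$sample_id)], 0.5, 0)
  df$ci_high <- df$ci_low + 1
  df
}

test_that("ensemble filter requires a strict majority in both sexes", {
  sex <- setNames(c(rep("F", 18), rep("M", 32)), sprintf("S%02d", 1:50))
  pat <- matrix(FALSE, 3, 50,
                dimnames = list(c("both_majorities", "female_at_half", "everywhere"),
                                names(sex)))
  pat["both_majorities", c(1:10, 19:35)] <- TRUE   # 10/18 F, 17/32 M
  pat["female_at_half", c(1:9, 19:50)] <- TRUE     # 9/18 F (exactly 50%), 32/32 M
  pat["everywhere", ] <- TRUE
  kept <- ensemble_filter(make_presence(pat, sex), sex)
  expect_setequal(kept, c("both_majorities", "everywhere"))

  expect_error(ensemble_filter(make_presence(pat, sex),
                               setNames(rep("M", 50), names(sex))),
               "both sexes")
})

test_that("ensemble filter matches truth-table enumeration on a 4F/4M toy", {
  sex <- setNames(c(rep("F", 4), rep("M", 4)), paste0("s", 1:8))
  for (code in 0:255) {
    present <- as.logical(bitwAnd(bitwShiftR(code, 0:7), 1L))
    pat <- matrix(present, 1, 8, dimnames = list("t", names(sex)))
    kept <- ensemble_filter(make_presence(pat, sex), sex)
    manual <- sum(present[1:4]) > 2 && sum(present[5:8]) > 2
    expect_identical(length(kept) == 1, manual)
  }
})

test_that("junction-chain classification is exhaustive and strand-aware", {
  ref <- data.frame(
    transcript_id = rep("R1", 3), gene_id = "G1", chromosome = "chr1",
    strand = "+", start = c(100, 500, 900), end = c(200, 600, 1000))
  mono_ref <- data.frame(transcript_id = "R2", gene_id = "G2",
                         chromosome = "chr1", strand = "+",
                         start = 5000, end = 5600)
  reference <- rbind(ref, mono_ref)

  exact <- transform(ref, transcript_id = "T1")
  first_junction_only <- transform(ref, transcript_id = "T2",
                                   start = c(100, 500, 930),
                                   end = c(200, 600, 1030))
  opposite <- transform(ref, transcript_id = "T3", strand = "-")
  disjoint <- data.frame(transcript_id = rep("T4", 2), gene_id = "G",
                         chromosome = "chr1", strand = "+",
                         start = c(7000, 7500), end = c(7100, 7600))
  mono_exact <- transform(mono_ref, transcript_id = "T5")
  mono_partial <- transform(mono_ref, transcript_id = "T6",
                            start = 5300, end = 5900)
  mono_away <- transform(mono_ref, transcript_id = "T7",
                         start = 8000, end = 8400)
  obs <- rbind(exact, first_junction_only, opposite, disjoint,
               mono_exact, mono_partial, mono_away)
  cls <- classify_vs_reference(obs, reference)
  got <- setNames(cls$class, cls$transcript_id)
  expect_equal(unname(got[paste0("T", 1:7)]),
               c("exact_junction_match", "shared_junction", "novel", "novel",
                 "exact_overlap", "partial_overlap", "no_overlap"))

  # self-consistency: every transcript is exact against a set containing it
  self <- classify_vs_reference(reference, reference)
  expect_setequal(self$class, c("exact_junction_match", "exact_overlap"))
})

test_that("longest ORF follows the first-in-frame-stop rule", {
  expect_equal(longest_orf("ATGAAATAA"),
               list(start = 0L, length_nt = 9L, protein_length = 2L))
  # the later, longer ORF beats the earlier, shorter one
  expect_equal(longest_orf("CCATGTAACATGAAAAAATGA")[c("start", "length_nt")],
               list(start = 9L, length_nt = 12L))
  expect_null(longest_orf("AAACCC"))
  expect_null(longest_orf("ATGAAACCC")) # start but no in-frame stop
  expect_equal(longest_orf("atgtaa")$length_nt, 6L) # case-insensitive
})

test_that("longest ORF agrees with the all-pairs oracle on random sequences", {
  set.seed(71)
  for (rep in 1:1000) {
    n <- sample(10:300, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    got <- longest_orf(s)
    want <- oracle_orf(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$length_nt, want$length_nt, info = s)
      expect_equal(got$start, want$start, info = s)
    }
  }
})

test_that("coverage binning applies the overlap and floor rules", {
  reads <- list(
    s1 = data.frame(chromosome = "chr1",
                    start = c(rep(10, 60), 95), end = c(rep(90, 60), 130)),
    s2 = data.frame(chromosome = "chr1",
                    start = rep(120, 60), end = rep(180, 60)))
  totals <- c(s1 = 1e7, s2 = 1e7)
  track <- bin_coverage(reads, totals, bin_size = 100, read_floor = 100)
  # bin 1 (0-100): 61 reads in s1 only -> below floor of 100 -> 0
  expect_equal(track$value[1], 0)
  # bin 2 (100-200): spanning read (95-130) counts in both bins;
  # 1 + 60 = 61 in s2... plus the spanning read in s1
  cnt <- attr(track, "counts")$chr1
  expect_equal(unname(cnt[, 2]), c(1, 60)) # spanning read hits bin 2 too
  expect_equal(unname(cnt["s1", 1]), 61)

  # floor boundary: exactly 100 summed reads keeps its value
  reads2 <- list(s1 = data.frame(chromosome = "c", start = rep(0, 40), end = rep(50, 40)),
                 s2 = data.frame(chromosome = "c", start = rep(0, 60), end = rep(50, 60)))
  t2 <- bin_coverage(reads2, c(s1 = 1e7, s2 = 2e7), read_floor = 100)
  expect_equal(t2$value[1], mean(c(40 / 1e7, 60 / 2e7)))
  # at 99 summed reads the bin is silenced
  reads3 <- list(s1 = data.frame(chromosome = "c", start = rep(0, 99), end = rep(50, 99)))
  expect_equal(bin_coverage(reads3, c(s1 = 1e7), read_floor = 100)$value[1], 0)

  expect_error(bin_coverage(list(s1 = data.frame(chromosome = "c", start = 5, end = 5)),
                            c(s1 = 10)), "end > start")
})

test_that("above-floor bins reconstruct per-sample read counts exactly", {
  set.seed(73)
  reads <- lapply(1:4, function(s) {
    st <- sample(0:2000, 400, replace = TRUE)
    data.frame(chromosome = "chrZ", start = st,
               end = st + sample(30:150, 400, replace = TRUE))
  })
  names(reads) <- paste0("s", 1:4)
  totals <- setNames(rep(5e6, 4), names(reads))
  track <- bin_coverage(reads, totals, read_floor = 20)
  cnt <- attr(track, "counts")$chrZ
  above <- colSums(cnt) >= 20
  # value * n_samples * total reconstructs the summed count when totals equal
  expect_equal(track$value[above] * 4 * 5e6, colSums(cnt)[above],
               ignore_attr = TRUE)
})

test_that("single/multi-exon composition and printed-scale summaries", {
  tx <- data.frame(transcript_id = c("a", "b", "b", "c", "c", "c"))
  out <- single_exon_fraction(tx)
  expect_equal(out$n_single, 1)
  expect_equal(out$n_multi, 2)

  both <- single_exon_summary(1, 2)
  expect_equal(both$pct_single, 50)
  expect_equal(both$pct_multi, 50)
  all_single <- single_exon_summary(5, 5)
  expect_equal(all_single$pct_single, 100)
  expect_equal(all_single$pct_multi, 0)
})
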