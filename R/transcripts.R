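#' Ensemble presence filter across sexed samples
#'
#' A transcript counts as present in a sample when the lower bound of its
#' expression confidence interval is strictly above 0. A transcript is
#' retained when it is present in strictly more than 50% of the female
#' samples AND strictly more than 50% of the male samples (equivalently:
#' removed when its confidence interval includes 0 in at least half of
#' either sex's samples).
#'
#' @param presence data.frame with columns `transcript_id`, `sample_id`,
#'   `ci_low`, `ci_high` (ci_low <= ci_high; absent rows count as absent).
#' @param sample_sex named character vector mapping sample id to "F"/"M";
#'   both sexes must be represented.
#' @return character vector of retained transcript ids.
#' @export
ensemble_filter <- function(presence, sample_sex) {
  stopifnot(all(c("transcript_id", "sample_id", "ci_low") %in%
                  names(presence)))
  if (!is.null(presence$ci_high) &&
      any(presence$ci_high < presence$ci_low)) {
    stop("ci_high must be >= ci_low")
  }
  n_f <- sum(sample_sex == "F")
  n_m <- sum(sample_sex == "M")
  if (n_f == 0 || n_m == 0) stop("both sexes must have at least one sample")
  stopifnot(all(presence$sample_id %in% names(sample_sex)))

  pres <- presence[presence$ci_low > 0, , drop = FALSE]
  sex <- sample_sex[pres$sample_id]
  tab <- table(factor(pres$transcript_id,
                      levels = unique(presence$transcript_id)),
               factor(sex, levels = c("F", "M")))
  keep <- tab[, "F"] > n_f / 2 & tab[, "M"] > n_m / 2
  rownames(tab)[keep]
}

# ordered junction chain per transcript: "end-start" strings, genomic order
junction_chains <- function(exons) {
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  lapply(split(exons, exons$transcript_id, drop = TRUE), function(e) {
    n <- nrow(e)
    if (any(e$end[-n] > e$start[-1])) stop("overlapping exons in ",
                                           e$transcript_id[1])
    if (n == 1) return(character(0))
    paste0(e$end[-n], "-", e$start[-1])
  })
}

#' Classify observed transcripts against a reference annotation
#'
#' Multi-exonic transcripts: `exact_junction_match` when a reference
#' transcript on the same chromosome and strand has the identical ordered
#' junction chain; otherwise `shared_junction` when at least one junction
#' coincides exactly (same chromosome/strand, exact coordinates, no fuzz);
#' otherwise `novel`. Mono-exonic transcripts: `exact_overlap` when an
#' identical exon interval exists in the reference on the same chromosome
#' and strand; `partial_overlap` when the exon overlaps any reference exon
#' on the same chromosome by at least 1 bp (strand ignored, as single-exon
#' fragments carry no splice-based strand evidence); otherwise `no_overlap`.
#'
#' @param observed,reference exon data.frames with columns `transcript_id`,
#'   `chromosome`, `strand`, `start`, `end` (0-based half-open, exons of a
#'   transcript disjoint).
#' @return data.frame `transcript_id`, `n_exons`, `class`.
#' @export
classify_vs_reference <- function(observed, reference) {
  obs_chain <- junction_chains(observed)
  ref_chain <- junction_chains(reference)
  meta <- function(exons) {
    first <- exons[!duplicated(exons$transcript_id), ]
    stats::setNames(paste(first$chromosome, first$strand), first$transcript_id)
  }
  obs_loc <- meta(observed)
  ref_loc <- meta(reference)

  # exact chains and individual junctions, keyed by chrom/strand
  ref_multi <- names(ref_chain)[lengths(ref_chain) > 0]
  chain_sig <- paste(ref_loc[ref_multi],
                     vapply(ref_chain[ref_multi], paste, character(1),
                            collapse = ","))
  junc_sig <- unlist(lapply(ref_multi, function(t) {
    paste(ref_loc[t], ref_chain[[t]])
  }), use.names = FALSE)

  # reference exon intervals for the mono-exonic comparisons
  ref_ex <- reference
  ref_exact_mono <- unique(paste(ref_ex$chromosome, ref_ex$strand,
                                 ref_ex$start, ref_ex$end))

  out <- lapply(names(obs_chain), function(t) {
    ch <- obs_chain[[t]]
    loc <- obs_loc[t]
    if (length(ch) > 0) {
      cls <- if (paste(loc, paste(ch, collapse = ",")) %in% chain_sig) {
        "exact_junction_match"
      } else if (any(paste(loc, ch) %in% junc_sig)) {
        "shared_junction"
      } else "novel"
    } else {
      e <- observed[observed$transcript_id == t, ]
      same_chr <- ref_ex[ref_ex$chromosome == e$chromosome, , drop = FALSE]
      cls <- if (paste(e$chromosome, e$strand, e$start, e$end) %in%
                   ref_exact_mono) {
        "exact_overlap"
      } else if (any(same_chr$start < e$end & same_chr$end > e$start)) {
        "partial_overlap"
      } else "no_overlap"
    }
    data.frame(transcript_id = t, n_exons = length(ch) + 1L, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Longest complete open reading frame of a transcript sequence
#'
#' Scans the given (sense) strand in all three frames for ATG-initiated
#' reading frames terminated by the first in-frame stop codon (TAA, TAG or
#' TGA) fully inside the sequence, and returns the longest by nucleotide
#' length (stop codon included). Ties go to the smallest start offset.
#'
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive).
#' @return list with `start` (0-based offset), `length_nt` (including the
#'   stop codon) and `protein_length` (codons before the stop), or `NULL`
#'   when no complete ORF exists.
#' @export
longest_orf <- function(sequence) {
  s <- toupper(sequence)
  starts <- as.integer(gregexpr("ATG", s, fixed = TRUE)[[1]])
  if (length(starts) == 1 && starts[1] == -1) return(NULL)
  stops <- sort(unlist(lapply(c("TAA", "TAG", "TGA"), function(p) {
    h <- as.integer(gregexpr(p, s, fixed = TRUE)[[1]])
    h[h > 0]
  })))
  if (length(stops) == 0) return(NULL)

  best_len <- 0L
  best_start <- NA_integer_
  for (f in 0:2) {
    st <- starts[(starts - 1) %% 3 == f]
    sp <- stops[(stops - 1) %% 3 == f]
    if (length(st) == 0 || length(sp) == 0) next
    # first in-frame stop at or after start + 3
    j <- findInterval(st + 3 - 1e-9, sp) + 1L
    ok <- j <= length(sp)
    len <- sp[j[ok]] + 3L - st[ok]
    for (i in seq_along(len)) {
      if (len[i] > best_len ||
          (len[i] == best_len && st[ok][i] < best_start)) {
        best_len <- len[i]
        best_start <- st[ok][i]
      }
    }
  }
  if (best_len == 0L) return(NULL)
  list(start = best_start - 1L, length_nt = best_len,
       protein_length = best_len / 3L - 1L)
}

#' Binned average-coverage track
#'
#' Divides each chromosome into fixed-width bins from coordinate 0. A read
#' counts in every bin it overlaps by at least 1 bp. Bins whose summed read
#' count across all samples is below `floor` are treated as not expressed
#' (value 0); the remaining bins get the mean over samples of
#' (reads in bin / total aligned reads of the sample).
#'
#' @param reads per-sample list of data.frames with columns `chromosome`,
#'   `start`, `end` (0-based half-open; `end > start`).
#' @param totals per-sample total aligned read counts (positive), parallel
#'   to `reads`.
#' @param bin_size bin width in nucleotides (default 100).
#' @param read_floor minimum summed read count for a bin to be expressed
#'   (default 100; bins at exactly the floor get a value).
#' @return data.frame `chromosome`, `bin_start`, `bin_end`, `value`, plus
#'   attribute `counts`: per-chromosome sample x bin count matrices.
#' @export
bin_coverage <- function(reads, totals, bin_size = 100, read_floor = 100) {
  stopifnot(length(reads) == length(totals), all(totals > 0))
  all_reads <- do.call(rbind, reads)
  if (any(all_reads$end <= all_reads$start)) {
    stop("read intervals must satisfy end > start")
  }
  chroms <- sort(unique(all_reads$chromosome))
  n_s <- length(reads)

  out <- list()
  count_mats <- list()
  for (ch in chroms) {
    n_bins <- ceiling(max(all_reads$end[all_reads$chromosome == ch]) /
                        bin_size)
    cnt <- matrix(0, n_s, n_bins, dimnames = list(names(reads), NULL))
    for (s in seq_len(n_s)) {
      r <- reads[[s]]
      r <- r[r$chromosome == ch, , drop = FALSE]
      if (nrow(r) == 0) next
      first <- r$start %/% bin_size
      last <- (r$end - 1L) %/% bin_size
      idx <- unlist(mapply(seq.int, first, last, SIMPLIFY = FALSE)) + 1L
      cnt[s, ] <- tabulate(idx, nbins = n_bins)
    }
    total_per_bin <- colSums(cnt)
    value <- colMeans(cnt / totals)
    value[total_per_bin < read_floor] <- 0
    out[[ch]] <- data.frame(
      chromosome = ch,
      bin_start = (seq_len(n_bins) - 1L) * bin_size,
      bin_end = seq_len(n_bins) * bin_size,
      value = value, stringsAsFactors = FALSE)
    count_mats[[ch]] <- cnt
  }
  track <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(track, "counts") <- count_mats
  track
}

#' Single- versus multi-exon transcript composition
#'
#' @param transcripts exon data.frame (`transcript_id`, one row per exon),
#'   or alternatively use [single_exon_summary()] with precomputed counts.
#' @return list `n_single`, `n_multi`, `pct_single`, `pct_multi`
#'   (percentages rounded to the integer for reporting).
#' @export
single_exon_fraction <- function(transcripts) {
  stopifnot(nrow(transcripts) > 0)
  ex_per_tx <- table(transcripts$transcript_id)
  single_exon_summary(sum(ex_per_tx == 1), length(ex_per_tx))
}

#' @rdname single_exon_fraction
#' @param n_single,n_total transcript counts.
#' @export
single_exon_summary <- function(n_single, n_total) {
  stopifnot(n_total > 0, n_single >= 0, n_single <= n_total)
  list(n_single = n_single, n_multi = n_total - n_single,
       pct_single = pct_of(n_single, n_total),
       pct_multi = pct_of(n_total - n_single, n_total))
}
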