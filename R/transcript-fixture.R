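#' Toy transcript fixture: references, derived variants, presence, reads
#'
#' Emulates the inputs of the transcript-level utilities on one small
#' contig. A set of reference transcripts (alternating multi- and
#' mono-exonic, alternating strand) is laid out in disjoint 10 kb blocks;
#' from each reference three observed variants are derived:
#' \describe{
#'   \item{exact}{a copy with the identical exon chain;}
#'   \item{shared}{(multi-exonic references) keeps the first junction and
#'     shifts the remaining exon starts, or (mono-exonic) shifts the exon so
#'     it still overlaps partially;}
#'   \item{novel}{placed in a disjoint region of the contig, sharing no
#'     junction (and no overlap) with any reference.}
#' }
#' Each observed transcript gets a random nucleotide sequence of its spliced
#' length, a per-sample expression 95% confidence interval whose lower bound
#' is 0 with probability `ci_zero_fraction`, and per-sample read intervals
#' over the reference exons for coverage binning.
#'
#' @param config a [simulation_config()]; uses `n_ref_transcripts`,
#'   `n_samples`, `n_female`, `ci_zero_fraction` and the seed.
#' @return list with `reference` and `observed` exon tables (data.frames
#'   `transcript_id`, `gene_id`, `chromosome`, `strand`, `start`, `end`;
#'   0-based half-open), `variant_class` (named vector over observed
#'   transcripts), `sequences` (named character), `presence` (data.frame
#'   `transcript_id`, `sample_id`, `ci_low`, `ci_high`), `sample_sex`,
#'   `reads` (per-sample list of interval data.frames) and `read_totals`.
#' @export
generate_transcript_fixture <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config, 6L))
  n_ref <- config$n_ref_transcripts
  n_s <- config$n_samples
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  sex <- stats::setNames(
    c(rep("F", config$n_female), rep("M", n_s - config$n_female)),
    sample_ids)
  chrom <- "chrT"
  block <- 10000L

  ref <- list(); obs <- list(); cls <- character(0)
  for (i in seq_len(n_ref)) {
    off <- (i - 1L) * block
    strand <- if (i %% 2 == 0) "-" else "+"
    multi <- i %% 3 != 0 # every third reference is mono-exonic
    rid <- sprintf("ref%02d", i)
    if (multi) {
      n_ex <- 3L + (i %% 2)
      starts <- off + cumsum(c(100L, rep(500L, n_ex - 1L)))
      widths <- 150L + 30L * seq_len(n_ex)
      ex <- data.frame(start = starts, end = starts + widths)
    } else {
      ex <- data.frame(start = off + 100L, end = off + 700L)
    }
    ref[[rid]] <- cbind(transcript_id = rid, gene_id = sprintf("rgene%02d", i),
                        chromosome = chrom, strand = strand, ex,
                        stringsAsFactors = FALSE)

    # exact copy
    oid <- sprintf("obs%02d_exact", i)
    obs[[oid]] <- transform(ref[[rid]], transcript_id = oid,
                            gene_id = sprintf("ogene%02d", i))
    cls[oid] <- "exact"

    # shared-junction (multi) / partial-overlap (mono) variant
    oid <- sprintf("obs%02d_shared", i)
    v <- ref[[rid]]
    if (multi) {
      # keep exon 1-2 (first junction); shift later exon starts by 37 bp
      later <- seq(3, nrow(v))
      v$start[later] <- v$start[later] + 37L
      v$end[later] <- v$end[later] + 37L
    } else {
      half <- floor((v$end - v$start) / 2)
      v$start <- v$start + half
      v$end <- v$end + half
    }
    v$transcript_id <- oid
    v$gene_id <- sprintf("ogene%02d", i)
    obs[[oid]] <- v
    cls[oid] <- if (multi) "shared" else "partial"

    # novel variant: disjoint region beyond all reference blocks
    oid <- sprintf("obs%02d_novel", i)
    noff <- (n_ref + i) * block
    if (multi) {
      starts <- noff + cumsum(c(200L, 600L, 600L))
      nv <- data.frame(start = starts, end = starts + 180L)
    } else {
      nv <- data.frame(start = noff + 200L, end = noff + 800L)
    }
    obs[[oid]] <- cbind(transcript_id = oid, gene_id = sprintf("ngene%02d", i),
                        chromosome = chrom, strand = strand, nv,
                        stringsAsFactors = FALSE)
    cls[oid] <- "novel"
  }
  reference <- do.call(rbind, c(ref, list(make.row.names = FALSE)))
  observed <- do.call(rbind, c(obs, list(make.row.names = FALSE)))

  # spliced sequences for the observed transcripts
  splen <- tapply(observed$end - observed$start, observed$transcript_id, sum)
  sequences <- vapply(splen, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))

  # presence table: ci_low = 0 with probability ci_zero_fraction
  tids <- unique(observed$transcript_id)
  grid <- expand.grid(transcript_id = tids, sample_id = sample_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  zero <- stats::runif(nrow(grid)) < config$ci_zero_fraction
  ci_low <- ifelse(zero, 0, stats::runif(nrow(grid), 0.1, 5))
  presence <- data.frame(grid, ci_low = ci_low,
                         ci_high = ci_low + stats::runif(nrow(grid), 0.1, 2))

  # per-sample reads over the reference exons (fixed length 100)
  reads <- lapply(sample_ids, function(s) {
    n_reads <- 150L + sample.int(100L, 1)
    ex <- reference[sample.int(nrow(reference), n_reads, replace = TRUE), ]
    pos <- ex$start + floor(stats::runif(n_reads) *
                              pmax(1, ex$end - ex$start - 100L))
    data.frame(chromosome = ex$chromosome, start = pos, end = pos + 100L,
               stringsAsFactors = FALSE)
  })
  names(reads) <- sample_ids
  read_totals <- stats::setNames(rep(1e6, n_s), sample_ids)

  list(reference = reference, observed = observed, variant_class = cls,
       sequences = sequences, presence = presence, sample_sex = sex,
       reads = reads, read_totals = read_totals)
}
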