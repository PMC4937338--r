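#' Tabular readers and writers for the pipeline's plain-text formats
#'
#' Counts are written genes-in-rows with a `gene_id` column and one column
#' per sample; annotation as `gene_id`/`length_bp`/`chromosome`; seed lists
#' one gene per line; edge lists as 2- or 3-column TSV. All TSVs are
#' tab-separated with a header row and no quoting.
#'
#' @param counts gene x sample matrix.
#' @param path file path.
#' @name tabular_io
NULL

#' @rdname tabular_io
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname tabular_io
#' @param annotation data.frame `gene_id`, `length_bp`, `chromosome`.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname tabular_io
#' @param genes character vector of gene ids.
#' @export
write_seed_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_seed_list <- function(path) {
  readLines(path)
}

#' @rdname tabular_io
#' @param edges data.frame with `gene_i`, `gene_j` (and optionally `scc`).
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_edges_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Transcript models to/from GTF
#'
#' Internally exons are 0-based half-open; GTF is 1-based inclusive, and the
#' conversion happens here (via `rtracklayer`, which uses 1-based `GRanges`).
#'
#' @param exons exon data.frame (`transcript_id`, `gene_id`, `chromosome`,
#'   `strand`, `start`, `end`; 0-based half-open).
#' @param path file path.
#' @return `read_transcripts_gtf` returns an exon data.frame in the internal
#'   convention.
#' @export
write_transcripts_gtf <- function(exons, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chromosome,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "retinet"
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id
  S4Vectors::mcols(gr)$transcript_id <- exons$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_transcripts_gtf
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  data.frame(
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    gene_id = S4Vectors::mcols(gr)$gene_id,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
}

#' Read intervals to/from BED (0-based half-open, as stored internally)
#'
#' @param intervals data.frame `chromosome`, `start`, `end`.
#' @param path file path.
#' @export
write_reads_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chromosome,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a coverage track as bedGraph
#'
#' @param track data.frame from [bin_coverage()].
#' @param path file path.
#' @param drop_zero omit zero-valued bins (default TRUE, the usual bedGraph
#'   convention).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  if (drop_zero) track <- track[track$value > 0, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = track$chromosome,
    ranges = IRanges::IRanges(start = track$bin_start + 1L,
                              end = track$bin_end),
    score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
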