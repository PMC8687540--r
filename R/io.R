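# Readers and writers for the package's plain-text interchange formats.
# Counts / truth / junction tables are TSV; peaks are BED6+; annotation is
# GTF (1-based inclusive, via rtracklayer); UTRs are FASTA (Biostrings).

#' Read and write count matrices as TSV
#'
#' Genes x samples TSV with a `gene_id` first column and one column per
#' sample.
#'
#' @param mat Count (or any numeric) matrix with gene rownames.
#' @param path File path.
#' @return `read_counts_tsv()` returns a numeric matrix with gene rownames;
#'   writers return `path` invisibly.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene_id
  m
}

#' Read and write CLIP peak tables as BED6+
#'
#' Columns: chrom, start, end (0-based half-open), name (`rbp:replicate`),
#' score, strand, ip_reads, input_reads, ip_total, input_total. The
#' coordinate round-trip is byte-stable.
#'
#' @param peaks Peak tibble (extra bookkeeping columns are dropped).
#' @param path File path.
#' @return `read_peaks_bed()` returns the peak tibble with `rbp_id` and
#'   `replicate` re-derived from the name field.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed_cols <- c("chrom", "start", "end", "name", "score", "strand",
                "ip_reads", "input_reads", "ip_total", "input_total")
  readr::write_tsv(peaks[bed_cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "ip_reads", "input_reads", "ip_total", "input_total"),
    col_types = "ciiciciidd",
    show_col_types = FALSE
  )
  parts <- stringr::str_split_fixed(df$name, ":", 2)
  df$rbp_id <- parts[, 1]
  df$replicate <- as.integer(stringr::str_remove(parts[, 2], "^rep"))
  tibble::as_tibble(df)
}

#' Read and write the annotation as GTF
#'
#' 1-based inclusive coordinates, features typed `exon`, `CDS`,
#' `five_prime_utr`, `three_prime_utr`, with `gene_id` and `transcript_id`
#' attributes.
#'
#' @param annotation Annotation tibble.
#' @param path File path.
#' @return `read_annotation()` returns the annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$seqnames,
    IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = annotation$type,
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id
  )
  # rtracklayer warns that CDS features carry no phase; phase is not part of
  # this annotation model
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  tibble(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Read and write generic long-format TSV tables
#'
#' Used for the truth table, junction counts, correlation records and other
#' record-shaped outputs.
#'
#' @param tbl A tibble.
#' @param path File path.
#' @return `read_table_tsv()` returns a tibble.
#' @export
write_table_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
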