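#' Simulate a transcript annotation with UTR/CDS structure
#'
#' Generates a compact, GTF-style gene annotation for a synthetic genome:
#' each gene carries one (optionally two) spliced transcripts with contiguous
#' 5'UTR, CDS and 3'UTR on the mature mRNA, projected onto genomic exons
#' separated by introns. Feature lengths are drawn from lognormal
#' distributions, mirroring the long-tailed length distributions of human
#' protein-coding genes; the CDS length is always a multiple of 3.
#'
#' @param n_genes Number of genes to simulate.
#' @param length_params Named list of `c(meanlog, sdlog)` lognormal parameters
#'   for `utr5`, `cds`, `utr3`, `intron` lengths (nucleotides) and `n_exons`
#'   (exon count per transcript). Defaults approximate human medians
#'   (5'UTR ~170 nt, CDS ~1500 nt, 3'UTR ~800 nt, ~8 exons).
#' @param n_isoforms Transcripts per gene (1 or 2). A second isoform is an
#'   independently drawn structure on the same locus, used for
#'   principal-isoform selection and isoform-level TE comparisons.
#' @param seed Integer seed; identical seeds give byte-identical annotations.
#'
#' @return A tibble with one row per feature: `gene_id`, `transcript_id`,
#'   `seqnames`, `strand`, `type` (one of `exon`, `five_prime_utr`, `CDS`,
#'   `three_prime_utr`), `start`, `end` (1-based inclusive, GTF convention).
#' @export
#' @examples
#' ann <- simulate_annotation(5, seed = 1)
#' feature_lengths(ann)
simulate_annotation <- function(n_genes,
                                length_params = default_length_params(),
                                n_isoforms = 1L,
                                seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes")
  n_isoforms <- check_count(n_isoforms, "n_isoforms")
  if (n_isoforms > 2L) stop_config("`n_isoforms` must be 1 or 2")
  lp <- modifyList(default_length_params(), as.list(length_params))
  for (nm in c("utr5", "cds", "utr3", "intron", "n_exons")) {
    if (is.null(lp[[nm]]) || length(lp[[nm]]) != 2L) {
      stop_config(sprintf("length_params$%s must be c(meanlog, sdlog)", nm))
    }
  }

  with_seed(seed, {
    rows <- vector("list", n_genes)
    cursor <- 1000L
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("G%05d", g)
      strand <- if (runif(1) < 0.5) "+" else "-"
      tx_rows <- vector("list", n_isoforms)
      for (iso in seq_len(n_isoforms)) {
        tx_id <- sprintf("%s.T%d", gene_id, iso)
        tx_rows[[iso]] <- build_transcript(tx_id, gene_id, "chrS1", strand,
                                           cursor, lp)
        cursor <- max(tx_rows[[iso]]$end) + 2000L +
          as.integer(rlnorm1(lp$intron))
      }
      rows[[g]] <- bind_rows(tx_rows)
    }
    out <- bind_rows(rows)
    tibble::as_tibble(out[, c("gene_id", "transcript_id", "seqnames", "strand",
                              "type", "start", "end")])
  })
}

default_length_params <- function() {
  list(
    utr5    = c(log(170), 0.8),
    cds     = c(log(1500), 0.7),
    utr3    = c(log(800), 0.9),
    intron  = c(log(400), 0.8),
    n_exons = c(log(8), 0.5)
  )
}

rlnorm1 <- function(p, n = 1L) exp(rnorm(n, p[1], p[2]))

# One transcript: draw mRNA-space feature lengths, cut the mature mRNA into
# exons, insert introns, and project the UTR/CDS boundaries back to the
# genome (strand-aware).
build_transcript <- function(tx_id, gene_id, chrom, strand, gstart, lp) {
  u5 <- max(10L, as.integer(round(rlnorm1(lp$utr5))))
  cds <- max(60L, as.integer(round(rlnorm1(lp$cds))))
  cds <- cds - (cds %% 3L)
  u3 <- max(30L, as.integer(round(rlnorm1(lp$utr3))))
  L <- u5 + cds + u3
  n_ex <- max(1L, min(as.integer(round(rlnorm1(lp$n_exons))), L %/% 40L))

  # exon cut points on the mRNA (each exon >= 20 nt)
  if (n_ex > 1L) {
    cuts <- sort(sample.int(L - 1L, n_ex - 1L))
    # enforce a minimal exon width by respacing degenerate draws
    widths <- diff(c(0L, cuts, L))
    while (any(widths < 20L) && n_ex > 1L) {
      n_ex <- n_ex - 1L
      cuts <- if (n_ex > 1L) sort(sample.int(L - 1L, n_ex - 1L)) else integer(0)
      widths <- diff(c(0L, cuts, L))
    }
  } else {
    widths <- L
  }
  introns <- if (n_ex > 1L) {
    pmax(60L, as.integer(round(rlnorm1(lp$intron, n_ex - 1L))))
  } else integer(0)

  # genomic exon blocks, left to right
  ex_start <- integer(n_ex)
  ex_end <- integer(n_ex)
  pos <- gstart
  for (i in seq_len(n_ex)) {
    ex_start[i] <- pos
    ex_end[i] <- pos + widths[i] - 1L
    pos <- ex_end[i] + if (i < n_ex) introns[i] + 1L else 1L
  }

  feat <- tibble(
    type = c("five_prime_utr", "CDS", "three_prime_utr"),
    m_start = c(1L, u5 + 1L, u5 + cds + 1L),
    m_end = c(u5, u5 + cds, L)
  )
  feat_rows <- purrr::pmap(feat, function(type, m_start, m_end) {
    blk <- project_mrna_interval(m_start, m_end, ex_start, ex_end, strand)
    tibble(type = type, start = blk$start, end = blk$end)
  })
  out <- bind_rows(
    tibble(type = "exon", start = ex_start, end = ex_end),
    bind_rows(feat_rows)
  )
  out$gene_id <- gene_id
  out$transcript_id <- tx_id
  out$seqnames <- chrom
  out$strand <- strand
  out
}

# Project a closed interval [m_start, m_end] on the mature mRNA onto genomic
# exon blocks (given left-to-right). On "-" transcripts the mRNA runs from the
# rightmost exon leftwards.
project_mrna_interval <- function(m_start, m_end, ex_start, ex_end, strand) {
  widths <- ex_end - ex_start + 1L
  ord <- if (strand == "+") seq_along(widths) else rev(seq_along(widths))
  offs <- cumsum(c(0L, widths[ord]))[seq_along(widths)]
  gs <- integer(0); ge <- integer(0)
  for (k in seq_along(ord)) {
    i <- ord[k]
    lo <- offs[k] + 1L
    hi <- offs[k] + widths[i]
    a <- max(m_start, lo); b <- min(m_end, hi)
    if (a > b) next
    if (strand == "+") {
      gs <- c(gs, ex_start[i] + (a - lo))
      ge <- c(ge, ex_start[i] + (b - lo))
    } else {
      ge <- c(ge, ex_end[i] - (a - lo))
      gs <- c(gs, ex_end[i] - (b - lo))
    }
  }
  o <- order(gs)
  list(start = gs[o], end = ge[o])
}

#' Per-transcript feature lengths
#'
#' @param annotation Annotation tibble from [simulate_annotation()] or
#'   [read_annotation()].
#' @return Tibble with `gene_id`, `transcript_id` and summed `utr5_len`,
#'   `cds_len`, `utr3_len`, `tx_len` (mature mRNA) in nucleotides.
#' @export
feature_lengths <- function(annotation) {
  wide <- annotation |>
    filter(.data$type != "exon") |>
    mutate(len = .data$end - .data$start + 1L) |>
    group_by(.data$gene_id, .data$transcript_id, .data$type) |>
    summarise(len = sum(.data$len), .groups = "drop") |>
    pivot_wider(names_from = "type", values_from = "len", values_fill = 0L)
  wide |>
    rename(utr5_len = "five_prime_utr", cds_len = "CDS",
           utr3_len = "three_prime_utr") |>
    mutate(tx_len = .data$utr5_len + .data$cds_len + .data$utr3_len)
}
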