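#' Simulate replicated CLIP peak tables with decoys
#'
#' Emits per-RBP peak tables in BED-like coordinates (0-based, half-open):
#' true targets (from the planted truth) receive peaks with strong IP over
#' input enrichment whose scores are correlated across replicates; decoy
#' genes receive input-like peaks at rate `fp_rate` with replicate scores
#' drawn independently, so downstream reproducibility (IDR) and enrichment
#' filters are genuinely exercised rather than rubber-stamped.
#'
#' @param truth Truth tibble from [simulate_cohort()] (columns `rbp_id`,
#'   `gene_id`), or any tibble mapping RBPs to true target genes.
#' @param annotation Annotation tibble; peaks are placed inside target
#'   transcripts on the matching strand.
#' @param fp_rate Probability that a non-target gene receives a decoy peak.
#' @param fn_rate Probability that a true target is dropped (no peak at all).
#' @param n_replicates Number of CLIP replicates (>= 2; IDR needs two).
#' @param ip_total,input_total Library sizes used for the BED+ total columns.
#' @param seed Integer seed.
#'
#' @return Tibble with BED6+ columns: `chrom`, `start`, `end`, `name`
#'   (`rbp:replicate`), `score`, `strand`, `ip_reads`, `input_reads`,
#'   `ip_total`, `input_total`, plus convenience columns `rbp_id`,
#'   `replicate`, `peak_id`, `gene_id` (generator-side bookkeeping only;
#'   the BED writer drops them).
#' @export
simulate_clip_peaks <- function(truth, annotation,
                                fp_rate = 0.05, fn_rate = 0.05,
                                n_replicates = 2L,
                                ip_total = 2e5, input_total = 2e5,
                                seed = NULL) {
  check_fraction(fp_rate, "fp_rate")
  check_fraction(fn_rate, "fn_rate")
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (n_replicates < 2L) stop_config("n_replicates must be >= 2 (IDR needs two)")

  tx <- annotation |>
    filter(.data$type == "exon") |>
    group_by(.data$gene_id) |>
    summarise(seqnames = first(.data$seqnames), strand = first(.data$strand),
              gstart = min(.data$start), gend = max(.data$end),
              .groups = "drop")
  rbp_ids <- unique(truth$rbp_id)
  all_genes <- tx$gene_id

  with_seed(seed, {
    out <- vector("list", length(rbp_ids))
    for (i in seq_along(rbp_ids)) {
      rbp <- rbp_ids[i]
      true_targets <- unique(truth$gene_id[truth$rbp_id == rbp])
      kept <- true_targets[runif(length(true_targets)) >= fn_rate]
      decoy_pool <- setdiff(all_genes, c(true_targets, rbp))
      decoys <- decoy_pool[runif(length(decoy_pool)) < fp_rate]

      peaks_for <- function(gene_ids, is_true) {
        if (length(gene_ids) == 0L) return(NULL)
        # true targets carry 1-3 binding sites; decoys a single spurious one
        site_n <- if (is_true) 1L + rpois(length(gene_ids), 0.8) else
          rep(1L, length(gene_ids))
        gene_ids <- rep(gene_ids, site_n)
        g <- tx[match(gene_ids, tx$gene_id), ]
        width <- 50L
        pos <- g$gstart +
          floor(runif(nrow(g)) * pmax(1, g$gend - g$gstart - width))
        # latent binding strength shared across replicates for true peaks
        lat <- rnorm(nrow(g))
        purrr::map(seq_len(n_replicates), function(rep_i) {
          if (is_true) {
            ip <- rnbinom(nrow(g), mu = 120 * exp(0.5 * lat), size = 8)
            inp <- rnbinom(nrow(g), mu = 6, size = 8)
          } else {
            ip <- rnbinom(nrow(g), mu = 8, size = 4)
            inp <- rnbinom(nrow(g), mu = 7, size = 4)
          }
          tibble(
            chrom = g$seqnames,
            start = as.integer(pos - 1L),           # BED 0-based
            end = as.integer(pos + width - 1L),
            name = paste0(rbp, ":rep", rep_i),
            score = 0L,
            strand = g$strand,
            ip_reads = as.integer(ip),
            input_reads = as.integer(inp),
            ip_total = as.integer(ip_total),
            input_total = as.integer(input_total),
            rbp_id = rbp,
            replicate = rep_i,
            peak_id = paste0(rbp, ":", g$gene_id, ":",
                             if (is_true) "t" else "d", seq_len(nrow(g))),
            gene_id = g$gene_id
          )
        }) |> bind_rows()
      }
      out[[i]] <- bind_rows(peaks_for(kept, TRUE), peaks_for(decoys, FALSE))
    }
    bind_rows(out)
  })
}
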