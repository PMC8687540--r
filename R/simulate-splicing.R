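#' Simulate junction counts whose PSI tracks an RBP's expression
#'
#' For a set of cassette exons in an RBP's target genes, the true
#' percent-spliced-in follows `logit(PSI) = b0 + 2 * coupling * z` where `z`
#' is the standardized RBP expression, and observed inclusion (upstream /
#' downstream) and exclusion junction counts are Poisson around the implied
#' rates. An inclusion-isoform TE offset is emitted alongside, so isoform
#' TE comparisons can be benchmarked from the same table.
#'
#' @param truth Truth tibble from [simulate_cohort()]; exons are drawn from
#'   the target genes of `rbp_id`.
#' @param annotation Annotation tibble: designated exons must exist in it.
#' @param rbp_id RBP whose expression drives splicing.
#' @param rbp_z Numeric vector of standardized RBP expression per sample (any
#'   expression proxy works; it is standardized internally).
#' @param coupling Coupling in `[-1, 1]` between PSI and RBP expression.
#' @param n_exons Number of designated cassette exons.
#' @param mean_coverage Mean junction coverage per exon per sample.
#' @param te_offset Log TE offset of the inclusion isoform relative to the
#'   exclusion isoform.
#' @param exons Optional tibble (`gene_id`, `exon_id`) naming the designated
#'   exons explicitly; an error is raised if an exon is absent from the
#'   annotation.
#' @param seed Integer seed.
#'
#' @return Tibble with one row per exon x sample: `gene_id`, `exon_id`,
#'   `sample_id`, `ij_up`, `ij_down`, `ej` (junction counts), `true_psi`,
#'   and `te_incl_offset`.
#' @export
simulate_splicing <- function(truth, annotation, rbp_id, rbp_z,
                              coupling, n_exons = 20L, mean_coverage = 60,
                              te_offset = -0.5, exons = NULL, seed = NULL) {
  if (length(coupling) != 1L || is.na(coupling) || abs(coupling) > 1) {
    stop_config("`coupling` must be a single value in [-1, 1]")
  }
  z <- as.numeric(scale(rbp_z))
  ex_ann <- annotation |>
    filter(.data$type == "exon") |>
    group_by(.data$transcript_id) |>
    mutate(exon_id = paste0(.data$transcript_id, ":E",
                            row_number())) |>
    ungroup()
  if (is.null(exons)) {
    target_genes <- unique(truth$gene_id[truth$rbp_id == rbp_id])
    pool <- ex_ann |> filter(.data$gene_id %in% target_genes)
    if (nrow(pool) == 0L) stop_config("rbp has no target genes with exons")
    with_seed(child_seed(seed, "pick"), {
      pool <- pool[sample.int(nrow(pool), min(n_exons, nrow(pool))), ]
    })
    exons <- pool |> select("gene_id", "exon_id")
  } else {
    missing <- setdiff(exons$exon_id, ex_ann$exon_id)
    if (length(missing) > 0) {
      stop_config(paste0("designated exon(s) absent from annotation: ",
                         paste(missing, collapse = ", ")))
    }
  }

  with_seed(seed, {
    n <- length(z)
    samples <- sprintf("S%03d", seq_len(n))
    rows <- purrr::map(seq_len(nrow(exons)), function(i) {
      b0 <- rnorm(1, 0, 0.5)
      psi <- stats::plogis(b0 + 2 * coupling * z)
      cov_mu <- mean_coverage
      ij_up <- rpois(n, cov_mu * psi)
      ij_down <- rpois(n, cov_mu * psi)
      ej <- rpois(n, cov_mu * (1 - psi))
      tibble(gene_id = exons$gene_id[i], exon_id = exons$exon_id[i],
             sample_id = samples, ij_up = ij_up, ij_down = ij_down, ej = ej,
             true_psi = psi, te_incl_offset = te_offset)
    })
    bind_rows(rows)
  })
}
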