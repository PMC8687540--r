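#' Joint median-of-ratios size factors
#'
#' Estimates one size factor per library with the median-of-ratios estimator
#' on the combined gene x library matrix. For cohort data the RNA-seq and
#' Ribo-seq libraries must be normalized jointly (a single geometric-mean
#' reference across both assays) so that the two measures of gene expression
#' are on a comparable scale and their ratio (TE) is meaningful.
#'
#' Genes with a zero count in any library are excluded from the geometric-mean
#' reference; each library's factor is the median over remaining genes of
#' count / geometric mean.
#'
#' @param counts Non-negative integer matrix, genes x libraries. For joint
#'   normalization pass `cbind(rna, ribo)` with distinct library names.
#' @return Named numeric vector of size factors, one per library.
#' @export
#' @examples
#' m <- matrix(c(2, 4, 2, 4, 2, 4), nrow = 3, byrow = TRUE)
#' estimate_size_factors(m)  # c(0.7071, 1.4142)
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_config("counts must be non-negative")
  geo <- apply(counts, 1L, geomean_nonzero)
  use <- !is.na(geo)
  if (!any(use)) {
    stop_config(paste("no gene has nonzero counts in every library;",
                      "the median-of-ratios reference is undefined"))
  }
  sf <- apply(counts[use, , drop = FALSE] / geo[use], 2L, median)
  setNames(as.numeric(sf), colnames(counts))
}

#' Size-factor normalization
#'
#' Divides each library by its size factor.
#'
#' @param counts Matrix, genes x libraries.
#' @param size_factors Numeric vector, one strictly positive factor per
#'   library (recycled by position; names checked when present).
#' @return Normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts, size_factors) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0L) return(counts)
  if (length(size_factors) != ncol(counts)) {
    stop_config("one size factor per library is required")
  }
  if (any(size_factors <= 0)) stop_config("size factors must be > 0")
  if (!is.null(names(size_factors)) && !is.null(colnames(counts)) &&
      !identical(names(size_factors), colnames(counts))) {
    size_factors <- size_factors[colnames(counts)]
  }
  sweep(counts, 2L, size_factors, "/")
}

#' FPKM from a count matrix
#'
#' `FPKM = count / ((length/1e3) * (library_total/1e6))`. Feature lengths
#' should be the lengths over which reads were counted; for CDS-restricted
#' counting that is the CDS length.
#'
#' @param counts Matrix, genes x libraries.
#' @param lengths Numeric vector of feature lengths (nt) per gene, > 0.
#' @param library_totals Optional per-library totals; defaults to column sums.
#' @return FPKM matrix.
#' @export
compute_fpkm <- function(counts, lengths, library_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) {
    stop_config("one length per gene is required")
  }
  if (any(lengths <= 0)) stop_config("feature lengths must be > 0")
  if (any(library_totals == 0)) stop_config("library total of zero")
  counts / outer(lengths / 1e3, library_totals / 1e6)
}

#' Expression filter for translated genes
#'
#' A gene is retained iff its mean FPKM across samples exceeds
#' `min_mean_fpkm` (strict) and it has at least one Ribo-seq *and* one
#' RNA-seq read in at least `min_samples` samples.
#'
#' @param fpkm FPKM matrix (typically RNA-seq), genes x samples.
#' @param rna,ribo Raw count matrices aligned to `fpkm`.
#' @param min_mean_fpkm Strict lower bound on mean FPKM (default 1).
#' @param min_samples Minimum number of samples with evidence in both assays
#'   (default 20).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(fpkm, rna, ribo, min_mean_fpkm = 1,
                             min_samples = 20L) {
  if (!identical(rownames(rna), rownames(ribo)) ||
      !identical(rownames(fpkm), rownames(rna))) {
    stop_config("fpkm, rna and ribo must share gene ids in the same order")
  }
  min_samples <- check_count(min_samples, "min_samples", min = 0L)
  if (min_samples > ncol(rna)) {
    stop_config("min_samples exceeds the number of samples")
  }
  mean_ok <- rowMeans(fpkm) > min_mean_fpkm
  both_ok <- rowSums(rna >= 1 & ribo >= 1) >= min_samples
  rownames(fpkm)[mean_ok & both_ok]
}

#' Translational efficiency
#'
#' TE is the elementwise ratio of jointly normalized Ribo-seq over RNA-seq
#' values per gene and sample; entries with zero normalized RNA are missing
#' (no imputation — downstream correlations are pairwise-complete).
#'
#' @param ribo_norm,rna_norm Normalized matrices aligned on genes x samples.
#' @return Matrix of TE values with `NA` where `rna_norm == 0`.
#' @export
compute_te <- function(ribo_norm, rna_norm) {
  if (!identical(dim(ribo_norm), dim(rna_norm))) {
    stop_config("ribo and rna matrices must have identical shape")
  }
  te <- ribo_norm / rna_norm
  te[rna_norm == 0] <- NA_real_
  te
}

#' Percent spliced in (PSI)
#'
#' `PSI = mean(ij_up, ij_down) / (mean(ij_up, ij_down) + ej)`, with the value
#' set missing when `mean(ij) + ej < min_total` (insufficient junction
#' coverage to call splicing).
#'
#' @param junctions Tibble with columns `gene_id`, `exon_id`, `sample_id`,
#'   `ij_up`, `ij_down`, `ej` (upstream/downstream inclusion and exclusion
#'   junction counts).
#' @param min_total Coverage floor (default 10).
#' @return The input tibble with a `psi` column appended.
#' @export
#' @examples
#' compute_psi(tibble::tibble(gene_id = "g", exon_id = "e", sample_id = "s",
#'                            ij_up = 8, ij_down = 12, ej = 10))$psi  # 0.5
compute_psi <- function(junctions, min_total = 10) {
  need <- c("ij_up", "ij_down", "ej")
  if (!all(need %in% names(junctions))) {
    stop_config("junctions needs columns ij_up, ij_down, ej")
  }
  if (any(junctions$ij_up < 0 | junctions$ij_down < 0 | junctions$ej < 0)) {
    stop_config("junction counts must be non-negative")
  }
  junctions |>
    mutate(
      .ij = (.data$ij_up + .data$ij_down) / 2,
      psi = if_else(.data$.ij + .data$ej >= min_total,
                    .data$.ij / (.data$.ij + .data$ej), NA_real_)
    ) |>
    select(-".ij")
}
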