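#' Minimum free energy of an RNA sequence (built-in engine)
#'
#' Folds a sequence with the package's built-in nested-structure dynamic
#' program: allowed pairs GC/CG (-3), AU/UA (-2), GU/UG (-1), minimum
#' hairpin loop of 3 unpaired bases, structure energy = sum of pair
#' energies, no pseudoknots. The returned MFE is the minimum energy over all
#' nested structures and is always <= 0 (the open chain scores 0). `T` is
#' converted to `U`; any other non-ACGU character is an error.
#'
#' A different folding engine (e.g. a thermodynamic partition-function
#' folder) can be plugged in via `engine`, a function mapping one sequence
#' to an energy; all packaged analyses default to the built-in model so
#' results are engine-pinned.
#'
#' @param seq Character vector of RNA sequences.
#' @param min_loop Minimum hairpin loop length (default 3).
#' @param engine Optional replacement folding function.
#' @return Numeric vector of MFE values.
#' @export
#' @examples
#' fold_mfe("GGGAAAACCC")  # -9: three GC pairs close the hairpin
fold_mfe <- function(seq, min_loop = 3L, engine = NULL) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    stop_config(sprintf("invalid RNA character(s) in sequence(s): %s",
                        paste(which(bad), collapse = ", ")))
  }
  if (!is.null(engine)) return(vapply(seq, engine, numeric(1), USE.NAMES = FALSE))
  vapply(seq, .fold_mfe_cpp, numeric(1), min_loop = as.integer(min_loop),
         USE.NAMES = FALSE)
}

#' Length-normalized MFE
#'
#' MFE divided by sequence length (energy per nucleotide, <= 0). Sequences
#' shorter than `min_length` return `NA`: very short leaders carry almost no
#' foldable signal and are excluded from structural comparisons.
#'
#' @inheritParams fold_mfe
#' @param min_length Minimum sequence length to evaluate (default 20).
#' @return Numeric vector of normalized MFE values (`NA` below `min_length`).
#' @export
normalized_mfe <- function(seq, min_length = 20L, min_loop = 3L, engine = NULL) {
  len <- nchar(seq)
  out <- rep(NA_real_, length(seq))
  ok <- len >= min_length
  if (any(ok)) {
    out[ok] <- fold_mfe(seq[ok], min_loop = min_loop, engine = engine) / len[ok]
  }
  names(out) <- names(seq)
  out
}

#' Compare 5'UTR structure between positively and negatively correlating
#' targets
#'
#' Wilcoxon rank-sum test on length-normalized MFE between the targets whose
#' trait correlates positively versus negatively with the RBP. Sequences
#' shorter than `min_length` are excluded; a sign group with fewer than 3
#' evaluable members yields a missing result.
#'
#' @param records Correlation records (significant rows are used) with
#'   `rho` and `gene_id`.
#' @param utr_seqs Named character vector of 5'UTR sequences.
#' @param min_length Minimum UTR length (default 20).
#' @param engine Optional folding engine (see [fold_mfe()]).
#' @param nmfe Optional named vector of precomputed normalized MFE values
#'   (bypasses folding; useful when many RBPs share target genes).
#' @return One-row tibble: `n_pos`, `n_neg`, `mean_nmfe_pos`,
#'   `mean_nmfe_neg`, `W`, `p`.
#' @export
compare_mfe_by_sign <- function(records, utr_seqs, min_length = 20L,
                                engine = NULL, nmfe = NULL) {
  sig <- if ("significant" %in% names(records)) {
    records |> filter(.data$significant)
  } else records
  universe <- if (is.null(nmfe)) names(utr_seqs) else names(nmfe)
  sig <- sig[sig$gene_id %in% universe, ]
  nm <- if (is.null(nmfe)) {
    normalized_mfe(utr_seqs[sig$gene_id], min_length = min_length,
                   engine = engine)
  } else unname(nmfe[sig$gene_id])
  pos <- nm[sig$rho > 0 & !is.na(nm)]
  neg <- nm[sig$rho < 0 & !is.na(nm)]
  if (length(pos) < 3L || length(neg) < 3L) {
    return(tibble(n_pos = length(pos), n_neg = length(neg),
                  mean_nmfe_pos = NA_real_, mean_nmfe_neg = NA_real_,
                  W = NA_real_, p = NA_real_))
  }
  wt <- rank_sum_test(pos, neg)
  tibble(n_pos = length(pos), n_neg = length(neg),
         mean_nmfe_pos = mean(pos), mean_nmfe_neg = mean(neg),
         W = wt$W, p = wt$p)
}
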