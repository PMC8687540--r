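#' Fraction of correlations replicating in direction
#'
#' Among discovery-significant (RBP, gene, trait) pairs, the fraction whose
#' replication-cohort Spearman rho has the same sign as in discovery. A zero
#' replication rho counts as non-replicated.
#'
#' @param disc_rho,repl_rho Numeric vectors of correlation coefficients over
#'   the same pairs.
#' @return Fraction in `[0, 1]`, or `NA` when no evaluable pairs.
#' @export
replication_fraction <- function(disc_rho, repl_rho) {
  keep <- !is.na(disc_rho) & !is.na(repl_rho)
  if (!any(keep)) return(NA_real_)
  mean(sign(disc_rho[keep]) == sign(repl_rho[keep]) & repl_rho[keep] != 0)
}

#' Permutation test for directional replication
#'
#' Permutes the replication rho vector over pairs (within the RBP) and
#' compares the permuted replication fractions with the observed one:
#' `p = (1 + #\{perm fraction >= observed\}) / (1 + n_perm)`. The +1
#' smoothing keeps the p-value away from zero.
#'
#' @param disc_rho,repl_rho Correlation coefficients over the
#'   discovery-significant pairs of one RBP.
#' @param n_perm Number of permutations (default 10000; below 100 a warning
#'   is raised).
#' @param seed Integer seed.
#' @return One-row tibble: `n_pairs`, `fraction`, `p`.
#' @export
replication_permutation_test <- function(disc_rho, repl_rho, n_perm = 1e4,
                                         seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100L) warn("fewer than 100 permutations: p-values are coarse")
  keep <- !is.na(disc_rho) & !is.na(repl_rho)
  disc_rho <- disc_rho[keep]; repl_rho <- repl_rho[keep]
  n <- length(disc_rho)
  if (n == 0L) return(tibble(n_pairs = 0L, fraction = NA_real_, p = NA_real_))
  if (n < 10L) warn("fewer than 10 evaluable pairs: replication test is weak")
  obs <- replication_fraction(disc_rho, repl_rho)
  ds <- sign(disc_rho)
  with_seed(seed, {
    perm_frac <- vapply(seq_len(n_perm), function(i) {
      mean(ds == sign(repl_rho[sample.int(n)]) & repl_rho != 0)
    }, numeric(1))
    tibble(n_pairs = n, fraction = obs,
           p = (1 + sum(perm_frac >= obs)) / (1 + n_perm))
  })
}

#' Cross-cohort replication of RBP-target correlation direction
#'
#' Joins discovery-significant correlation records with a replication
#' cohort's correlation table on (rbp_id, gene_id, trait), computes each
#' RBP's replicated-direction fraction, its within-RBP permutation p, and
#' BH-adjusts across RBPs.
#'
#' @param discovery Correlation records with `significant` flags (from
#'   [correlate_targets()]).
#' @param replication Correlation table of the replication cohort (columns
#'   `rbp_id`, `gene_id`, `trait`, `rho`); genes absent from it are not
#'   evaluable.
#' @param n_perm,seed Passed to [replication_permutation_test()].
#' @return Tibble per RBP x trait: `rbp_id`, `trait`, `n_pairs`, `fraction`,
#'   `p`, `p_adj`.
#' @export
replicate_correlations <- function(discovery, replication, n_perm = 1e4,
                                   seed = NULL) {
  pairs <- discovery |>
    filter(.data$significant) |>
    inner_join(replication |> select("rbp_id", "gene_id", "trait",
                                     repl_rho = "rho"),
               by = c("rbp_id", "gene_id", "trait"))
  out <- pairs |>
    group_by(.data$rbp_id, .data$trait) |>
    group_split() |>
    purrr::imap(function(d, i) {
      res <- replication_permutation_test(
        d$rho, d$repl_rho, n_perm = n_perm,
        seed = child_seed(seed, paste0(d$rbp_id[1], d$trait[1]))
      )
      mutate(res, rbp_id = d$rbp_id[1], trait = d$trait[1])
    }) |>
    bind_rows()
  if (nrow(out) == 0L) {
    return(tibble(rbp_id = character(0), trait = character(0),
                  n_pairs = integer(0), fraction = numeric(0),
                  p = numeric(0), p_adj = numeric(0)))
  }
  out |>
    mutate(p_adj = adjust_bh(.data$p)) |>
    select("rbp_id", "trait", "n_pairs", "fraction", "p", "p_adj")
}
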