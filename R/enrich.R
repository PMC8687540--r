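# The empirical target-set sampling test: how often do randomly drawn,
# equally sized gene sets from the translated universe contain as many
# BH-significant correlations with the RBP as its CLIP-derived target set?

# Number of BH rejections at level alpha within one family of p-values.
bh_significant_count <- function(p, alpha) {
  p <- p[!is.na(p)]
  k <- length(p)
  if (k == 0L) return(0L)
  ps <- sort(p)
  ok <- which(ps <= alpha * seq_len(k) / k)
  if (length(ok) == 0L) 0L else max(ok)
}

#' Null distribution of significant-target counts over sampled gene sets
#'
#' Draws `n_sets` gene sets of size `set_size` uniformly without replacement
#' from the universe (independently across sets) and, for each, counts how
#' many member genes are BH-significant at `alpha` — using the per-gene
#' p-values of the *same* RBP correlation procedure as the observed count,
#' with BH applied within each sampled set (the identical family convention).
#' `method = "enumerate"` replaces sampling with exhaustive enumeration of
#' all `choose(|universe|, set_size)` sets.
#'
#' @param gene_p Named numeric vector of per-gene correlation p-values over
#'   the universe (from [spearman_vs_matrix()] against the RBP).
#' @param set_size Target-set size; must not exceed the universe size.
#' @param n_sets Number of sampled sets (default 100000). Ignored when
#'   enumerating.
#' @param alpha BH significance level within each set (default 0.05).
#' @param seed Integer seed.
#' @param method `"sample"` (default) or `"enumerate"`.
#' @return Integer vector of significant counts, one per set, with
#'   attributes `n_sets` and `seed`.
#' @export
sample_null_sets <- function(gene_p, set_size, n_sets = 1e5, alpha = 0.05,
                             seed = NULL, method = c("sample", "enumerate")) {
  method <- match.arg(method)
  m <- length(gene_p)
  set_size <- check_count(set_size, "set_size")
  if (set_size > m) stop_config("set_size exceeds the universe size")
  if (method == "enumerate") {
    sets <- combn(m, set_size)
    counts <- apply(sets, 2L, function(idx)
      bh_significant_count(gene_p[idx], alpha))
  } else {
    n_sets <- check_count(n_sets, "n_sets")
    counts <- with_seed(seed, {
      vapply(seq_len(n_sets), function(i) {
        bh_significant_count(gene_p[sample.int(m, set_size)], alpha)
      }, integer(1))
    })
  }
  structure(as.integer(counts), n_sets = length(counts), seed = seed)
}

#' Empirical p-value against a sampled null
#'
#' `p = #\{null >= observed\} / n_sets`, floored at `1/n_sets`: with a fixed
#' number of sampled sets a zero count only bounds the p-value, so the
#' smallest reportable value is one over the number of sets.
#'
#' @param observed Observed significant-target count.
#' @param null Integer vector of null counts (from [sample_null_sets()]).
#' @return Empirical p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  if (length(null) == 0L) stop_config("empty null distribution")
  max(sum(null >= observed), 1L) / length(null)
}

#' Glass' delta effect size
#'
#' `(observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation of the control (null) group.
#'
#' @inheritParams empirical_pvalue
#' @return Glass' delta.
#' @export
glass_delta <- function(observed, null) {
  s <- sd(null)
  if (is.na(s) || s == 0) {
    abort("degenerate null distribution: sd is zero",
          class = "rbptraits_degenerate_null")
  }
  (observed - mean(null)) / s
}

#' Empirical enrichment test for one RBP and trait
#'
#' Computes per-gene Spearman p-values of the RBP's expression against the
#' trait over the whole universe (minus the RBP's own gene), counts the
#' BH-significant members of the CLIP target set, builds the sampled null of
#' equally sized sets, and summarizes with the empirical p-value and Glass'
#' delta.
#'
#' @param rbp_expr Numeric vector: the RBP's normalized Ribo-seq values.
#' @param trait_matrix Genes x samples trait matrix (universe rows).
#' @param targets Character vector of the RBP's CLIP target genes.
#' @param universe Character vector of translated genes to sample from; the
#'   RBP's own gene is removed. Defaults to all rows of `trait_matrix`.
#' @param rbp_id,trait Labels for the record.
#' @param n_sets,alpha,seed,method Passed to [sample_null_sets()].
#' @param min_pairs Minimum complete pairs per correlation.
#' @return An object of class `rbp_enrichment`: a list with the one-row
#'   `record` tibble (`rbp_id`, `trait`, `n_targets`, `observed`,
#'   `null_mean`, `null_sd`, `emp_p`, `glass_delta`), the `null` counts, the
#'   per-target correlation `records`, and call metadata.
#' @export
enrichment_test <- function(rbp_expr, trait_matrix, targets, universe = NULL,
                            rbp_id = "RBP", trait = "trait",
                            n_sets = 1e5, alpha = 0.05, seed = NULL,
                            method = c("sample", "enumerate"),
                            min_pairs = 10L) {
  method <- match.arg(method)
  universe <- universe %||% rownames(trait_matrix)
  universe <- setdiff(intersect(universe, rownames(trait_matrix)), rbp_id)
  targets <- intersect(targets, universe)
  if (length(targets) == 0L) stop_config("no target genes in the universe")

  univ_p <- spearman_vs_matrix(rbp_expr,
                               trait_matrix[universe, , drop = FALSE],
                               min_pairs = min_pairs)
  gene_p <- setNames(univ_p$p, univ_p$gene_id)
  observed <- bh_significant_count(gene_p[targets], alpha)
  null <- sample_null_sets(gene_p, length(targets), n_sets = n_sets,
                           alpha = alpha, seed = seed, method = method)
  rec <- tibble(
    rbp_id = rbp_id, trait = trait, n_targets = length(targets),
    observed = observed, null_mean = mean(null), null_sd = sd(null),
    emp_p = empirical_pvalue(observed, null),
    glass_delta = if (sd(null) > 0) glass_delta(observed, null) else NA_real_
  )
  target_records <- univ_p |>
    filter(.data$gene_id %in% targets) |>
    mutate(rbp_id = rbp_id, trait = trait,
           p_adj = adjust_bh(.data$p),
           significant = !is.na(.data$p_adj) & .data$p_adj <= alpha) |>
    select("rbp_id", "gene_id", "trait", "rho", "n", "p", "p_adj",
           "significant")
  structure(
    list(record = rec, null = as.integer(null), records = target_records,
         alpha = alpha, seed = seed, method = method),
    class = "rbp_enrichment"
  )
}

#' @export
print.rbp_enrichment <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "Empirical target-set enrichment: %s / %s\n  %d targets, %d significant (null %.2f +/- %.2f over %d sets)\n  empirical p = %.3g, Glass' delta = %.2f\n",
    r$rbp_id, r$trait, r$n_targets, r$observed, r$null_mean, r$null_sd,
    length(x$null), r$emp_p, r$glass_delta))
  invisible(x)
}

#' @export
tidy.rbp_enrichment <- function(x, ...) x$records

#' @export
glance.rbp_enrichment <- function(x, ...) x$record

#' Classify RBPs from their per-trait enrichment records
#'
#' BH-adjusts the empirical p-values across RBPs within each trait and
#' labels each RBP: `mRNA-RBP` and/or `TE-RBP` when the respective adjusted
#' p is at or below `alpha`, `multifunctional` when both, `none` otherwise.
#'
#' @param records Tibble of enrichment records (rows per RBP x trait with
#'   `rbp_id`, `trait`, `emp_p`; [glance()] rows bind directly).
#' @param alpha Classification level (default 0.05).
#' @return Tibble per RBP: `rbp_id`, `p_adj_mrna`, `p_adj_te`, `mrna_rbp`,
#'   `te_rbp`, `label` (one of `mRNA-RBP`, `TE-RBP`, `multifunctional`,
#'   `none`).
#' @export
classify_rbps <- function(records, alpha = 0.05) {
  adj <- records |>
    group_by(.data$trait) |>
    mutate(p_adj = adjust_bh(.data$emp_p)) |>
    ungroup() |>
    select("rbp_id", "trait", "p_adj") |>
    pivot_wider(names_from = "trait", values_from = "p_adj")
  for (col in c("mRNA", "TE")) {
    if (is.null(adj[[col]])) adj[[col]] <- NA_real_
  }
  adj |>
    rename(p_adj_mrna = "mRNA", p_adj_te = "TE") |>
    mutate(
      mrna_rbp = !is.na(.data$p_adj_mrna) & .data$p_adj_mrna <= alpha,
      te_rbp = !is.na(.data$p_adj_te) & .data$p_adj_te <= alpha,
      label = dplyr::case_when(
        .data$mrna_rbp & .data$te_rbp ~ "multifunctional",
        .data$mrna_rbp ~ "mRNA-RBP",
        .data$te_rbp ~ "TE-RBP",
        TRUE ~ "none"
      )
    )
}

#' Overlap between mRNA and TE target sets
#'
#' Venn counts and the overlap percentage `100 * |A intersect B| / |A union
#' B|` between an RBP's significant mRNA targets and significant TE targets.
#'
#' @param mrna_targets,te_targets Character vectors of gene ids.
#' @return One-row tibble: `n_mrna_only`, `n_shared`, `n_te_only`,
#'   `overlap_pct` (`NA` when both sets are empty).
#' @export
target_overlap <- function(mrna_targets, te_targets) {
  a <- unique(mrna_targets); b <- unique(te_targets)
  un <- union(a, b)
  tibble(
    n_mrna_only = length(setdiff(a, b)),
    n_shared = length(intersect(a, b)),
    n_te_only = length(setdiff(b, a)),
    overlap_pct = if (length(un) == 0) NA_real_ else
      100 * length(intersect(a, b)) / length(un)
  )
}

#' @rdname enrichment_test
#' @param object An `rbp_enrichment` object.
#' @param ... Unused.
#' @export
autoplot.rbp_enrichment <- function(object, ...) {
  df <- tibble(count = object$null)
  ggplot(df, aes(x = .data$count)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$record$observed, colour = "firebrick",
               linewidth = 0.8) +
    labs(
      x = "significant targets per sampled set",
      y = "sampled sets",
      title = sprintf("%s / %s: observed %d, empirical p = %.3g, Δ = %.2f",
                      object$record$rbp_id, object$record$trait,
                      object$record$observed, object$record$emp_p,
                      object$record$glass_delta)
    ) +
    theme_minimal()
}
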