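#' Pairwise-complete Spearman correlation
#'
#' Midrank (average-rank) Spearman correlation over samples where both
#' vectors are observed. The p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` for `n >= 10` and the exact permutation
#' null (all `n!` rank arrangements) for smaller `n`; two-sided throughout.
#'
#' @param x,y Numeric vectors of equal length; `NA`s are dropped pairwise.
#' @param min_pairs Minimum number of complete pairs (default 10); below it
#'   the result is a missing record with `reason = "too_few_pairs"`.
#' @return One-row tibble: `rho`, `n`, `p`, `reason` (`NA` when computed).
#' @export
#' @examples
#' cor_spearman(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
cor_spearman <- function(x, y, min_pairs = 10L) {
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n < min_pairs) {
    return(tibble(rho = NA_real_, n = n, p = NA_real_,
                  reason = "too_few_pairs"))
  }
  rx <- rank(x[keep]); ry <- rank(y[keep])
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble(rho = NA_real_, n = n, p = NA_real_, reason = "constant"))
  }
  rho <- cor(rx, ry)
  p <- spearman_pvalue(rho, rx, ry)
  tibble(rho = rho, n = n, p = p, reason = NA_character_)
}

spearman_pvalue <- function(rho, rx, ry) {
  n <- length(rx)
  if (n >= 10L) {
    if (abs(rho) >= 1) return(0)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  } else {
    # exact two-sided permutation null over all n! arrangements
    pm <- all_permutations(n)
    cx <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
    cy <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    rhos <- as.numeric(matrix(cy[pm], nrow = nrow(pm)) %*% cx)
    mean(abs(rhos) >= abs(rho) - 1e-12)
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Spearman correlation of one vector against every row of a matrix
#'
#' Vectorized pairwise-complete Spearman: rows without missing values share
#' one rank transform and a matrix product; rows with missingness fall back
#' to the scalar [cor_spearman()] path (which also supplies exact small-n
#' p-values).
#'
#' @param x Numeric vector (e.g. an RBP's expression), length `ncol(Y)`.
#' @param Y Numeric matrix, genes x samples; `NA` allowed.
#' @param min_pairs Minimum complete pairs per row.
#' @return Tibble with `gene_id`, `rho`, `n`, `p` per row of `Y`.
#' @export
spearman_vs_matrix <- function(x, Y, min_pairs = 10L) {
  stopifnot(length(x) == ncol(Y))
  genes <- rownames(Y)
  rho <- rep(NA_real_, nrow(Y)); pval <- rep(NA_real_, nrow(Y))
  npair <- integer(nrow(Y))
  x_ok <- !is.na(x)
  complete_rows <- which(rowSums(is.na(Y)) == 0L)
  # the shared-rank fast path needs a complete x and the t approximation
  if (!all(x_ok) || ncol(Y) < 10L) complete_rows <- integer(0)

  if (length(complete_rows) > 0) {
    rx <- rank(x)
    cx <- rx - mean(rx)
    cx_norm <- sqrt(sum(cx^2))
    R <- t(apply(Y[complete_rows, , drop = FALSE], 1L, rank))
    Rc <- R - rowMeans(R)
    norms <- sqrt(rowSums(Rc^2))
    r <- as.numeric(Rc %*% cx) / (norms * cx_norm)
    r[norms == 0 | cx_norm == 0] <- NA_real_
    n <- ncol(Y)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p[abs(r) >= 1] <- 0
    rho[complete_rows] <- r
    pval[complete_rows] <- p
    npair[complete_rows] <- n
  }
  rest <- setdiff(seq_len(nrow(Y)), complete_rows)
  for (i in rest) {
    rec <- cor_spearman(x, Y[i, ], min_pairs = min_pairs)
    rho[i] <- rec$rho; pval[i] <- rec$p; npair[i] <- rec$n
  }
  tibble(gene_id = genes %||% as.character(seq_len(nrow(Y))),
         rho = rho, n = npair, p = pval)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_config("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Correlate one RBP against its target genes
#'
#' Spearman correlation of the RBP's (Ribo-seq) expression against each
#' target gene's trait values, BH-adjusted within the RBP x trait family.
#'
#' @param rbp_expr Numeric vector: the RBP's normalized Ribo-seq values per
#'   sample.
#' @param trait_matrix Genes x samples matrix of the trait (normalized mRNA
#'   abundance or TE; `NA` allowed).
#' @param targets Character vector of target gene ids (must appear in
#'   `trait_matrix`; absent ones are dropped).
#' @param rbp_id,trait Labels copied into the records.
#' @param alpha Significance level on the adjusted p (default 0.05,
#'   retained iff `p_adj <= alpha`).
#' @param min_pairs Minimum complete pairs per correlation.
#' @return Tibble of correlation records: `rbp_id`, `gene_id`, `trait`,
#'   `rho`, `n`, `p`, `p_adj`, `significant`.
#' @export
correlate_targets <- function(rbp_expr, trait_matrix, targets,
                              rbp_id = "RBP", trait = "trait",
                              alpha = 0.05, min_pairs = 10L) {
  targets <- intersect(targets, rownames(trait_matrix))
  if (length(targets) == 0L) {
    return(tibble(rbp_id = character(0), gene_id = character(0),
                  trait = character(0), rho = numeric(0), n = integer(0),
                  p = numeric(0), p_adj = numeric(0), significant = logical(0)))
  }
  res <- spearman_vs_matrix(rbp_expr, trait_matrix[targets, , drop = FALSE],
                            min_pairs = min_pairs)
  res |>
    mutate(rbp_id = rbp_id, trait = trait,
           p_adj = adjust_bh(.data$p),
           significant = !is.na(.data$p_adj) & .data$p_adj <= alpha) |>
    select("rbp_id", "gene_id", "trait", "rho", "n", "p", "p_adj",
           "significant")
}

#' Rank-based partial correlation
#'
#' Spearman-type partial correlation of `x` and `y` given conditioning
#' variables `z`: all variables are midrank-transformed over jointly complete
#' samples, `x` and `y` are residualized on the rank-transformed `z` by least
#' squares, and the residuals are correlated. With one conditioning variable
#' this equals the first-order closed form
#' `(r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2))`. The p-value is a t test
#' with `n - 2 - k` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param z Numeric vector or matrix (samples x k) of conditioning variables.
#' @return One-row tibble: `rho`, `n`, `p`.
#' @export
partial_spearman <- function(x, y, z) {
  z <- as.matrix(z)
  keep <- complete.cases(x, y, z)
  n <- sum(keep)
  k <- ncol(z)
  if (k >= n - 3L) stop_config("too many conditioning variables for n")
  rx <- rank(x[keep]); ry <- rank(y[keep])
  rz <- apply(z[keep, , drop = FALSE], 2L, rank)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  # residual variance at numerical zero: the conditioning set explains the
  # variable completely, nothing left to correlate
  tol <- 1e-8 * n
  if (sd(ex) < tol || sd(ey) < tol) {
    return(tibble(rho = 0, n = n, p = 1))
  }
  r <- cor(ex, ey)
  df <- n - 2L - k
  tt <- r * sqrt(df / max(1 - r^2, 1e-300))
  tibble(rho = r, n = n, p = 2 * pt(-abs(tt), df = df))
}

#' Fisher Z comparison of two correlation coefficients
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (> 3).
#' @return One-row tibble: `z`, `p`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stop_config("|r| must be < 1 for Fisher Z")
  if (any(c(n1, n2) <= 3)) stop_config("n must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Collinearity control within an RBP cluster
#'
#' For each RBP in a cluster of co-expressed RBPs, each of its significant
#' targets is re-tested with a rank partial correlation conditioning on the
#' other cluster members' expression; the target "remains" if the partial
#' correlation stays BH-significant within the RBP x trait family with an
#' unchanged sign. The per-RBP fraction remaining quantifies how much of its
#' apparent regulation is explainable by collinear cluster partners.
#'
#' @param records Correlation records (from [correlate_targets()]); only
#'   rows with `significant == TRUE` are evaluated.
#' @param rbp_expr_matrix RBPs x samples matrix of cluster-member expression
#'   (rownames = RBP ids; must cover the cluster).
#' @param trait_matrix Genes x samples trait matrix.
#' @param cluster Character vector of RBP ids forming the cluster.
#' @param alpha Significance level (default 0.05).
#' @return Tibble per RBP x trait: `rbp_id`, `trait`, `n_significant`,
#'   `n_remaining`, `fraction_remaining` (`NA` when the RBP has no
#'   significant targets). A cluster of one is an identity passthrough
#'   (fraction 1).
#' @export
collinearity_filter <- function(records, rbp_expr_matrix, trait_matrix,
                                cluster, alpha = 0.05) {
  cluster <- intersect(cluster, rownames(rbp_expr_matrix))
  sig <- records |> filter(.data$significant, .data$rbp_id %in% cluster)
  sig |>
    group_by(.data$rbp_id, .data$trait) |>
    group_split() |>
    purrr::map(function(d) {
      rbp <- d$rbp_id[1]; tr <- d$trait[1]
      others <- setdiff(cluster, rbp)
      if (length(others) == 0L) {
        return(tibble(rbp_id = rbp, trait = tr, n_significant = nrow(d),
                      n_remaining = nrow(d), fraction_remaining = 1))
      }
      x <- rbp_expr_matrix[rbp, ]
      zc <- t(rbp_expr_matrix[others, , drop = FALSE])
      part <- purrr::map(d$gene_id, function(g) {
        partial_spearman(x, trait_matrix[g, ], zc)
      }) |> bind_rows()
      p_adj <- adjust_bh(part$p)
      remain <- p_adj <= alpha & sign(part$rho) == sign(d$rho)
      tibble(rbp_id = rbp, trait = tr, n_significant = nrow(d),
             n_remaining = sum(remain, na.rm = TRUE),
             fraction_remaining = if (nrow(d) > 0)
               sum(remain, na.rm = TRUE) / nrow(d) else NA_real_)
    }) |>
    bind_rows()
}
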