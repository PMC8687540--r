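#' Hierarchically cluster RBPs by their target correlation profiles
#'
#' Euclidean distance between the rows of the RBP x target Spearman rho
#' matrix (missing rho treated as 0 for distance purposes), followed by
#' hierarchical clustering; complete linkage by default. Ties in the
#' distance matrix are broken deterministically by row order (the behaviour
#' of [stats::hclust()]).
#'
#' @param rho_matrix RBPs x targets matrix of correlations.
#' @param linkage Linkage method (default `"complete"`).
#' @param k Optional number of flat clusters to cut.
#' @return Object of class `rbp_clustering`: list with the `hclust` tree,
#'   `labels` (flat cluster labels when `k` given), `distance` and `linkage`.
#' @export
cluster_correlations <- function(rho_matrix, linkage = "complete", k = NULL) {
  if (nrow(rho_matrix) < 2L) stop_config("need at least 2 RBP rows to cluster")
  m <- rho_matrix
  m[is.na(m)] <- 0
  tree <- hclust(dist(m, method = "euclidean"), method = linkage)
  labels <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
  structure(list(tree = tree, labels = labels, distance = "euclidean",
                 linkage = linkage),
            class = "rbp_clustering")
}

#' Cluster RBPs by target-set overlap
#'
#' Pairwise distance `1 - Jaccard(target sets)` with average linkage, to
#' group RBPs binding similar regulons.
#'
#' @param target_sets Named list of character vectors (gene ids per RBP).
#' @param linkage Linkage method (default `"average"`).
#' @return An `rbp_clustering` object (distance `"1 - Jaccard"`).
#' @export
cluster_target_overlap <- function(target_sets, linkage = "average") {
  if (length(target_sets) < 2L) stop_config("need at least 2 RBPs")
  if (all(lengths(target_sets) == 0L)) {
    stop_config("all target sets are empty; Jaccard distance undefined")
  }
  n <- length(target_sets)
  d <- matrix(0, n, n, dimnames = list(names(target_sets), names(target_sets)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      un <- length(union(target_sets[[i]], target_sets[[j]]))
      jac <- if (un == 0) 0 else
        length(intersect(target_sets[[i]], target_sets[[j]])) / un
      d[i, j] <- d[j, i] <- 1 - jac
    }
  }
  tree <- hclust(as.dist(d), method = linkage)
  structure(list(tree = tree, labels = NULL, distance = "1 - Jaccard",
                 linkage = linkage),
            class = "rbp_clustering")
}

#' @export
print.rbp_clustering <- function(x, ...) {
  cat(sprintf("RBP clustering: %d leaves, %s distance, %s linkage\n",
              length(x$tree$order), x$distance, x$linkage))
  invisible(x)
}

#' @export
tidy.rbp_clustering <- function(x, ...) {
  tibble(merge1 = x$tree$merge[, 1], merge2 = x$tree$merge[, 2],
         height = x$tree$height)
}

#' @rdname cluster_correlations
#' @param object An `rbp_clustering` object.
#' @param ... Unused.
#' @export
autoplot.rbp_clustering <- function(object, ...) {
  dend <- stats::as.dendrogram(object$tree)
  seg <- dendrogram_segments(dend)
  ggplot(seg) +
    geom_segment(aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend)) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(object$tree$labels[object$tree$order]),
      labels = object$tree$labels[object$tree$order]
    ) +
    labs(x = NULL, y = sprintf("%s linkage height", object$linkage)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# flatten a dendrogram into plottable segments
dendrogram_segments <- function(d) {
  segs <- list()
  walk <- function(node) {
    if (stats::is.leaf(node)) {
      return(tibble(x = attr(node, "x"), y = 0))
    }
    h <- attr(node, "height")
    kids <- purrr::map(seq_along(node), function(i) walk(node[[i]]))
    xs <- purrr::map_dbl(kids, ~ .x$x[1])
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1L]] <<- tibble(x = xs[i], y = kids[[i]]$y[1],
                                           xend = xs[i], yend = h)
    }
    segs[[length(segs) + 1L]] <<- tibble(x = min(xs), y = h,
                                         xend = max(xs), yend = h)
    tibble(x = mean(range(xs)), y = h)
  }
  # assign leaf x positions in plotting order
  leaf_x <- 0
  assign_x <- function(node) {
    if (stats::is.leaf(node)) {
      leaf_x <<- leaf_x + 1
      attr(node, "x") <- leaf_x
      return(node)
    }
    for (i in seq_along(node)) node[[i]] <- assign_x(node[[i]])
    node
  }
  d <- assign_x(d)
  walk(d)
  bind_rows(segs)
}

#' Select each gene's principal isoform
#'
#' The most abundant transcript per gene (highest mean of the supplied
#' abundance proxy), with ties broken by longer mature transcript, then by
#' lexicographic transcript id.
#'
#' @param annotation Annotation tibble.
#' @param tx_abundance Named numeric vector of mean abundance per
#'   `transcript_id` (missing transcripts count as 0).
#' @return Tibble `gene_id`, `transcript_id` of the principal isoform.
#' @export
select_principal_isoform <- function(annotation, tx_abundance) {
  fl <- feature_lengths(annotation)
  if (nrow(fl) == 0L) stop_config("annotation contains no transcripts")
  fl$abundance <- unname(tx_abundance[fl$transcript_id])
  fl$abundance[is.na(fl$abundance)] <- 0
  fl |>
    arrange(.data$gene_id, desc(.data$abundance), desc(.data$tx_len),
            .data$transcript_id) |>
    group_by(.data$gene_id) |>
    slice(1L) |>
    ungroup() |>
    select("gene_id", "transcript_id")
}

# Wilcoxon rank-sum wrapper: exact for small tie-free groups, normal
# approximation with tie correction otherwise.
rank_sum_test <- function(a, b, exact_max = 8L) {
  exact <- min(length(a), length(b)) <= exact_max &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Compare feature lengths between two target groups
#'
#' Two-sided Wilcoxon rank-sum test on a chosen feature length between two
#' gene groups (e.g. an RBP's mRNA targets vs TE targets).
#'
#' @param group_a,group_b Character vectors of gene ids (each >= 3).
#' @param lengths_tbl Tibble from [feature_lengths()] (first transcript per
#'   gene is used).
#' @param feature One of `"utr5"`, `"cds"`, `"utr3"`, `"transcript"`.
#' @return One-row tibble: `feature`, `n_a`, `n_b`, `median_a`, `median_b`,
#'   `W`, `p`.
#' @export
compare_lengths <- function(group_a, group_b, lengths_tbl,
                            feature = c("cds", "utr5", "utr3", "transcript")) {
  feature <- match.arg(feature)
  col <- c(cds = "cds_len", utr5 = "utr5_len", utr3 = "utr3_len",
           transcript = "tx_len")[[feature]]
  one <- lengths_tbl |> group_by(.data$gene_id) |> slice(1L) |> ungroup()
  a <- one[[col]][match(group_a, one$gene_id)]
  b <- one[[col]][match(group_b, one$gene_id)]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop_config("each group needs at least 3 genes with known lengths")
  }
  wt <- rank_sum_test(a, b)
  tibble(feature = feature, n_a = length(a), n_b = length(b),
         median_a = median(a), median_b = median(b), W = wt$W, p = wt$p)
}

#' Length-matched subsampling of gene groups
#'
#' Draws `n_per_group` genes per group, stratified on deciles of the pooled
#' length distribution, so the subsampled groups have closely matched length
#' profiles (e.g. before comparing 5'UTR structure between groups whose
#' lengths are confounded). Every group draws the same per-bin allocation,
#' targeting the pooled distribution but capped by the scarcest group's
#' supply per bin (the excess is reallocated to bins all groups can fill).
#' After sampling, every group pair must show a length Wilcoxon p >
#' `p_floor`; otherwise sampling is repeated (up to `max_attempts`).
#'
#' @param groups Named list of named numeric vectors (`gene_id` -> length).
#' @param n_per_group Genes to draw per group (default 50).
#' @param n_bins Number of pooled-quantile strata (default 10).
#' @param p_floor Minimum pairwise length-balance p (default 0.1).
#' @param max_attempts Resampling attempts (default 100).
#' @param seed Integer seed.
#' @return Named list of character vectors (sampled gene ids per group),
#'   with attribute `balance_p` (smallest pairwise length Wilcoxon p).
#' @export
length_matched_subsample <- function(groups, n_per_group = 50L, n_bins = 10L,
                                     p_floor = 0.1, max_attempts = 100L,
                                     seed = NULL) {
  if (any(lengths(groups) < n_per_group)) {
    stop_config("every group needs at least n_per_group genes")
  }
  pooled <- unlist(unname(groups))
  brk <- unique(quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1)))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  n_b <- length(brk) - 1L
  # every group draws the SAME per-bin allocation, capped by the smallest
  # group's supply in that bin and targeting the pooled length distribution
  w <- tabulate(cut(pooled, brk, labels = FALSE), n_b) / length(pooled)
  group_bins <- purrr::map(groups, ~ cut(.x, brk, labels = FALSE))
  cap <- purrr::map(group_bins, ~ tabulate(.x, n_b)) |>
    (\(x) do.call(pmin, x))()
  if (sum(cap) < n_per_group) {
    stop_config("groups do not share enough length support to balance")
  }
  alloc <- pmin(floor(n_per_group * w), cap)
  while (sum(alloc) < n_per_group) {
    open <- which(alloc < cap)
    b <- open[which.max(w[open] - alloc[open] / n_per_group)]
    alloc[b] <- alloc[b] + 1L
  }

  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      samp <- purrr::imap(groups, function(g, nm) {
        bins <- group_bins[[nm]]
        unlist(lapply(which(alloc > 0L), function(b) {
          avail <- names(g)[bins == b]
          avail[sample.int(length(avail), alloc[b])]
        }))
      })
      ps <- c()
      nms <- names(groups)
      for (i in seq_along(groups)[-1]) {
        for (j in seq_len(i - 1L)) {
          ps <- c(ps, rank_sum_test(groups[[nms[i]]][samp[[nms[i]]]],
                                    groups[[nms[j]]][samp[[nms[j]]]])$p)
        }
      }
      if (all(ps > p_floor)) {
        attr(samp, "balance_p") <- min(ps)
        return(samp)
      }
    }
    warn("length-matched subsampling did not balance within max_attempts; returning last draw")
    attr(samp, "balance_p") <- min(ps)
    samp
  })
}

#' Ubiquitous-expression classification from a tissue TPM table
#'
#' An RBP counts as ubiquitously expressed when its TPM is at or above
#' `high` in strictly more than `min_tissues` tissues; the number of tissues
#' with detectable expression (TPM >= `detect`) is reported alongside.
#'
#' @param tpm Genes x tissues matrix or tibble of tissue-averaged TPM (if a
#'   tibble, a `gene_id` column is used for names).
#' @param detect,high TPM thresholds (defaults 1 and 10).
#' @param min_tissues Strict lower bound on high-expression tissue count
#'   (default 30).
#' @return Tibble: `gene_id`, `n_detected`, `n_high`, `ubiquitous`.
#' @export
classify_ubiquity <- function(tpm, detect = 1, high = 10, min_tissues = 30L) {
  if (is.data.frame(tpm)) {
    ids <- tpm$gene_id
    tpm <- as.matrix(tpm[setdiff(names(tpm), "gene_id")])
    rownames(tpm) <- ids
  }
  if (ncol(tpm) < 1L) stop_config("tissue TPM table needs >= 1 tissue column")
  tibble(
    gene_id = rownames(tpm) %||% as.character(seq_len(nrow(tpm))),
    n_detected = as.integer(rowSums(tpm >= detect)),
    n_high = as.integer(rowSums(tpm >= high)),
    ubiquitous = unname(rowSums(tpm >= high) > min_tissues)
  )
}

#' Compare translational efficiency between two isoforms
#'
#' Two-sided Wilcoxon rank-sum test between the per-sample TE vectors of two
#' isoforms of the same gene.
#'
#' @param te_a,te_b Numeric TE vectors over samples (each >= 3 values).
#' @return One-row tibble: `n_a`, `n_b`, `median_a`, `median_b`, `W`, `p`.
#' @export
compare_isoform_te <- function(te_a, te_b) {
  te_a <- te_a[!is.na(te_a)]; te_b <- te_b[!is.na(te_b)]
  if (length(te_a) < 3L || length(te_b) < 3L) {
    stop_config("each isoform needs at least 3 TE values")
  }
  wt <- rank_sum_test(te_a, te_b)
  tibble(n_a = length(te_a), n_b = length(te_b),
         median_a = median(te_a), median_b = median(te_b),
         W = wt$W, p = wt$p)
}
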