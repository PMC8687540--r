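test_that("correlation clustering merges identical rows first and matches a hand-computed linkage", {
  m <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 3, 0), d = c(0, 0, 5))
  cl <- cluster_correlations(m)
  expect_equal(cl$tree$height[1], 0)     # identical rows merge at height 0
  # complete-linkage agglomeration by hand on the 4-point configuration:
  # d(a,b)=0; d(a,c)=d(b,c)=sqrt(1+9); d(a,d)=d(b,d)=sqrt(1+25);
  # d(c,d)=sqrt(9+25). Merge {a,b} at 0; then {ab,c} at sqrt(10);
  # finally {abc, d} at max(sqrt(26), sqrt(34)) = sqrt(34).
  expect_equal(cl$tree$height, c(0, sqrt(10), sqrt(34)), tolerance = 1e-12)
  expect_true(all(diff(cl$tree$height) >= 0))
  expect_error(cluster_correlations(m[1, , drop = FALSE]),
               class = "rbptraits_config_error")
  # sign-flipped profile is farther than either row is from zero
  m2 <- rbind(x = c(1, -1, 2), y = -c(1, -1, 2), z = c(0, 0, 0))
  d2 <- as.matrix(dist(m2))
  expect_gt(d2["x", "y"], d2["x", "z"])
  expect_gt(d2["x", "y"], d2["y", "z"])
})

test_that("clustering is invariant to row permutation up to labels", {
  set.seed(161)
  m <- matrix(rnorm(8 * 10), nrow = 8, dimnames = list(letters[1:8], NULL))
  c1 <- cluster_correlations(m)
  perm <- sample(8)
  c2 <- cluster_correlations(m[perm, ])
  expect_equal(sort(c1$tree$height), sort(c2$tree$height), tolerance = 1e-12)
  expect_equal(as.matrix(stats::cophenetic(c1$tree))[letters[1:8],
                                                     letters[1:8]],
               as.matrix(stats::cophenetic(c2$tree))[letters[1:8],
                                                     letters[1:8]],
               tolerance = 1e-12)
})

test_that("overlap dendrogram uses 1 - Jaccard distances", {
  sets <- list(A = c("a", "b", "c"), B = c("c", "d"), C = c("a", "b", "c"))
  cl <- cluster_target_overlap(sets)
  expect_equal(cl$tree$height[1], 0)  # A and C identical
  expect_equal(max(cl$tree$height), 0.75)  # 1 - 1/4 between {A,C} and B
  expect_error(cluster_target_overlap(list(A = character(0),
                                           B = character(0))),
               class = "rbptraits_config_error")
  expect_s3_class(autoplot(cl), "ggplot")
})

test_that("principal isoform selection follows abundance, then length, then id", {
  ann <- simulate_annotation(4, n_isoforms = 2, seed = 162)
  fl <- feature_lengths(ann)
  # abundance rules
  ab <- setNames(rep(0, nrow(fl)), fl$transcript_id)
  ab[fl$transcript_id[1]] <- 10; ab[fl$transcript_id[2]] <- 5
  pick <- select_principal_isoform(ann, ab)
  expect_equal(pick$transcript_id[pick$gene_id == fl$gene_id[1]],
               fl$transcript_id[1])
  # tie on abundance: longer transcript wins
  g2 <- fl[fl$gene_id == unique(fl$gene_id)[2], ]
  longer <- g2$transcript_id[which.max(g2$tx_len)]
  pick2 <- select_principal_isoform(ann, setNames(numeric(0), character(0)))
  expect_equal(pick2$transcript_id[pick2$gene_id == g2$gene_id[1]], longer)
})

test_that("length comparisons use the exact rank-sum distribution", {
  lengths_tbl <- tibble::tibble(
    gene_id = paste0("g", 1:6), transcript_id = paste0("t", 1:6),
    utr5_len = 1, cds_len = c(1, 2, 3, 10, 20, 30), utr3_len = 1,
    tx_len = 1)
  out <- compare_lengths(paste0("g", 1:3), paste0("g", 4:6), lengths_tbl)
  expect_equal(out$p, 0.1)  # 2/choose(6,3)
  expect_error(compare_lengths("g1", paste0("g", 4:6), lengths_tbl),
               class = "rbptraits_config_error")
})

test_that("exact Wilcoxon matches enumeration of all rank arrangements", {
  set.seed(163)
  for (i in 1:60) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    repeat {
      a <- round(rnorm(n, 0, 5), 3); b <- round(rnorm(m, 1, 5), 3)
      if (!any(duplicated(c(a, b)))) break
    }
    got <- rbptraits:::rank_sum_test(a, b)
    expect_equal(got$p, wilcox_exact_enum(a, b), tolerance = 1e-10)
  }
})

test_that("length-matched subsampling balances confounded groups deterministically", {
  set.seed(164)
  groups <- list(
    short = setNames(rlnorm(200, log(80), 0.5), paste0("s", 1:200)),
    long = setNames(rlnorm(200, log(200), 0.5), paste0("l", 1:200))
  )
  # the raw groups are strongly length-confounded
  expect_lt(rbptraits:::rank_sum_test(groups$short, groups$long)$p, 1e-10)
  sub <- length_matched_subsample(groups, n_per_group = 50, seed = 7)
  expect_identical(sub, length_matched_subsample(groups, n_per_group = 50,
                                                 seed = 7))
  expect_equal(lengths(sub), c(short = 50L, long = 50L))
  p_bal <- rbptraits:::rank_sum_test(groups$short[sub$short],
                                     groups$long[sub$long])$p
  expect_gt(p_bal, 0.1)
  expect_error(length_matched_subsample(groups, n_per_group = 500),
               class = "rbptraits_config_error")
})

test_that("ubiquity classification enforces the strict tissue-count rule", {
  tpm <- rbind(ubi = c(rep(12, 31), rep(0, 23)),
               edge = c(rep(12, 30), rep(0, 24)),
               silent = rep(0, 54))
  colnames(tpm) <- paste0("t", 1:54)
  out <- classify_ubiquity(tpm)
  expect_equal(out$ubiquitous, c(TRUE, FALSE, FALSE))
  expect_equal(out$n_high, c(31L, 30L, 0L))
  expect_equal(out$n_detected, c(31L, 30L, 0L))
  expect_error(classify_ubiquity(tpm[, 0, drop = FALSE]),
               class = "rbptraits_config_error")
})

test_that("isoform TE comparison recovers a planted offset", {
  expect_equal(compare_isoform_te(c(1, 2, 3), c(10, 20, 30))$p, 0.1)
  expect_equal(compare_isoform_te(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(165)
  te_a <- exp(rnorm(40, 0, 0.3)); te_b <- exp(rnorm(40, 0.6, 0.3))
  expect_lt(compare_isoform_te(te_a, te_b)$p, 0.05)
  expect_error(compare_isoform_te(c(1, 2), c(1, 2, 3)),
               class = "rbptraits_config_error")
})

test_that("splicing generator couples PSI to RBP expression as configured", {
  tc <- tiny_cohort(n_genes = 100, n_samples = 80)
  co <- tc$cohort
  rbp <- "G00002"
  z <- log1p(co$ribo[rbp, ])
  # null coupling: correlations centered at zero
  j0 <- simulate_splicing(co$truth, tc$annotation, rbp, z, coupling = 0,
                          n_exons = 15, seed = 166)
  psi0 <- compute_psi(j0)
  rh0 <- vapply(split(psi0, psi0$exon_id), function(d)
    cor_spearman(d$psi, z[match(d$sample_id, names(z))])$rho, numeric(1))
  expect_lt(abs(mean(rh0, na.rm = TRUE)), 0.15)
  # strong negative coupling with heavy coverage: monotone decreasing PSI
  j1 <- simulate_splicing(co$truth, tc$annotation, rbp, z, coupling = -1,
                          n_exons = 3, mean_coverage = 5e4, seed = 167)
  p1 <- compute_psi(j1)
  d <- p1[p1$exon_id == p1$exon_id[1], ]
  ord <- order(z[match(d$sample_id, names(z))])
  expect_lt(cor_spearman(d$psi[ord], seq_along(ord))$rho, -0.95)
  # recovery at the study coupling
  j2 <- simulate_splicing(co$truth, tc$annotation, rbp, z, coupling = 0.8,
                          n_exons = 20, seed = 168)
  p2 <- compute_psi(j2)
  rh2 <- vapply(split(p2, p2$exon_id), function(d)
    cor_spearman(d$psi, z[match(d$sample_id, names(z))])$rho, numeric(1))
  expect_gte(mean(rh2 >= 0.6, na.rm = TRUE), 0.9)
  expect_error(
    simulate_splicing(co$truth, tc$annotation, rbp, z, coupling = 0.5,
                      exons = tibble::tibble(gene_id = "G00001",
                                             exon_id = "nope")),
    class = "rbptraits_config_error")
})
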