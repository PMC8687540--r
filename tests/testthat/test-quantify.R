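test_that("median-of-ratios size factors reproduce hand-computed values", {
  m <- matrix(c(2, 4, 2, 4, 2, 4), nrow = 3, byrow = TRUE)
  expect_equal(estimate_size_factors(m), c(2 / sqrt(8), 4 / sqrt(8)),
               tolerance = 1e-6, ignore_attr = TRUE)
  ident <- matrix(5, nrow = 4, ncol = 3)
  expect_equal(unname(estimate_size_factors(ident)), rep(1, 3))
})

test_that("size factors are scale-equivariant and permutation-invariant", {
  set.seed(101)
  m <- matrix(rpois(200, 50), nrow = 20)
  nlib <- ncol(m)
  sf <- estimate_size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  sf2 <- estimate_size_factors(m2)
  # scaling one library rescales the geometric-mean reference of every gene
  # by c^(1/m), so the exact equivariance is: the scaled library's factor
  # grows by c and all others shrink by the common reference shift
  shift <- 4^(1 / nlib)
  expect_equal(unname(sf2[3]), unname(sf[3]) * 4 / shift, tolerance = 1e-12)
  expect_equal(unname(sf2[-3]), unname(sf[-3]) / shift, tolerance = 1e-12)
  # relative factors between untouched libraries are untouched
  expect_equal(sf2[1] / sf2[2], sf[1] / sf[2], tolerance = 1e-12)
  perm <- c(5, 1, 7, 3, 9, 2, 10, 8, 6, 4)
  expect_equal(unname(estimate_size_factors(m[, perm])), unname(sf[perm]))
})

test_that("size factors agree with the DESeq2 estimator", {
  # odd gene count: the arithmetic median of ratios and DESeq2's log-space
  # median pick the same middle element exactly
  set.seed(102)
  m <- matrix(rnbinom(610, mu = 100, size = 5), nrow = 61)
  colnames(m) <- paste0("s", 1:10)
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("all-zero-containing genes leave no reference and raise an error", {
  m <- matrix(c(0, 5, 3, 0), nrow = 2)
  expect_error(estimate_size_factors(m), "median-of-ratios")
})

test_that("normalization divides by the factor and validates input", {
  m <- matrix(c(2, 4), nrow = 1)
  out <- normalize_counts(m, c(1 / sqrt(2), sqrt(2)))
  expect_equal(as.numeric(out), c(2.8284271, 2.8284271), tolerance = 1e-6)
  expect_error(normalize_counts(m, c(0, 1)), class = "rbptraits_config_error")
  empty <- matrix(numeric(0), nrow = 0, ncol = 0)
  expect_identical(normalize_counts(empty, numeric(0)), empty)
})

test_that("FPKM follows its defining arithmetic", {
  m <- matrix(c(100, 0), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  out <- compute_fpkm(m, lengths = c(1000, 500), library_totals = 1e6)
  expect_equal(out["a", 1], 100)
  expect_equal(out["b", 1], 0)
  # doubling length halves FPKM
  out2 <- compute_fpkm(m, lengths = c(2000, 500), library_totals = 1e6)
  expect_equal(out2["a", 1], 50)
  expect_error(compute_fpkm(m, c(1000, 0)), class = "rbptraits_config_error")
})

test_that("expression filter enforces both evidence rules strictly", {
  n <- 25
  rna <- matrix(1, nrow = 3, ncol = n,
                dimnames = list(c("pass", "few", "lowfpkm"), NULL))
  ribo <- rna
  rna["few", 20:n] <- 0   # nonzero in only 19 samples
  fpkm <- matrix(2, nrow = 3, ncol = n, dimnames = dimnames(rna))
  fpkm["lowfpkm", ] <- 1  # mean exactly 1: excluded by strict >
  kept <- filter_expressed(fpkm, rna, ribo, min_mean_fpkm = 1,
                           min_samples = 20)
  expect_identical(kept, "pass")
  # idempotence: filtering the retained set keeps it
  kept2 <- filter_expressed(fpkm[kept, , drop = FALSE],
                            rna[kept, , drop = FALSE],
                            ribo[kept, , drop = FALSE], 1, 20)
  expect_identical(kept2, kept)
  expect_error(filter_expressed(fpkm, rna, ribo, min_samples = n + 1),
               class = "rbptraits_config_error")
})

test_that("TE is the ribo/rna ratio with missing at zero RNA", {
  ribo <- matrix(c(10, 4), nrow = 1)
  rna <- matrix(c(5, 0), nrow = 1)
  te <- compute_te(ribo, rna)
  expect_equal(te[1, 1], 2)
  expect_true(is.na(te[1, 2]))
  # joint per-sample rescaling cancels
  te2 <- compute_te(ribo * 3, rna * 3)
  expect_equal(te2[1, 1], te[1, 1])
  expect_error(compute_te(ribo, matrix(1, 2, 2)),
               class = "rbptraits_config_error")
})

test_that("PSI follows the averaged-inclusion formula with a coverage floor", {
  j <- tibble::tibble(gene_id = "g", exon_id = "e",
                      sample_id = c("a", "b", "c"),
                      ij_up = c(8, 10, 1), ij_down = c(12, 10, 1),
                      ej = c(10, 0, 2))
  out <- compute_psi(j, min_total = 10)
  expect_equal(out$psi, c(0.5, 1.0, NA_real_))
  # full inclusion below the floor is callable once the floor allows it
  expect_equal(compute_psi(j[3, ], min_total = 3)$psi, 1 / 3)
  expect_error(compute_psi(dplyr::mutate(j, ej = c(-1, 0, 2))),
               class = "rbptraits_config_error")
})

test_that("PSI is monotone in inclusion and exclusion counts and bounded", {
  set.seed(103)
  base <- tibble::tibble(gene_id = "g", exon_id = "e", sample_id = "s",
                         ij_up = 20, ij_down = 30, ej = 25)
  p0 <- compute_psi(base)$psi
  expect_gt(compute_psi(dplyr::mutate(base, ij_up = 40))$psi, p0)
  expect_lt(compute_psi(dplyr::mutate(base, ej = 50))$psi, p0)
  rand <- tibble::tibble(gene_id = "g", exon_id = "e",
                         sample_id = as.character(1:200),
                         ij_up = rpois(200, 20), ij_down = rpois(200, 20),
                         ej = rpois(200, 20))
  psi <- compute_psi(rand)$psi
  expect_true(all(is.na(psi) | (psi >= 0 & psi <= 1)))
})
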