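test_that("information content follows p*log2(p/q)", {
  # equal fractions: zero information
  expect_equal(peak_information_content(9, 9, 1000, 1000), 0)
  # IP fraction 4x input: 0.004 * log2(4) = 0.008 (pseudocount-free form)
  expect_equal(peak_information_content(4, 1, 1000, 1000, pseudocount = 0),
               0.004 * 2)
  # depleted peak: negative information
  expect_lt(peak_information_content(0, 50, 1000, 1000), 0)
  expect_error(peak_information_content(-1, 0, 10, 10),
               class = "rbptraits_config_error")
})

test_that("fold change and binomial enrichment p match brute-force tails", {
  pe <- peak_enrichment(20, 5, 1000, 1000, pseudocount = 0)
  expect_equal(pe$fc, 4.0)
  # exhaustive tail sum of the binomial pmf
  oracle <- sum(dbinom(20:1000, 1000, 5 / 1000))
  expect_equal(pe$p, oracle, tolerance = 1e-10)
  expect_equal(peak_enrichment(5, 5, 1000, 1000, pseudocount = 0)$fc, 1)
  expect_error(peak_enrichment(1, 1, 0, 10), class = "rbptraits_config_error")
})

test_that("IDR separates reproducible from irreproducible peaks", {
  set.seed(111)
  strong <- rnorm(60, 5, 0.4); weak <- rnorm(60, 0, 0.4)
  s1 <- c(strong, weak)
  s2 <- s1 + rnorm(120, 0, 0.1)
  idr <- compute_idr(s1, s2)
  expect_true(all(idr[1:60] < 0.01))
  # independently shuffled replicate: mostly irreproducible
  idr_shuf <- compute_idr(s1, sample(s1))
  expect_gt(median(idr_shuf), 0.5)
  expect_error(compute_idr(rep(1, 30), rnorm(30)), "constant")
  expect_error(compute_idr(rnorm(10), rnorm(10)), "at least 20")
})

test_that("median IDR never decreases with added rank discordance", {
  set.seed(112)
  s1 <- c(rnorm(60, 4, 0.5), rnorm(60, 0, 0.5))
  meds <- vapply(c(0, 0.3, 0.6, 1), function(frac) {
    s2 <- s1 + rnorm(120, 0, 0.1)
    k <- round(frac * 120)
    if (k >= 2) {
      idx <- sample(120, k)
      s2[idx] <- s2[sample(idx)]
    }
    median(compute_idr(s1, s2))
  }, numeric(1))
  expect_true(all(diff(meds) >= -0.05))
  expect_gt(meds[4], meds[1])
})

test_that("peak filter honors the strictness of each threshold exactly", {
  peaks <- tibble::tibble(
    idr = c(0.009, 0.01, 0.009, 0.009, 0.5),
    p   = c(1e-5, 1e-6, 2e-5, 1e-6, 1e-9),
    fc  = c(8.1, 9, 9, 8.0, 100),
    id  = c("keep", "idr_at_cut", "p_above", "fc_at_cut", "idr_high")
  )
  kept <- filter_peaks(peaks)
  expect_identical(kept$id, "keep")
})

test_that("pooling keeps the most significant peak per overlap component", {
  pk <- tibble::tibble(
    chrom = "c", strand = "+",
    start = c(0, 40, 80, 200, 500),
    end   = c(50, 90, 130, 260, 550),
    p     = c(1e-6, 1e-8, 1e-4, 1e-6, 1e-2),
    ic    = c(1, 2, 3, 1, 1),
    id    = c("a", "b", "c", "d", "e")
  )
  pooled <- pool_peaks(pk)
  # chain a-b-c is one single-linkage component; b has the smallest p
  expect_setequal(pooled$id, c("b", "d", "e"))
  # idempotent
  expect_identical(pool_peaks(pooled), pooled)
  # tie on p resolved by larger information content
  tie <- tibble::tibble(chrom = "c", strand = "+",
                        start = c(0, 10), end = c(30, 40),
                        p = c(1e-6, 1e-6), ic = c(1, 5), id = c("lo", "hi"))
  expect_identical(pool_peaks(tie)$id, "hi")
  bad <- tibble::tibble(chrom = "c", strand = "+", start = 10, end = 10,
                        p = 1, ic = 1)
  expect_error(pool_peaks(bad), class = "rbptraits_config_error")
})

test_that("target assignment respects strand and midpoint region priority", {
  ann <- simulate_annotation(1, length_params = fixed_length_params(),
                             seed = 121)
  # forced single-exon plus-or-minus strand transcript starting at 1000
  cds <- ann[ann$type == "CDS", ]
  utr5 <- ann[ann$type == "five_prime_utr", ]
  mk_peak <- function(center, strand, rbp = "R1") {
    tibble::tibble(chrom = "chrS1", start = center - 10L, end = center + 10L,
                   strand = strand, rbp_id = rbp)
  }
  cds_mid <- as.integer((cds$start + cds$end) / 2)
  sense <- ann$strand[1]
  anti <- setdiff(c("+", "-"), sense)
  tg <- assign_targets(mk_peak(cds_mid, sense), ann)
  expect_equal(tg$gene_id, "G00001")
  expect_equal(tg$prop_cds, 1)
  # antisense peak is not a target
  tg2 <- assign_targets(mk_peak(cds_mid, anti), ann)
  expect_equal(nrow(tg2), 0L)
  # two CDS + two intron-free UTR peaks split proportions
  utr_mid <- as.integer((utr5$start + utr5$end) / 2)
  pk <- dplyr::bind_rows(mk_peak(cds_mid, sense), mk_peak(cds_mid + 2L, sense),
                         mk_peak(utr_mid, sense), mk_peak(utr_mid + 2L, sense))
  tg3 <- assign_targets(pk, ann)
  expect_equal(tg3$prop_cds, 0.5)
  expect_equal(tg3$prop_utr5, 0.5)
  expect_equal(tg3$n_peaks, 4L)
  # unknown chromosome: warning and skip
  expect_warning(
    out <- assign_targets(
      tibble::tibble(chrom = "chrX", start = 1, end = 10, strand = "+",
                     rbp_id = "R1"), ann),
    "skipped")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("intronic peaks are classified as intron binding", {
  # multi-exon gene: find an intron gap
  ann <- simulate_annotation(30, seed = 122)
  ex <- ann[ann$type == "exon", ]
  multi <- names(which(table(ex$transcript_id) >= 2))[1]
  sub <- ex[ex$transcript_id == multi, ]
  sub <- sub[order(sub$start), ]
  gap_mid <- as.integer((sub$end[1] + sub$start[2]) / 2)
  g <- ann$gene_id[ann$transcript_id == multi][1]
  pk <- tibble::tibble(chrom = sub$seqnames[1], start = gap_mid - 5L,
                       end = gap_mid + 5L, strand = sub$strand[1],
                       rbp_id = "R1")
  tg <- assign_targets(pk, ann)
  expect_equal(tg$gene_id, g)
  expect_equal(tg$prop_intron, 1)
})
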