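test_that("Spearman handles monotone, antitone and small-n cases", {
  x <- 1:12
  expect_equal(cor_spearman(x, x^3)$rho, 1)
  expect_equal(cor_spearman(x, -exp(x))$rho, -1)
  r <- cor_spearman(c(1, 2, 3), c(2, 1, 3), min_pairs = 3)
  expect_equal(r$rho, 0.5)  # 1 - 6*2/(3*8)
  # too few pairs gives a reasoned missing record
  r2 <- cor_spearman(1:5, c(1, NA, NA, NA, NA))
  expect_true(is.na(r2$rho))
  expect_equal(r2$reason, "too_few_pairs")
})

test_that("Spearman equals rank-then-Pearson on random vectors to 1e-12", {
  set.seed(131)
  for (i in 1:400) {
    n <- sample(10:30, 1)
    x <- sample(1:8, n, replace = TRUE)  # ties on purpose
    y <- rnorm(n)
    got <- cor_spearman(x, y)$rho
    want <- pearson_sums(midranks(x), midranks(y))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Spearman p-values: t approximation and exact permutation null", {
  set.seed(132)
  x <- rnorm(20); y <- rnorm(20)
  r <- cor_spearman(x, y)
  tt <- r$rho * sqrt((20 - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tt), 18), tolerance = 1e-12)
  # exact permutation for n < 10: brute-force all 5! arrangements
  x5 <- c(3, 1, 4, 1, 5); y5 <- c(9, 2, 6, 5, 3)
  r5 <- cor_spearman(x5, y5, min_pairs = 5)
  perms <- rbptraits:::all_permutations(5)
  rho_all <- apply(perms, 1, function(pm)
    pearson_sums(midranks(x5), midranks(y5)[pm]))
  expect_equal(r5$p, mean(abs(rho_all) >= abs(r5$rho) - 1e-12),
               tolerance = 1e-12)
})

test_that("vectorized Spearman matches the scalar path, with and without NAs", {
  set.seed(133)
  Y <- matrix(rnorm(15 * 40), nrow = 15,
              dimnames = list(paste0("g", 1:15), NULL))
  Y[2, 5] <- NA; Y[7, c(1, 9)] <- NA
  x <- rnorm(40)
  fast <- spearman_vs_matrix(x, Y)
  for (i in 1:15) {
    slow <- cor_spearman(x, Y[i, ])
    expect_equal(fast$rho[i], slow$rho, tolerance = 1e-12)
    expect_equal(fast$p[i], slow$p, tolerance = 1e-12)
    expect_equal(fast$n[i], slow$n)
  }
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(134)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_equal(adjust_bh(p), bh_direct(p), tolerance = 1e-12)
  }
  # permutation invariance
  p <- runif(20)
  perm <- sample(20)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "rbptraits_config_error")
})

test_that("correlate_targets flags noise-free monotone targets and controls the null", {
  x <- as.numeric(1:40)
  Y <- rbind(a = x^2, b = -x, c = 2 * x + 100)
  rec <- correlate_targets(x, Y, c("a", "b", "c"))
  expect_true(all(rec$significant))
  expect_equal(abs(rec$rho), rep(1, 3))
  # permuted labels: significant fraction within the binomial envelope
  set.seed(135)
  n_t <- 300
  Yn <- matrix(rnorm(n_t * 40), nrow = n_t,
               dimnames = list(paste0("g", 1:n_t), NULL))
  recn <- correlate_targets(rnorm(40), Yn, rownames(Yn))
  frac <- mean(recn$significant)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_t))
  # empty target set
  expect_equal(nrow(correlate_targets(x, Y, character(0))), 0L)
})

test_that("partial correlation matches the first-order closed form", {
  set.seed(136)
  for (i in 1:50) {
    n <- 30
    z <- rnorm(n)
    x <- 0.6 * z + rnorm(n)
    y <- -0.4 * z + rnorm(n)
    got <- partial_spearman(x, y, z)
    rxy <- cor(rank(x), rank(y)); rxz <- cor(rank(x), rank(z))
    ryz <- cor(rank(y), rank(z))
    want <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(got$rho, want, tolerance = 1e-10)
  }
  # independence from z returns the marginal association
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.2); z <- rnorm(50)
  expect_gt(partial_spearman(x, y, z)$rho, 0.9)
  # conditioning on y itself explains everything
  expect_lt(abs(partial_spearman(x, y, y)$rho), 1e-6)
  expect_error(partial_spearman(rnorm(5), rnorm(5), matrix(rnorm(15), 5)),
               class = "rbptraits_config_error")
})

test_that("Fisher Z comparison matches its closed form and is antisymmetric", {
  out <- fisher_z_test(0.5, 53, 0.3, 53)
  expect_equal(out$z, (atanh(0.5) - atanh(0.3)) / 0.2, tolerance = 1e-4)
  expect_equal(out$z, 1.199, tolerance = 1e-3)
  same <- fisher_z_test(0.4, 30, 0.4, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  flip <- fisher_z_test(0.3, 53, 0.5, 53)
  expect_equal(flip$z, -out$z)
  expect_error(fisher_z_test(1, 10, 0.5, 10), class = "rbptraits_config_error")
})

test_that("collinearity filter zeroes out a duplicated RBP's contribution", {
  set.seed(137)
  n <- 60
  z <- rnorm(n)
  expr <- rbind(R1 = z + rnorm(n, 0, 0.05),
                R2 = z + rnorm(n, 0, 0.05),   # near-copy of R1
                R3 = rnorm(n))                 # independent
  targets <- t(sapply(1:30, function(i) z * 1.2 + rnorm(n, 0, 0.4)))
  rownames(targets) <- paste0("g", 1:30)
  indep_targets <- t(sapply(1:30, function(i)
    expr["R3", ] * 1.2 + rnorm(n, 0, 0.4)))
  rownames(indep_targets) <- paste0("h", 1:30)
  tm <- rbind(targets, indep_targets)
  recs <- dplyr::bind_rows(
    correlate_targets(expr["R1", ], tm, rownames(targets), rbp_id = "R1",
                      trait = "TE"),
    correlate_targets(expr["R3", ], tm, rownames(indep_targets),
                      rbp_id = "R3", trait = "TE")
  )
  out <- collinearity_filter(recs, expr, tm, cluster = c("R1", "R2", "R3"))
  r1 <- out$fraction_remaining[out$rbp_id == "R1"]
  r3 <- out$fraction_remaining[out$rbp_id == "R3"]
  expect_lt(r1, 0.2)   # explained away by its near-copy R2
  expect_gt(r3, 0.8)   # independent RBP survives conditioning
  # a cluster of one is a passthrough
  solo <- collinearity_filter(recs[recs$rbp_id == "R3", ], expr, tm, "R3")
  expect_equal(solo$fraction_remaining, 1)
})
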