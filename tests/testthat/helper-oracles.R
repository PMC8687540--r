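# Independent oracles used across tests. These deliberately re-derive each
# quantity by brute force (enumeration, closed form, first-principles sums)
# rather than calling the implementation under test.

# Pearson correlation from first-principles sums.
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Midranks computed by explicit tie-group averaging.
midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Benjamini-Hochberg from the direct definition:
# p_adj(i) = min over j with rank(j) >= rank(i) of p(j) * m / rank(j), cap 1.
bh_direct <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(p[r >= r[i]] * m / r[r >= r[i]]))
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
wilcox_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  sets <- combn(n + m, n)
  u_all <- apply(sets, 2L, function(idx) sum(rk[idx]) - n * (n + 1) / 2)
  if (u_obs > n * m / 2) {
    min(1, 2 * mean(u_all >= u_obs))
  } else {
    min(1, 2 * mean(u_all <= u_obs))
  }
}

# Exhaustive enumeration of all nested RNA structures (explicit pair lists)
# and the minimum of their summed pair energies.
pair_e <- function(a, b) {
  key <- paste0(a, b)
  e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  if (key %in% names(e)) unname(e[[key]]) else 0
}

enum_mfe <- function(seq, min_loop = 3L) {
  s <- strsplit(seq, "")[[1]]
  best <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    # enumerate: j unpaired, or j paired with any admissible k
    vals <- best(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      e <- pair_e(s[k], s[j])
      if (e == 0) next
      left <- if (k > i) best(i, k - 1L) else 0
      inside <- if (k + 1L <= j - 1L) best(k + 1L, j - 1L) else 0
      vals <- c(vals, left + e + inside)
    }
    min(vals)
  }
  if (length(s) == 0L) return(0)
  best(1L, length(s))
}

revcomp_rna <- function(seq) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
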