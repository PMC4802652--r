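# Independent brute-force oracles, deliberately coded differently from the
# package implementations they check.

# Per-point multivariate Gaussian log-density, summed: explicit inverse and
# log-determinant, one quadratic form per row (no Cholesky).
oracle_gauss_log_sum <- function(members, mu, sigma) {
  members <- as.matrix(members)
  q <- length(mu)
  inv <- solve(sigma)
  ld <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
  total <- 0
  for (r in seq_len(nrow(members))) {
    dev <- members[r, ] - mu
    total <- total - 0.5 * (q * log(2 * pi) + ld +
                              drop(t(dev) %*% inv %*% dev))
  }
  total
}

# Adjusted Rand Index by explicit pair counting (agreement table over all
# n*(n-1)/2 pairs), using the 2(ad-bc) identity rather than the contingency
# table form.
oracle_ari_pairs <- function(p1, p2) {
  n <- length(p1)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s1 <- p1[i] == p1[j]
      s2 <- p2[i] == p2[j]
      if (s1 && s2) a <- a + 1
      else if (s1 && !s2) b <- b + 1
      else if (!s1 && s2) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  2 * (a * d - b * cc) / den
}

# Small well-separated two-blob dataset for clustering sanity checks.
make_two_blobs <- function(n_per = 30L, sep = 20, d = 10L, seed = 42L) {
  set.seed(seed)
  centers <- rbind(rep(0, d), c(rep(sep, 2), rep(0, d - 2)))
  labels <- rep(1:2, each = n_per)
  x <- centers[labels, ] + matrix(rnorm(2 * n_per * d), 2 * n_per, d)
  rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("g%02d", seq_len(d))
  list(x = x, labels = labels)
}

# Minimal stand-in hierarchy holding given per-level partitions, for
# consensus tests that only need partition_at().
fake_hierarchy <- function(partitions_by_k, n) {
  k_init <- max(as.integer(names(partitions_by_k)))
  m <- matrix(1L, n, k_init, dimnames = list(NULL, paste0("k=", seq(k_init, 1))))
  for (k in names(partitions_by_k)) {
    m[, paste0("k=", k)] <- partitions_by_k[[k]]
  }
  structure(list(assignments = m, n = n, k_init = k_init),
            class = "pcah_hierarchy")
}
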