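test_that("pooled moments are exact size-weighted convex combinations", {
  pm <- pooled_moments(3, c(0, 0), diag(2), 1, c(4, 0), diag(2))
  expect_equal(pm$mean, c(1, 0))
  expect_equal(pm$cov, diag(2))

  m <- c(2.5, -1); s <- matrix(c(2, 0.3, 0.3, 1), 2)
  pm2 <- pooled_moments(7, m, s, 12, m, s)
  expect_equal(pm2$mean, m)
  expect_equal(pm2$cov, s)

  pm3 <- pooled_moments(5, c(0, 0, 0), diag(3), 5, c(1, 1, 1), 3 * diag(3))
  expect_equal(pm3$cov, 2 * diag(3))
  # pooled mean sits on the segment between the two centroids
  expect_equal(pm3$mean, 0.5 * c(0, 0, 0) + 0.5 * c(1, 1, 1))

  expect_error(pooled_moments(3, c(0, 0), diag(2), 2, c(1, 1, 1), diag(3)),
               class = "pcah_invalid_input")
  expect_error(pooled_moments(0, c(0), diag(1), 1, c(1), diag(1)),
               class = "pcah_invalid_input")
})

test_that("merge log score matches the Gaussian density oracle", {
  # a single member at the mode of a standard 2-D Gaussian
  expect_equal(merge_log_score(matrix(c(1, 2), 1), c(1, 2), diag(2)),
               -log(2 * pi), tolerance = 1e-12)

  # translation invariance
  set.seed(7)
  pts <- matrix(rnorm(24), 8, 3)
  mu <- colMeans(pts)
  sigma <- cov(pts) + 0.1 * diag(3)
  shift <- c(100, -3, 7)
  expect_equal(merge_log_score(pts, mu, sigma),
               merge_log_score(sweep(pts, 2, -shift), mu + shift, sigma),
               tolerance = 1e-8)

  # brute-force per-point oracle, including the ridge
  for (i in 1:5) {
    set.seed(100 + i)
    p <- matrix(rnorm(30), 10, 3)
    m <- rnorm(3)
    a <- matrix(rnorm(9), 3)
    s <- crossprod(a) + 0.05 * diag(3)
    ridge <- 1e-4
    expect_equal(merge_log_score(p, m, s, ridge = ridge),
                 oracle_gauss_log_sum(p, m, s + ridge * diag(3)),
                 tolerance = 1e-8)
    expect_equal(merge_log_score(p, m, s, ridge = ridge, mode = "mean"),
                 merge_log_score(p, m, s, ridge = ridge) / nrow(p),
                 tolerance = 1e-10)
  }

  # a hard zero covariance is flagged as degenerate
  expect_error(merge_log_score(matrix(0, 2, 2), c(0, 0), matrix(0, 2, 2)),
               class = "pcah_numerical_degeneracy")
})

test_that("pair scoring enumerates all pairs and ignores cluster labelling order", {
  set.seed(5)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- compute_scores(x, 4)
  st2 <- initialise_clusters(y, 5, seed = 1)
  cands <- score_all_pairs(st2, y, ridge = 1e-6)
  expect_length(cands, 10L)
  pairs <- t(vapply(cands, `[[`, numeric(2), "pair"))
  expect_true(all(pairs[, 1] < pairs[, 2]))

  y1 <- compute_scores(x, 1)
  st1 <- initialise_clusters(y1, 2, seed = 1)
  expect_length(score_all_pairs(st1, y1, ridge = 1e-6), 1L)

  # relabelling clusters permutes the pairs but not the multiset of scores
  perm <- c(3L, 5L, 1L, 2L, 4L)
  st_perm <- st2
  st_perm$assignment <- perm[st2$assignment]
  ord <- order(perm)
  st_perm$sizes <- st2$sizes[ord]
  st_perm$centroids <- st2$centroids[ord, , drop = FALSE]
  st_perm$covariances <- st2$covariances[ord]
  cands_perm <- score_all_pairs(st_perm, y, ridge = 1e-6)
  expect_equal(sort(vapply(cands_perm, `[[`, numeric(1), "log_score")),
               sort(vapply(cands, `[[`, numeric(1), "log_score")),
               tolerance = 1e-10)
})

test_that("merge selection takes the argmax (smallest pair on ties) and samples by weight", {
  cand <- function(i, j, ls) list(pair = c(i, j), pooled_mean = 0,
                                  pooled_cov = diag(1), log_score = ls)
  cs <- list(cand(1, 2, -5), cand(1, 3, -1), cand(2, 3, -9))
  expect_equal(select_merge(cs, "max")$pair, c(1, 3))
  expect_equal(select_merge(cs[1], "max")$pair, c(1, 2))
  expect_equal(select_merge(cs[1], "sample")$pair, c(1, 2))

  tied <- list(cand(1, 2, -2), cand(1, 3, -2))
  expect_equal(select_merge(tied, "max")$pair, c(1, 2))

  # sampling frequencies approach the normalised weights (1:3)
  two <- list(cand(1, 2, log(1)), cand(1, 3, log(3)))
  set.seed(99)
  draws <- replicate(10000, select_merge(two, "sample")$pair[2])
  p_hat <- mean(draws == 3)
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(p_hat - 0.75), 3 * se)

  expect_error(select_merge(list(), "max"), class = "pcah_invalid_input")
})

test_that("k-means initialisation separates obvious groups and handles edge cases", {
  blobs <- make_two_blobs(n_per = 15, sep = 100, d = 4, seed = 3)
  y <- compute_scores(blobs$x, 1)
  st <- initialise_clusters(y, 2, seed = 1)
  expect_equal(adjusted_rand_index(st$assignment, blobs$labels), 1)
  expect_equal(sum(st$sizes), 30L)
  # centroids equal member means; covariances are symmetric PSD
  for (i in 1:2) {
    rows <- y$scores[st$assignment == i, , drop = FALSE]
    expect_equal(st$centroids[i, ], colMeans(rows), tolerance = 1e-10,
                 ignore_attr = TRUE)
    ev <- eigen(st$covariances[[i]], symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))
  }

  # K = n: every cluster a singleton with a zero covariance
  set.seed(8)
  xs <- matrix(rnorm(6 * 5), 6, 5)
  ys <- compute_scores(xs, 5)
  st_n <- initialise_clusters(ys, 6, seed = 2)
  expect_equal(sort(st_n$sizes), rep(1L, 6))
  expect_equal(st_n$covariances[[1]], matrix(0, 5, 5), ignore_attr = TRUE)

  expect_error(initialise_clusters(ys, 7, seed = 1),
               class = "pcah_invalid_parameter")
  expect_error(initialise_clusters(ys, 4, seed = 1),  # q mismatch
               class = "pcah_invalid_parameter")
})

test_that("applying a merge conserves membership and drops one dimension", {
  set.seed(13)
  x <- matrix(rnorm(30 * 8), 30, 8)
  y <- compute_scores(x, 3)
  st <- initialise_clusters(y, 4, seed = 1)
  cands <- score_all_pairs(st, y, ridge = 1e-6)
  ch <- select_merge(cands, "max")
  res <- apply_merge(st, ch, y)
  expect_equal(res$state$k, 3L)
  expect_equal(res$state$q_cur, 2L)
  expect_equal(res$y$q, 2L)
  expect_equal(sum(res$state$sizes), 30L)
  i <- ch$pair[1]; j <- ch$pair[2]
  merged_size <- st$sizes[i] + st$sizes[j]
  expect_true(merged_size %in% res$state$sizes)
  # merged centroid is the pooled mean restricted to surviving dimensions,
  # which equals the exact mean of the union
  members <- res$y$scores[res$state$assignment ==
                            match(i, setdiff(1:4, j)), , drop = FALSE]
  expect_equal(res$state$centroids[match(i, setdiff(1:4, j)), ],
               colMeans(members), tolerance = 1e-10, ignore_attr = TRUE)

  # stale candidate (cluster index out of range) is rejected
  bad <- ch; bad$pair <- c(3, 5)
  expect_error(apply_merge(st, bad, y), class = "pcah_invariant_violation")

  # final merge of two clusters keeps the last dimension
  y1 <- compute_scores(x, 1)
  st1 <- initialise_clusters(y1, 2, seed = 1)
  ch1 <- select_merge(score_all_pairs(st1, y1, ridge = 1e-6), "max")
  res1 <- apply_merge(st1, ch1, y1)
  expect_equal(res1$state$k, 1L)
  expect_equal(res1$state$q_cur, 1L)
  expect_equal(res1$state$sizes, 30L)
})

test_that("a full run yields a nested hierarchy on the k-1 dimension schedule", {
  set.seed(17)
  x <- matrix(rnorm(40 * 12), 40, 12)
  rownames(x) <- sprintf("c%02d", 1:40)
  h <- pcah_run(x, k_init = 10, strategy = "max", seed = 4)

  expect_s3_class(h, "pcah_hierarchy")
  expect_equal(ncol(h$assignments), 10L)
  for (k in 10:1) {
    expect_equal(length(unique(partition_at(h, k))), k)
  }
  expect_equal(unname(partition_at(h, 1)), rep(1L, 40))

  # nesting: level k arises from level k+1 by uniting exactly one pair
  for (k in 9:1) {
    fine <- partition_at(h, k + 1)
    coarse <- partition_at(h, k)
    mapping <- tapply(coarse, fine, unique)
    expect_true(all(lengths(mapping) == 1))      # no cluster is split
    expect_equal(sum(duplicated(unlist(mapping))), 1L)  # exactly one union
  }

  # dimension schedule: each merge at k clusters is scored in k-1 dimensions
  expect_equal(h$merge_trace$dim, h$merge_trace$level - 1L)
  expect_equal(h$merge_trace$level, 10:2)
})

test_that("runs are reproducible and recover well-separated blobs", {
  blobs <- make_two_blobs(n_per = 30, sep = 20, d = 10, seed = 1)
  for (seed in 1:10) {
    h <- pcah_run(blobs$x, k_init = 6, strategy = "max", seed = seed)
    expect_equal(adjusted_rand_index(partition_at(h, 2), blobs$labels), 1)
  }

  # identical seeds give identical hierarchies, for both strategies
  h1 <- pcah_run(blobs$x, k_init = 6, strategy = "max", seed = 2)
  h2 <- pcah_run(blobs$x, k_init = 6, strategy = "max", seed = 2)
  expect_identical(h1$assignments, h2$assignments)
  expect_identical(h1$merge_trace, h2$merge_trace)
  s1 <- pcah_run(blobs$x, k_init = 6, strategy = "sample", seed = 3)
  s2 <- pcah_run(blobs$x, k_init = 6, strategy = "sample", seed = 3)
  expect_identical(s1$assignments, s2$assignments)

  expect_error(pcah_run(blobs$x, k_init = 61), class = "pcah_invalid_parameter")
})

test_that("permuting the cells permutes every level identically (fixed init)", {
  set.seed(23)
  sim <- generate_hier_mixture(hier_mixture_spec(
    coarse_k = 2, fine_per_coarse = 2, n_per_fine = 8, d = 40,
    coarse_dims = 1, fine_dims = 1, seed = 9))
  n <- nrow(sim$x)
  ia <- rep_len(1:5, n)
  h <- pcah_run(sim$x, k_init = 5, strategy = "max", seed = 1,
                initial_assignment = ia)
  perm <- sample(n)
  hp <- pcah_run(sim$x[perm, ], k_init = 5, strategy = "max", seed = 1,
                 initial_assignment = ia[perm])
  for (k in 5:1) {
    expect_equal(adjusted_rand_index(partition_at(hp, k),
                                     partition_at(h, k)[perm]), 1)
  }
})

test_that("ensembles derive reproducible sub-seeds from the master seed", {
  blobs <- make_two_blobs(n_per = 10, sep = 15, d = 6, seed = 2)
  e1 <- pcah_ensemble(blobs$x, k_init = 4, n_runs = 3, seed = 11)
  e2 <- pcah_ensemble(blobs$x, k_init = 4, n_runs = 3, seed = 11)
  expect_length(e1, 3L)
  for (i in 1:3) expect_identical(e1[[i]]$assignments, e2[[i]]$assignments)

  # n_runs = 1 degenerates to a single sampling run with the derived sub-seed
  e <- pcah_ensemble(blobs$x, k_init = 4, n_runs = 1, seed = 7)
  solo <- pcah_run(blobs$x, k_init = 4, strategy = "sample",
                   seed = attr(e, "sub_seeds")[1])
  expect_identical(e[[1]]$assignments, solo$assignments)

  expect_error(pcah_ensemble(blobs$x, n_runs = 0, seed = 1),
               class = "pcah_invalid_parameter")
})
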