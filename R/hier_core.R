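# The agglomerative core: K-means initialisation in k_init - 1 principal
# directions, Gaussian pooled-moment merge scoring, merge selection (max or
# sampled), per-merge dimension dropping, and hierarchy assembly.

# A cluster state is a plain list:
#   assignment  length-n integer vector with values in 1..k (live indices)
#   sizes       length-k integer vector
#   centroids   k x q_cur matrix
#   covariances list of k symmetric q_cur x q_cur matrices (ML form,
#               denominator n_i, so singletons carry a zero matrix)
#   q_cur, k
new_cluster_state <- function(assignment, y) {
  assignment <- as.integer(canonicalise_labels(assignment))
  k <- max(assignment)
  q <- y$q
  s <- y$scores
  sizes <- tabulate(assignment, nbins = k)
  if (any(sizes == 0L)) {
    pcah_stop("cluster state has an empty cluster", "pcah_invariant_violation")
  }
  centroids <- matrix(0, k, q)
  covariances <- vector("list", k)
  for (i in seq_len(k)) {
    rows <- s[assignment == i, , drop = FALSE]
    centroids[i, ] <- colMeans(rows)
    cc <- sweep(rows, 2, centroids[i, ])
    covariances[[i]] <- crossprod(cc) / nrow(rows)  # ML denominator n_i
  }
  list(assignment = assignment, sizes = sizes, centroids = centroids,
       covariances = covariances, q_cur = q, k = k)
}

#' Initial partition by K-means in the leading k - 1 principal directions
#'
#' Runs K-means (multiple random restarts, best within-cluster sum of
#' squares kept) on the score matrix and derives per-cluster sizes, centroids
#' and maximum-likelihood covariances. The score matrix is expected to hold
#' `k - 1` directions, matching the rule that a k-cluster partition lives in
#' a (k-1)-dimensional representation.
#'
#' @param y a `pcah_scores` object with `q = k - 1` columns.
#' @param k number of initial clusters; `k <=` number of cells.
#' @param seed integer seed; the partition is a deterministic function of it.
#' @param nstart K-means random restarts (default 10).
#' @param max_retries bounded retries should K-means return an empty cluster.
#' @return a cluster state list (assignment, sizes, centroids, covariances,
#'   q_cur, k).
#' @export
initialise_clusters <- function(y, k, seed, nstart = 10L, max_retries = 5L) {
  with_seed(seed, initialise_clusters_impl(y, k, nstart, max_retries))
}

# RNG-stream version used inside pcah_run (seed handled by the caller).
initialise_clusters_impl <- function(y, k, nstart = 10L, max_retries = 5L) {
  stopifnot(inherits(y, "pcah_scores"))
  n <- nrow(y$scores)
  if (length(k) != 1L || k != round(k) || k < 1L || k > n) {
    pcah_stop(sprintf("k must be an integer in [1, %d]", n),
              "pcah_invalid_parameter")
  }
  k <- as.integer(k)
  if (y$q != k - 1L && k > 1L) {
    pcah_stop(sprintf("score matrix has %d directions; a %d-cluster state needs %d",
                      y$q, k, k - 1L),
              "pcah_invalid_parameter")
  }
  if (k == 1L) {
    return(new_cluster_state(rep(1L, n), y))
  }
  if (k == n) {
    # one point per cluster: K-means is degenerate, the answer is exact
    return(new_cluster_state(seq_len(n), y))
  }
  for (attempt in seq_len(max_retries + 1L)) {
    km <- tryCatch(
      stats::kmeans(y$scores, centers = k, nstart = nstart, iter.max = 100L),
      error = function(e) e
    )
    if (!inherits(km, "error") &&
        all(tabulate(km$cluster, nbins = k) > 0L)) {
      return(new_cluster_state(km$cluster, y))
    }
  }
  pcah_stop(sprintf("K-means failed to produce %d non-empty clusters after %d attempts",
                    k, max_retries + 1L),
            "pcah_degenerate_init")
}

#' Size-weighted pooled moments of two clusters
#'
#' The hypothetical merged cluster of clusters i and j is summarised by the
#' convex combinations
#' \deqn{\mu_{ij} = \frac{n_i}{n_i+n_j}\mu_i + \frac{n_j}{n_i+n_j}\mu_j,
#'       \quad
#'       \Sigma_{ij} = \frac{n_i}{n_i+n_j}\Sigma_i + \frac{n_j}{n_i+n_j}\Sigma_j.}
#' The pooled mean equals the exact mean of the union; the pooled covariance
#' deliberately omits the between-cluster spread, so well-separated pairs are
#' penalised when the union is scored against it.
#'
#' @param size_i,size_j cluster sizes (positive).
#' @param mean_i,mean_j centroid vectors of equal length.
#' @param cov_i,cov_j square covariance matrices conformable with the means.
#' @return list with `mean` and `cov`.
#' @export
pooled_moments <- function(size_i, mean_i, cov_i, size_j, mean_j, cov_j) {
  if (size_i < 1 || size_j < 1) {
    pcah_stop("cluster sizes must be >= 1", "pcah_invalid_input")
  }
  mean_i <- as.numeric(mean_i); mean_j <- as.numeric(mean_j)
  cov_i <- as.matrix(cov_i); cov_j <- as.matrix(cov_j)
  q <- length(mean_i)
  if (length(mean_j) != q || !all(dim(cov_i) == q) || !all(dim(cov_j) == q)) {
    pcah_stop("mean/covariance shapes do not agree", "pcah_invalid_input")
  }
  w_i <- size_i / (size_i + size_j)
  w_j <- 1 - w_i
  list(mean = w_i * mean_i + w_j * mean_j,
       cov = w_i * cov_i + w_j * cov_j)
}

#' Joint Gaussian log-likelihood of points under pooled moments
#'
#' The merge score of a candidate pair: the log-likelihood of all member
#' points of the union under a multivariate Gaussian with the pooled mean and
#' covariance. A ridge `ridge * I` is added to the covariance before the
#' Cholesky factorisation to keep rank-deficient (e.g. singleton-derived)
#' covariances invertible.
#'
#' With `mode = "joint"` (default) the per-point log-densities are summed —
#' the likelihood of the whole union. Note the sum has one term per member,
#' so small unions incur fewer penalty terms than large ones; `mode = "mean"`
#' averages instead, removing that size effect.
#'
#' @param members numeric matrix of score rows (one row per point).
#' @param pooled_mean,pooled_cov moments from [pooled_moments()].
#' @param ridge nonnegative ridge added to the covariance diagonal.
#' @param mode `"joint"` (sum of log-densities) or `"mean"` (average).
#' @return a single numeric log score.
#' @export
merge_log_score <- function(members, pooled_mean, pooled_cov, ridge = 0,
                            mode = c("joint", "mean")) {
  mode <- match.arg(mode)
  members <- as.matrix(members)
  pooled_mean <- as.numeric(pooled_mean)
  q <- length(pooled_mean)
  if (nrow(members) < 1L || ncol(members) != q) {
    pcah_stop("members must be a non-empty matrix with one column per dimension",
              "pcah_invalid_input")
  }
  s <- as.matrix(pooled_cov) + diag(ridge, q)
  ch <- tryCatch(chol(s), error = function(e) e)
  if (inherits(ch, "error")) {
    pcah_stop("pooled covariance is not positive definite after regularization",
              "pcah_numerical_degeneracy")
  }
  log_det <- 2 * sum(log(diag(ch)))
  centered <- sweep(members, 2, pooled_mean)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  quad <- colSums(z^2)
  ll <- -0.5 * (q * log(2 * pi) + log_det + quad)
  if (mode == "joint") sum(ll) else mean(ll)
}

#' Score every unordered pair of clusters as a merge candidate
#'
#' @param state a cluster state with `k >= 2` clusters.
#' @param y the `pcah_scores` object the state was built in (same dimension).
#' @param ridge,mode passed to [merge_log_score()].
#' @return list of candidates, each a list with `pair = c(i, j)` (i < j),
#'   `pooled_mean`, `pooled_cov`, `log_score`; ordered lexicographically by
#'   pair.
#' @export
score_all_pairs <- function(state, y, ridge = 0, mode = "joint") {
  k <- state$k
  if (k < 2L) pcah_stop("need at least two clusters", "pcah_invalid_input")
  s <- y$scores
  idx <- lapply(seq_len(k), function(i) which(state$assignment == i))
  out <- vector("list", k * (k - 1L) / 2L)
  pos <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      pm <- pooled_moments(state$sizes[i], state$centroids[i, ],
                           state$covariances[[i]],
                           state$sizes[j], state$centroids[j, ],
                           state$covariances[[j]])
      ls <- tryCatch(
        merge_log_score(s[c(idx[[i]], idx[[j]]), , drop = FALSE],
                        pm$mean, pm$cov, ridge = ridge, mode = mode),
        pcah_numerical_degeneracy = function(e) {
          pcah_stop(sprintf("degenerate pooled covariance for pair (%d, %d)", i, j),
                    "pcah_numerical_degeneracy")
        }
      )
      pos <- pos + 1L
      out[[pos]] <- list(pair = c(i, j), pooled_mean = pm$mean,
                         pooled_cov = pm$cov, log_score = ls)
    }
  }
  out
}

#' Choose the merge to perform
#'
#' `strategy = "max"` picks the candidate with the greatest log score, ties
#' broken by the lexicographically smallest pair. `strategy = "sample"` draws
#' a candidate with probability proportional to `exp(log_score - max)`, i.e.
#' the normalised merge probabilities computed stably in log space; it
#' advances the R random number stream.
#'
#' @param candidates candidate list from [score_all_pairs()].
#' @param strategy `"max"` or `"sample"`.
#' @return the chosen candidate.
#' @export
select_merge <- function(candidates, strategy = c("max", "sample")) {
  strategy <- match.arg(strategy)
  if (length(candidates) == 0L) {
    pcah_stop("no merge candidates", "pcah_invalid_input")
  }
  ls <- vapply(candidates, `[[`, numeric(1), "log_score")
  if (strategy == "max" || length(candidates) == 1L) {
    # candidates are in lexicographic pair order; which.max keeps the first
    # maximum, which is the smallest (i, j) among ties
    return(candidates[[which.max(ls)]])
  }
  w <- exp(ls - max(ls))
  candidates[[sample.int(length(w), 1L, prob = w)]]
}

#' Apply a chosen merge and drop the trailing direction
#'
#' Unites the chosen pair of clusters; the merged cluster takes the pooled
#' moments (restricted to the surviving dimensions) rather than re-estimating
#' from its members, and every centroid and covariance loses its last
#' coordinate together with the score matrix — except on the final merge to a
#' single cluster, where no direction below one dimension is dropped.
#'
#' @param state current cluster state.
#' @param chosen candidate from [select_merge()]; must refer to live clusters
#'   in `state`.
#' @param y current `pcah_scores` object.
#' @return list with the new `state` and the (possibly reduced) `y`.
#' @export
apply_merge <- function(state, chosen, y) {
  i <- chosen$pair[1L]
  j <- chosen$pair[2L]
  k <- state$k
  if (!(i >= 1L && j <= k && i < j) ||
      length(chosen$pooled_mean) != state$q_cur) {
    pcah_stop("stale merge candidate: pair does not refer to live clusters",
              "pcah_invariant_violation")
  }
  drop_dim <- k > 2L  # final 2 -> 1 merge keeps the single remaining dimension
  keep <- if (drop_dim) seq_len(state$q_cur - 1L) else seq_len(state$q_cur)

  survivors <- setdiff(seq_len(k), j)
  centroids <- state$centroids[survivors, keep, drop = FALSE]
  covariances <- lapply(state$covariances[survivors],
                        function(m) m[keep, keep, drop = FALSE])
  pos_i <- match(i, survivors)
  centroids[pos_i, ] <- chosen$pooled_mean[keep]
  covariances[[pos_i]] <- chosen$pooled_cov[keep, keep, drop = FALSE]

  sizes <- state$sizes[survivors]
  sizes[pos_i] <- state$sizes[i] + state$sizes[j]

  assignment <- state$assignment
  assignment[assignment == j] <- i
  assignment <- match(assignment, survivors)

  y2 <- if (drop_dim) drop_trailing_direction(y) else y
  list(state = list(assignment = as.integer(assignment), sizes = sizes,
                    centroids = centroids, covariances = covariances,
                    q_cur = length(keep), k = k - 1L),
       y = y2)
}

default_ridge <- function(y) {
  max(1e-6 * mean(diag(stats::cov(y$scores))), 1e-10)
}

#' Build a full cell-state hierarchy from an expression matrix
#'
#' The complete procedure: project onto the leading `k_init - 1` principal
#' directions, partition by K-means into `k_init` clusters, then alternately
#' merge the selected pair of clusters (Gaussian pooled-moment scoring) and
#' discard the trailing principal direction until a single cluster remains.
#' Every intermediate partition is retained, so the result holds `k_init`
#' nested levels, the level with k clusters living in k - 1 dimensions.
#'
#' @param x numeric expression matrix, cells in rows, genes in columns
#'   (typically log-scale expression).
#' @param k_init number of initial clusters (default 31, i.e. 30 leading
#'   principal directions); must satisfy `2 <= k_init <= min(n, d + 1)`.
#' @param strategy `"max"` (deterministic best merge) or `"sample"`
#'   (stochastic, proportional to normalised merge probabilities).
#' @param seed integer; fully determines the run, including K-means
#'   initialisation and any sampling.
#' @param score_mode `"joint"` or `"mean"`, see [merge_log_score()].
#' @param ridge covariance ridge; default `1e-6` times the mean diagonal of
#'   the global score covariance, floored at `1e-10`.
#' @param scale. passed to [compute_scores()].
#' @param nstart K-means restarts.
#' @param initial_assignment optional length-n vector of labels in
#'   `1..k_init`; bypasses K-means (useful for testing and for resuming).
#' @return an object of class `pcah_hierarchy`: list with
#'   \describe{
#'     \item{assignments}{n x k_init integer matrix; column `"k=<k>"` is the
#'       partition into k clusters, labels canonicalised by first appearance}
#'     \item{merge_trace}{data frame with one row per merge: `level` (cluster
#'       count before the merge), `cluster_a`, `cluster_b` (canonical labels
#'       at that level), `log_score`, `dim` (working dimension when scored)}
#'     \item{strategy, seed, k_init, ridge, score_mode, n}{run parameters}
#'   }
#' @examples
#' sim <- generate_hier_mixture(hier_mixture_spec(
#'   coarse_k = 2, fine_per_coarse = 2, n_per_fine = 10, d = 40, seed = 7))
#' h <- pcah_run(sim$x, k_init = 5, strategy = "max", seed = 1)
#' table(partition_at(h, 2), sim$coarse)
#' @export
pcah_run <- function(x, k_init = 31L, strategy = c("max", "sample"), seed = 1L,
                     score_mode = c("joint", "mean"), ridge = NULL,
                     scale. = FALSE, nstart = 10L, initial_assignment = NULL) {
  strategy <- match.arg(strategy)
  score_mode <- match.arg(score_mode)
  x <- as.matrix(x)
  validate_expression_matrix(x)
  n <- nrow(x)
  if (k_init != round(k_init) || k_init < 2L || k_init > min(n, ncol(x) + 1L)) {
    pcah_stop(sprintf("k_init must be an integer in [2, %d]",
                      min(n, ncol(x) + 1L)),
              "pcah_invalid_parameter")
  }
  k_init <- as.integer(k_init)
  y <- compute_scores(x, q = k_init - 1L, scale. = scale.)
  if (is.null(ridge)) ridge <- default_ridge(y)

  with_seed(seed, {
    state <- if (is.null(initial_assignment)) {
      initialise_clusters_impl(y, k_init, nstart = nstart)
    } else {
      ia <- as.integer(canonicalise_labels(initial_assignment))
      if (length(ia) != n || max(ia) != k_init) {
        pcah_stop("initial_assignment must label all cells with k_init clusters",
                  "pcah_invalid_parameter")
      }
      new_cluster_state(ia, y)
    }

    assignments <- matrix(NA_integer_, n, k_init,
                          dimnames = list(rownames(x),
                                          paste0("k=", seq(k_init, 1L))))
    assignments[, 1L] <- canonicalise_labels(state$assignment)
    trace <- vector("list", k_init - 1L)

    for (k in seq(k_init, 2L)) {
      cands <- score_all_pairs(state, y, ridge = ridge, mode = score_mode)
      chosen <- select_merge(cands, strategy)
      canon <- canonicalise_labels(state$assignment)
      pair_canon <- sort(c(canon[match(chosen$pair[1L], state$assignment)],
                           canon[match(chosen$pair[2L], state$assignment)]))
      trace[[k_init - k + 1L]] <- data.frame(
        level = k, cluster_a = pair_canon[1L], cluster_b = pair_canon[2L],
        log_score = chosen$log_score, dim = state$q_cur)
      res <- apply_merge(state, chosen, y)
      state <- res$state
      y <- res$y
      assignments[, k_init - k + 2L] <- canonicalise_labels(state$assignment)
    }

    structure(
      list(assignments = assignments,
           merge_trace = do.call(rbind, trace),
           strategy = strategy, seed = as.integer(seed), k_init = k_init,
           ridge = ridge, score_mode = score_mode, n = n),
      class = "pcah_hierarchy"
    )
  })
}

#' Extract the partition with k clusters from a hierarchy
#'
#' @param h a `pcah_hierarchy`.
#' @param k cluster count, between 1 and `h$k_init`.
#' @return integer vector of canonical labels, one per cell.
#' @export
partition_at <- function(h, k) {
  stopifnot(inherits(h, "pcah_hierarchy"))
  col <- paste0("k=", k)
  if (!col %in% colnames(h$assignments)) {
    pcah_stop(sprintf("no level with %s clusters in this hierarchy", k),
              "pcah_invalid_parameter")
  }
  h$assignments[, col]
}

#' @export
print.pcah_hierarchy <- function(x, ...) {
  cat(sprintf("Cell-state hierarchy: %d cells, levels k=%d..1, strategy '%s', seed %d\n",
              x$n, x$k_init, x$strategy, x$seed))
  cat(sprintf("score mode '%s', covariance ridge %.3g\n", x$score_mode, x$ridge))
  invisible(x)
}

#' Repeated stochastic runs for consensus analysis
#'
#' Runs the sampling-strategy algorithm `n_runs` times with per-run sub-seeds
#' derived from one master seed (a fixed-size draw from the seeded stream, so
#' the whole ensemble is reproducible from `seed` alone).
#'
#' @param x expression matrix, cells in rows.
#' @param k_init initial cluster count (default 31).
#' @param n_runs number of runs (default 100).
#' @param seed master seed.
#' @param ... further arguments passed to [pcah_run()].
#' @return a list of `pcah_hierarchy` objects of class `pcah_ensemble`, with
#'   attributes `seed` and `sub_seeds`.
#' @export
pcah_ensemble <- function(x, k_init = 31L, n_runs = 100L, seed = 1L, ...) {
  if (n_runs < 1L) pcah_stop("n_runs must be >= 1", "pcah_invalid_parameter")
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_runs))
  runs <- lapply(sub_seeds, function(s) {
    pcah_run(x, k_init = k_init, strategy = "sample", seed = s, ...)
  })
  structure(runs, class = c("pcah_ensemble", "list"),
            seed = as.integer(seed), sub_seeds = sub_seeds)
}

#' @export
print.pcah_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d sampling runs (master seed %d), %d cells, k_init %d\n",
              length(x), attr(x, "seed"), x[[1L]]$n, x[[1L]]$k_init))
  invisible(x)
}
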