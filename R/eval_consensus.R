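# Partition agreement (Adjusted Rand Index) and co-association consensus
# across repeated stochastic runs.

#' Adjusted Rand Index between two partitions
#'
#' The Hubert-Arabie chance-corrected Rand index computed from the
#' contingency table of the two labellings: 1 for partitions identical up to
#' relabelling, approximately 0 for independent ones. Symmetric in its
#' arguments and invariant to relabelling. When both partitions are
#' degenerate in the same way (the permutation-model denominator is zero,
#' e.g. both all-singletons) the partitions are necessarily identical and 1
#' is returned.
#'
#' @param p1,p2 label vectors of equal length (any atomic type); length >= 2.
#' @return a single number <= 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' adjusted_rand_index(c(1, 1, 1, 1), c(1, 2, 3, 1))          # 0
#' @export
adjusted_rand_index <- function(p1, p2) {
  n <- length(p1)
  if (length(p2) != n) {
    pcah_stop("partitions have different lengths", "pcah_invalid_input")
  }
  if (n < 2L) pcah_stop("need at least two items", "pcah_invalid_input")
  comb2 <- function(m) m * (m - 1) / 2
  tab <- table(p1, p2)
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Agreement of every hierarchy level with reference labellings
#'
#' Computes the Adjusted Rand Index between each level of a hierarchy and
#' each reference partition. Plotting the index against the level reveals at
#' which resolution the hierarchy best matches each reference: with both a
#' coarse and a fine reference, the curves are expected to peak at the
#' corresponding cluster counts.
#'
#' @param h a `pcah_hierarchy`.
#' @param refs named list of reference label vectors, each of length `h$n`.
#' @return data frame with columns `level` (cluster count), `reference`
#'   (name), `arandi`; one row per level x reference.
#' @export
level_concordance <- function(h, refs) {
  stopifnot(inherits(h, "pcah_hierarchy"))
  if (is.null(names(refs)) || any(names(refs) == "")) {
    names(refs) <- paste0("ref", seq_along(refs))
  }
  levels_k <- seq(h$k_init, 1L)
  out <- expand.grid(level = levels_k, reference = names(refs),
                     stringsAsFactors = FALSE)
  out$arandi <- mapply(function(k, nm) {
    ref <- refs[[nm]]
    if (length(ref) != h$n) {
      pcah_stop(sprintf("reference '%s' has length %d, expected %d",
                        nm, length(ref), h$n),
                "pcah_invalid_input")
    }
    adjusted_rand_index(partition_at(h, k), ref)
  }, out$level, out$reference)
  out
}

#' Co-association matrix across runs at one hierarchy level
#'
#' Entry (a, b) is the fraction of runs whose partition into `level` clusters
#' placed cells a and b in the same cluster. The matrix is symmetric with a
#' unit diagonal; with identical runs the entries are exactly 0 or 1.
#'
#' @param hierarchies list of `pcah_hierarchy` objects (e.g. a
#'   `pcah_ensemble`) sharing the same cells.
#' @param level cluster count at which to take each run's partition.
#' @return an object of class `pcah_consensus`: list with `co_assoc`
#'   (n x n matrix in `[0, 1]`), `n_runs`, `level`.
#' @export
build_consensus <- function(hierarchies, level) {
  if (length(hierarchies) < 1L) {
    pcah_stop("need at least one hierarchy", "pcah_invalid_input")
  }
  n <- hierarchies[[1L]]$n
  acc <- matrix(0, n, n)
  for (h in hierarchies) {
    if (!inherits(h, "pcah_hierarchy") || h$n != n) {
      pcah_stop("hierarchies disagree on the number of cells",
                "pcah_invalid_input")
    }
    p <- partition_at(h, level)
    acc <- acc + outer(p, p, `==`)
  }
  co <- acc / length(hierarchies)
  dimnames(co) <- list(rownames(hierarchies[[1L]]$assignments),
                       rownames(hierarchies[[1L]]$assignments))
  structure(list(co_assoc = co, n_runs = length(hierarchies),
                 level = as.integer(level)),
            class = "pcah_consensus")
}

#' Consensus partition from a co-association matrix
#'
#' Average-linkage agglomerative clustering on the dissimilarity
#' `1 - co_assoc`, cut at `k` clusters. Cells that co-cluster in most runs
#' have near-zero dissimilarity and end up together in the consensus.
#'
#' @param cm a `pcah_consensus` object.
#' @param k number of consensus clusters, `1 <= k <= n`.
#' @return integer vector of canonical cluster labels.
#' @export
cut_consensus <- function(cm, k) {
  stopifnot(inherits(cm, "pcah_consensus"))
  n <- nrow(cm$co_assoc)
  if (k != round(k) || k < 1L || k > n) {
    pcah_stop(sprintf("k must be an integer in [1, %d]", n),
              "pcah_invalid_parameter")
  }
  hc <- stats::hclust(stats::as.dist(1 - cm$co_assoc), method = "average")
  canonicalise_labels(stats::cutree(hc, k = k))
}

#' @export
print.pcah_consensus <- function(x, ...) {
  cat(sprintf("Co-association matrix: %d cells, %d runs, level k=%d\n",
              nrow(x$co_assoc), x$n_runs, x$level))
  invisible(x)
}
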