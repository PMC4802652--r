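# Principal-component embedding: centering, truncated scores, and the
# trailing-direction bookkeeping used between merges.

# Validate an expression matrix: cells in rows, genes in columns.
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    pcah_stop("expression input must be a numeric matrix (cells x genes)",
              "pcah_invalid_input")
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    pcah_stop("expression matrix needs at least 2 cells and 2 genes",
              "pcah_invalid_input")
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    pcah_stop(sprintf("non-finite value at cell row %d, gene column %d",
                      bad[1L], bad[2L]),
              "pcah_invalid_input")
  }
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x))) {
    pcah_stop("duplicated cell identifiers", "pcah_invalid_input")
  }
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) {
    pcah_stop("duplicated gene identifiers", "pcah_invalid_input")
  }
  invisible(x)
}

#' Project an expression matrix onto its leading principal directions
#'
#' Columns (genes) are mean-centered, the singular value decomposition of the
#' centered matrix is taken, and the cells' coordinates along the first `q`
#' principal directions are returned together with the sample variance each
#' direction explains. Columns are ordered by decreasing explained variance.
#'
#' A deterministic sign convention is applied (the largest-magnitude gene
#' loading of each component is made positive) so repeated runs are
#' bit-reproducible; all downstream Gaussian merge scores are invariant to
#' per-column sign flips in any case.
#'
#' @param x numeric matrix, cells in rows, genes in columns.
#' @param q number of leading principal directions to keep;
#'   `1 <= q <= min(nrow(x) - 1, ncol(x))`.
#' @param scale. logical; if `TRUE` genes are scaled to unit variance before
#'   the decomposition. Default `FALSE`: centering only, preserving genes'
#'   relative variance.
#' @return an object of class `pcah_scores`: a list with `scores` (n x q
#'   matrix, columns centered), `explained_variance` (length-q, non-increasing,
#'   sample-variance `n - 1` denominator), and `q`.
#' @examples
#' x <- matrix(rnorm(40), 8, 5)
#' y <- compute_scores(x, q = 3)
#' y$explained_variance
#' @export
compute_scores <- function(x, q, scale. = FALSE) {
  x <- as.matrix(x)
  validate_expression_matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  q_max <- min(n - 1L, d)
  if (length(q) != 1L || !is.finite(q) || q != round(q) || q < 1 || q > q_max) {
    pcah_stop(sprintf("q must be an integer in [1, %d], got %s",
                      q_max, paste(q, collapse = ",")),
              "pcah_invalid_parameter")
  }
  q <- as.integer(q)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale., rank. = q)
  scores <- pc$x[, seq_len(q), drop = FALSE]
  rot <- pc$rotation[, seq_len(q), drop = FALSE]
  for (j in seq_len(q)) {
    v <- rot[, j]
    s <- sign(v[which.max(abs(v))])
    if (is.finite(s) && s < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(q))
  rownames(scores) <- rownames(x)
  structure(
    list(scores = scores,
         explained_variance = pc$sdev[seq_len(q)]^2,
         q = q),
    class = "pcah_scores"
  )
}

#' Remove the trailing (lowest-variance) principal direction
#'
#' Returns the score object with its last column dropped; the remaining
#' columns are untouched. This is the per-merge dimension reduction step of
#' the hierarchy: after each cluster merge the representation loses the
#' direction explaining the least variance.
#'
#' @param y a `pcah_scores` object with `q >= 2`.
#' @return a `pcah_scores` object with `q - 1` columns.
#' @export
drop_trailing_direction <- function(y) {
  stopifnot(inherits(y, "pcah_scores"))
  if (y$q < 2L) {
    pcah_stop("cannot drop a direction: only one principal direction remains",
              "pcah_cannot_reduce")
  }
  keep <- seq_len(y$q - 1L)
  structure(
    list(scores = y$scores[, keep, drop = FALSE],
         explained_variance = y$explained_variance[keep],
         q = y$q - 1L),
    class = "pcah_scores"
  )
}

#' @export
print.pcah_scores <- function(x, ...) {
  cat(sprintf("Principal-component scores: %d cells x %d directions\n",
              nrow(x$scores), x$q))
  cat("explained variance:",
      paste(signif(x$explained_variance, 4), collapse = " "), "\n")
  invisible(x)
}
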