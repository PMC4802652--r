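# Synthetic hierarchically structured expression data with known two-level
# ground truth: coarse classes split into fine subtypes, with the coarse
# separation carried by higher-variance latent directions than the fine one.

# k points forming a regular simplex with the given edge length, embedded in
# the first k-1 of `dim` coordinates.
simplex_coords <- function(k, dim, edge) {
  if (dim < k - 1L) {
    pcah_stop(sprintf("%d points need at least %d dimensions", k, k - 1L),
              "pcah_invalid_parameter")
  }
  if (k == 1L) return(matrix(0, 1L, dim))
  v <- diag(k)                      # pairwise distance sqrt(2)
  v <- sweep(v, 2, colMeans(v))
  sv <- svd(v)
  coords <- (sv$u %*% diag(sv$d, k))[, seq_len(k - 1L), drop = FALSE]
  coords <- coords * (edge / sqrt(2))
  cbind(coords, matrix(0, k, dim - (k - 1L)))
}

# Haar-ish random rotation (sign-fixed QR of a Gaussian matrix).
random_rotation <- function(dim) {
  if (dim == 1L) return(matrix(1, 1L, 1L))
  qr_ <- qr(matrix(stats::rnorm(dim * dim), dim, dim))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), dim)
}

#' Specification of a two-level hierarchical mixture
#'
#' Describes a population of `coarse_k` broad classes, each split into fine
#' subtypes, observed across `d` genes. Class means sit at the vertices of a
#' regular simplex spanning the first `coarse_dims` latent directions with
#' edge length `coarse_separation * noise_sd`; within each class, subtype
#' means are offset by a randomly rotated simplex in the next `fine_dims`
#' latent directions with edge `fine_separation * noise_sd`. Because
#' `coarse_separation > fine_separation`, the broad-class signal dominates
#' the leading principal components while the subtype signal appears only in
#' later ones — the data regime the clustering algorithm is designed for.
#'
#' Default effect sizes are chosen so that, at the default sample and gene
#' counts, both signal layers produce sample-covariance eigenvalues clearly
#' above the pure-noise bulk, making the benchmark solvable in principle.
#'
#' @param coarse_k number of broad classes.
#' @param fine_per_coarse subtypes per class; scalar or length-`coarse_k`.
#' @param n_per_fine cells per subtype.
#' @param d number of genes.
#' @param coarse_separation,fine_separation distances between class /
#'   subtype means, in units of the within-cluster standard deviation;
#'   `coarse_separation > fine_separation > 0`.
#' @param coarse_dims,fine_dims latent directions carrying each layer.
#' @param noise_sd residual per-gene standard deviation.
#' @param dropout_rate probability of zeroing an entry (technical dropout).
#' @param seed integer seed; the generated data are a deterministic function
#'   of the spec.
#' @return a validated list of class `hier_mixture_spec`.
#' @export
hier_mixture_spec <- function(coarse_k = 4L, fine_per_coarse = c(2L, 2L, 2L, 3L),
                              n_per_fine = 30L, d = 500L,
                              coarse_separation = 12, fine_separation = 8,
                              coarse_dims = 3L, fine_dims = 2L,
                              noise_sd = 1, dropout_rate = 0, seed = 1L) {
  if (length(fine_per_coarse) == 1L) {
    fine_per_coarse <- rep(fine_per_coarse, coarse_k)
  }
  spec <- list(coarse_k = as.integer(coarse_k),
               fine_per_coarse = as.integer(fine_per_coarse),
               n_per_fine = as.integer(n_per_fine), d = as.integer(d),
               coarse_separation = coarse_separation,
               fine_separation = fine_separation,
               coarse_dims = as.integer(coarse_dims),
               fine_dims = as.integer(fine_dims),
               noise_sd = noise_sd, dropout_rate = dropout_rate,
               seed = as.integer(seed))
  with(spec, {
    if (coarse_k < 1L || any(fine_per_coarse < 1L) || n_per_fine < 1L || d < 2L) {
      pcah_stop("all counts must be positive (and d >= 2)", "pcah_invalid_parameter")
    }
    if (length(fine_per_coarse) != coarse_k) {
      pcah_stop("fine_per_coarse must have one entry per coarse class",
                "pcah_invalid_parameter")
    }
    if (!(coarse_separation > fine_separation && fine_separation > 0)) {
      pcah_stop("need coarse_separation > fine_separation > 0",
                "pcah_invalid_parameter")
    }
    if (dropout_rate < 0 || dropout_rate > 1) {
      pcah_stop("dropout_rate must lie in [0, 1]", "pcah_invalid_parameter")
    }
    if (coarse_dims < coarse_k - 1L || fine_dims < max(fine_per_coarse) - 1L) {
      pcah_stop("latent dimensions too small for the requested simplices",
                "pcah_invalid_parameter")
    }
    if (coarse_dims + fine_dims > d) {
      pcah_stop("latent dimension exceeds the number of genes",
                "pcah_invalid_parameter")
    }
  })
  structure(spec, class = "hier_mixture_spec")
}

#' Generate a hierarchical mixture with known two-level labels
#'
#' Draws the latent subtype means described by the spec, embeds them into
#' gene space through a random orthonormal map, adds isotropic Gaussian
#' noise, and optionally applies dropout (independent zeroing of entries).
#' The same spec (including its seed) always yields bit-identical output.
#'
#' @param spec a [hier_mixture_spec()].
#' @return list with `x` (n x d expression matrix with cell/gene ids),
#'   `coarse` and `fine` (integer label vectors; the coarse label is a
#'   deterministic function of the fine label), `fine_means` (the noise-free
#'   gene-space mean of each fine cluster, one row per fine label), and
#'   `spec`.
#' @examples
#' sim <- generate_hier_mixture(hier_mixture_spec(
#'   coarse_k = 2, fine_per_coarse = 2, n_per_fine = 5, d = 20, seed = 3))
#' dim(sim$x)
#' table(sim$coarse, sim$fine)
#' @export
generate_hier_mixture <- function(spec = hier_mixture_spec()) {
  stopifnot(inherits(spec, "hier_mixture_spec"))
  with_seed(spec$seed, {
    L <- spec$coarse_dims + spec$fine_dims
    coarse_means <- simplex_coords(spec$coarse_k, spec$coarse_dims,
                                   spec$coarse_separation * spec$noise_sd)
    coarse_means <- coarse_means %*% random_rotation(spec$coarse_dims)

    n_fine <- sum(spec$fine_per_coarse)
    latent_means <- matrix(0, n_fine, L)
    fine_to_coarse <- integer(n_fine)
    f <- 0L
    for (c_ in seq_len(spec$coarse_k)) {
      k_f <- spec$fine_per_coarse[c_]
      offs <- simplex_coords(k_f, spec$fine_dims,
                             spec$fine_separation * spec$noise_sd)
      offs <- offs %*% random_rotation(spec$fine_dims)
      for (s in seq_len(k_f)) {
        f <- f + 1L
        latent_means[f, ] <- c(coarse_means[c_, ], offs[s, ])
        fine_to_coarse[f] <- c_
      }
    }

    fine <- rep(seq_len(n_fine), each = spec$n_per_fine)
    coarse <- fine_to_coarse[fine]
    n <- length(fine)

    basis <- qr.Q(qr(matrix(stats::rnorm(spec$d * L), spec$d, L)))  # d x L
    gene_means <- latent_means %*% t(basis)
    x <- gene_means[fine, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$d, sd = spec$noise_sd), n, spec$d)
    if (spec$dropout_rate > 0) {
      x[stats::runif(n * spec$d) < spec$dropout_rate] <- 0
    }
    dimnames(x) <- list(sprintf("cell_%03d", seq_len(n)),
                        sprintf("gene_%04d", seq_len(spec$d)))
    list(x = x, coarse = coarse, fine = fine, fine_means = gene_means,
         spec = spec)
  })
}

#' The package's standard synthetic benchmark
#'
#' A fixed-seed instance with 4 coarse classes, one of which splits into 3
#' subtypes and the rest into 2 (9 fine clusters in total), 30 cells per
#' subtype (n = 270) and 500 genes — a deliberately solvable, desk-scale
#' analogue of multi-tissue cell-line study designs with both a tissue-level
#' and a cell-line-level ground truth.
#'
#' @return same structure as [generate_hier_mixture()].
#' @export
default_benchmark <- function() {
  generate_hier_mixture(hier_mixture_spec())
}
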