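# Readers and writers: expression matrices (delimited text or Matrix
# Market), reference labels, and the per-run output bundle (assignments,
# merge trace, Newick tree, metadata, manifest).

#' Read an expression matrix from disk
#'
#' Dense delimited text (TSV/CSV with a header row and a leading row-name
#' column) or sparse Matrix Market with companion one-id-per-line name
#' files. The orientation flag declares whether rows are cells or genes;
#' the returned matrix is always cells x genes.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the file
#'   extension.
#' @param orientation `"cells-rows"` (default) or `"genes-rows"`.
#' @param row_names,col_names for `format = "mtx"`: paths to text files with
#'   one identifier per line for the MTX rows / columns.
#' @return numeric matrix, cells in rows, with unique, finite-checked ids.
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "tsv", "csv", "mtx"),
                                   orientation = c("cells-rows", "genes-rows"),
                                   row_names = NULL, col_names = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    pcah_stop(sprintf("input file not found: %s", path), "pcah_io_error")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  }
  x <- switch(format,
    tsv = ,
    csv = {
      sep <- if (format == "csv") "," else "\t"
      df <- tryCatch(
        utils::read.delim(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE),
        error = function(e) {
          pcah_stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
                    "pcah_io_error")
        })
      as.matrix(df)
    },
    mtx = {
      m <- tryCatch(as.matrix(Matrix::readMM(path)), error = function(e) {
        pcah_stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
                  "pcah_io_error")
      })
      if (!is.null(row_names)) rownames(m) <- readLines(row_names)
      if (!is.null(col_names)) colnames(m) <- readLines(col_names)
      m
    })
  storage.mode(x) <- "double"
  if (orientation == "genes-rows") x <- t(x)
  validate_expression_matrix(x)
  x
}

#' Write an expression matrix as delimited text
#'
#' Cells in rows, header row of gene ids, leading column of cell ids;
#' the exact layout [read_expression_matrix()] expects back.
#'
#' @param x numeric matrix, cells in rows.
#' @param path output file.
#' @param sep field separator (default tab).
#' @export
write_expression_matrix <- function(x, path, sep = "\t") {
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell_%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("gene_%04d", seq_len(ncol(x)))
  df <- data.frame(cell_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reference labels from a two-column delimited file
#'
#' @param path TSV with a header and columns `cell_id`, `label` (names are
#'   free; the first column is the id, the second the label).
#' @param cell_ids optional vector to reorder the labels by id.
#' @return label vector, named by cell id.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) {
    pcah_stop("label file needs two columns: cell id and label", "pcah_io_error")
  }
  labels <- stats::setNames(df[[2L]], df[[1L]])
  if (!is.null(cell_ids)) {
    if (!all(cell_ids %in% names(labels))) {
      pcah_stop("label file is missing some requested cell ids", "pcah_io_error")
    }
    labels <- labels[cell_ids]
  }
  labels
}

#' Newick export of the merge tree
#'
#' Cells are the leaves; each initial cluster is a polytomy, and every merge
#' becomes an internal node labelled `m<level>` where `<level>` is the
#' cluster count after that merge. Branch lengths are not assigned.
#'
#' @param h a `pcah_hierarchy`.
#' @return single Newick string (terminated by `;`).
#' @export
hierarchy_to_newick <- function(h) {
  stopifnot(inherits(h, "pcah_hierarchy"))
  ids <- rownames(h$assignments)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_len(h$n))
  p_prev <- partition_at(h, h$k_init)
  nodes <- vapply(seq_len(h$k_init), function(cl) {
    members <- ids[p_prev == cl]
    if (length(members) == 1L) members else
      paste0("(", paste(members, collapse = ","), ")")
  }, character(1))
  for (k in seq(h$k_init - 1L, 1L)) {
    p_k <- partition_at(h, k)
    # label each level-(k+1) cluster carries at level k
    map <- p_k[match(seq_len(k + 1L), p_prev)]
    new_nodes <- character(k)
    for (lbl in seq_len(k)) {
      src <- which(map == lbl)
      new_nodes[lbl] <- if (length(src) == 1L) nodes[src] else
        paste0("(", nodes[src[1L]], ",", nodes[src[2L]], ")m", k)
    }
    nodes <- new_nodes
    p_prev <- p_k
  }
  paste0(nodes[1L], ";")
}

write_one_run <- function(h, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(h$assignments)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_len(h$n))
  paths <- c(assignments = file.path(dir, "assignments.tsv"),
             merge_trace = file.path(dir, "merge_trace.tsv"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "run_metadata.txt"))
  utils::write.table(
    data.frame(cell_id = ids, h$assignments, check.names = FALSE),
    paths[["assignments"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(h$merge_trace, paths[["merge_trace"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(hierarchy_to_newick(h), paths[["tree"]])
  writeLines(c(
    paste0("tool_version: pcahier ", as.character(utils::packageVersion("pcahier"))),
    paste0("n_cells: ", h$n),
    paste0("k_init: ", h$k_init),
    paste0("strategy: ", h$strategy),
    paste0("score_mode: ", h$score_mode),
    paste0("ridge: ", format(h$ridge, digits = 17)),
    paste0("seed: ", h$seed)
  ), paths[["metadata"]])
  paths
}

#' Write the output bundle of a run or an ensemble
#'
#' For a single hierarchy: an assignments table (cells x levels, columns
#' `k=<k_init>..k=1`), the merge trace, a Newick tree, and a metadata file
#' with the parameters and seed — enough to regenerate the run exactly. For
#' an ensemble: one sub-directory per run plus an ensemble metadata file. A
#' manifest listing every artifact with its MD5 checksum is always written.
#'
#' @param h a `pcah_hierarchy` or `pcah_ensemble`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_run_outputs <- function(h, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(h, "pcah_ensemble")) {
    paths <- unlist(lapply(seq_along(h), function(i) {
      write_one_run(h[[i]], file.path(dir, sprintf("run_%03d", i)))
    }))
    meta <- file.path(dir, "ensemble_metadata.txt")
    writeLines(c(
      paste0("tool_version: pcahier ", as.character(utils::packageVersion("pcahier"))),
      paste0("n_runs: ", length(h)),
      paste0("master_seed: ", attr(h, "seed")),
      paste0("sub_seeds: ", paste(attr(h, "sub_seeds"), collapse = ","))
    ), meta)
    paths <- c(paths, meta)
  } else {
    paths <- write_one_run(h, dir)
  }
  manifest <- data.frame(
    file = sub(paste0("^", dir, "/?"), "", unname(paths)),
    md5 = unname(tools::md5sum(unname(paths))))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read an assignments table back into a partition matrix
#'
#' @param path `assignments.tsv` written by [write_run_outputs()].
#' @return integer matrix, cells in rows (named), one column per level.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}
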