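#' Read a labeled numeric matrix from TSV
#'
#' Expects tab-separated values with a header row of experiment (column)
#' labels and a first column of gene (row) labels. All cells must be finite
#' numbers; duplicate row labels, non-numeric cells and ragged rows are
#' rejected with an error naming the offender.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- suppressWarnings(readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal", show_col_types = FALSE, progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in %s at line %d: %s",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels)) {
    abort(sprintf("duplicate row label in %s: '%s'",
                  path, labels[duplicated(labels)][1]))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric or non-finite cell '%s' in %s at data row %d ('%s'), column %d",
                  raw[bad[1], bad[2]], path, bad[1], labels[bad[1]], bad[2]))
  }
  dimnames(m) <- list(labels, colnames(df)[-1])
  m
}

#' Write a labeled numeric matrix as TSV
#'
#' Inverse of [read_matrix()]: header row of column labels, first column of
#' row labels, tab-separated, '.' decimal.
#'
#' @param x numeric matrix (dimnames filled in if missing).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- default_genes(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  df <- tibble::as_tibble(x, .name_repair = "minimal")
  df <- tibble::add_column(df, gene = rownames(x), .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a network from an edge-list or dense TSV
#'
#' Accepts either a dense matrix TSV (as written by [write_matrix()]) or a
#' headerless 3-column edge list (regulator, target, weight). Edge lists
#' need the gene universe via `genes`; unknown gene identifiers and
#' duplicate edges with conflicting weights are errors.
#'
#' @param path file path.
#' @param genes gene universe (required for edge lists; checked against
#'   dense files when given).
#' @return square weight matrix in the shared gene order.
#' @export
read_network <- function(path, genes = NULL) {
  line1 <- readLines(path, n = 1)
  if (length(line1) == 0) { # empty file: an edge list with no edges
    if (is.null(genes)) abort("edge-list networks need the gene universe via `genes`")
    return(matrix(0, length(genes), length(genes),
                  dimnames = list(genes, genes)))
  }
  first <- strsplit(line1, "\t", fixed = TRUE)[[1]]
  is_edges <- length(first) == 3 && !is.na(suppressWarnings(as.numeric(first[3])))
  if (!is_edges) {
    m <- read_matrix(path)
    if (nrow(m) != ncol(m)) {
      abort(sprintf("dense network in %s is not square (%d x %d)", path, nrow(m), ncol(m)))
    }
    colnames(m) <- rownames(m)
    if (!is.null(genes)) {
      if (!setequal(rownames(m), genes)) {
        abort(sprintf("network in %s is on a different gene set", path))
      }
      m <- m[genes, genes]
    }
    return(m)
  }
  if (is.null(genes)) {
    abort("edge-list networks need the gene universe via `genes`")
  }
  el <- readr::read_tsv(path, col_names = c("regulator", "target", "weight"),
                        col_types = "ccd", show_col_types = FALSE, progress = FALSE)
  unknown <- setdiff(unique(c(el$regulator, el$target)), genes)
  if (length(unknown) > 0) {
    abort(sprintf("unknown gene ID(s) in %s: %s", path,
                  paste(unknown, collapse = ", ")))
  }
  key <- paste(el$regulator, el$target)
  if (anyDuplicated(key)) {
    dups <- el[key %in% key[duplicated(key)], ]
    if (nrow(unique(dups)) != length(unique(paste(dups$regulator, dups$target)))) {
      abort(sprintf("conflicting duplicate edge(s) in %s: %s", path,
                    paste(unique(key[duplicated(key)]), collapse = "; ")))
    }
    el <- el[!duplicated(key), ]
  }
  A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  A[cbind(match(el$target, genes), match(el$regulator, genes))] <- el$weight
  A
}

#' Write a network as an edge list or dense TSV
#'
#' Edge lists are headerless 3-column TSV (regulator, target, weight),
#' strongest edges first, self-loops included.
#'
#' @param net square weight matrix.
#' @param path file path.
#' @param format `"edges"` (default) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edges", "dense")) {
  net <- as_network_matrix(net)
  format <- match.arg(format)
  if (format == "dense") {
    return(write_matrix(net, path))
  }
  idx <- which(net != 0, arr.ind = TRUE)
  el <- tibble::tibble(
    regulator = colnames(net)[idx[, 2]],
    target = rownames(net)[idx[, 1]],
    weight = net[idx])
  el <- el[order(-abs(el$weight), el$regulator, el$target), ]
  readr::write_tsv(el, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a sparsity sweep as a directory of edge lists plus a manifest
#'
#' Each candidate becomes one edge-list TSV (`candidate_<links>.tsv`); a
#' `sweep.json` manifest records the gene order, the backend label and the
#' link counts in sweep order.
#'
#' @param sweep a [grn_sweep()].
#' @param dir directory to create/fill.
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  if (!inherits(sweep, "grn_sweep")) sweep <- grn_sweep(sweep)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("candidate_%04d.tsv", sweep$link_counts)
  for (i in seq_along(sweep$candidates)) {
    write_network(sweep$candidates[[i]], file.path(dir, files[i]))
  }
  jsonlite::write_json(
    list(genes = sweep$genes, method = sweep$method,
         link_counts = sweep$link_counts, files = files),
    file.path(dir, "sweep.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a sparsity sweep written by [write_sweep()]
#'
#' @param dir directory containing `sweep.json` and the candidate files.
#' @return a [grn_sweep()].
#' @export
read_sweep <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "sweep.json"),
                                  simplifyVector = TRUE)
  candidates <- lapply(manifest$files, function(f) {
    read_network(file.path(dir, f), genes = manifest$genes)
  })
  grn_sweep(candidates, method = manifest$method %||% NA_character_)
}
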