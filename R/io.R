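# delimiter from file extension, unless given explicitly
guess_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

#' Read a binary adjacency matrix from a CSV/TSV file
#'
#' The file holds a square 0/1 table, comma-separated for `.csv` and
#' tab-separated otherwise (override with `delim`). An optional single
#' header row carries region labels. Entries must be exactly the characters
#' `0` or `1`; anything else is rejected with its row and column (1-based,
#' header excluded). Node `i` is row/column `i` of the table.
#'
#' @param path file path.
#' @param delim field delimiter; default from the extension.
#' @param symmetrize see [as_adjacency()].
#' @return an adjacency matrix, labels preserved if present.
#' @examples
#' path <- system.file("extdata", "worked_example.csv", package = "ubnin")
#' am <- read_adjacency(path)
#' @export
read_adjacency <- function(path, delim = NULL, symmetrize = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  delim <- guess_delim(path, delim)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty adjacency file: ", path)
  fields <- strsplit(lines, delim, fixed = TRUE)
  fields <- lapply(fields, trimws)
  labels <- NULL
  # a header row of region labels is recognized by non-numeric content, so
  # that a malformed data row (say a stray 2) still gets a data error
  if (any(!grepl("^[0-9.]+$", fields[[1L]]))) {
    labels <- fields[[1L]]
    fields <- fields[-1L]
  }
  n <- length(fields)
  if (n == 0L) stop("adjacency file has a header but no data rows: ", path)
  width <- lengths(fields)
  if (any(width != n)) {
    r <- which(width != n)[1L]
    stop(sprintf("adjacency table must be square: %d rows but row %d has %d fields",
                 n, r, width[r]))
  }
  am <- matrix(0L, n, n)
  for (r in seq_len(n)) {
    bad <- which(!(fields[[r]] %in% c("0", "1")))
    if (length(bad) > 0L) {
      stop(sprintf("entry at [%d, %d] is '%s'; entries must be exactly 0 or 1",
                   r, bad[1L], fields[[r]][bad[1L]]))
    }
    am[r, ] <- as.integer(fields[[r]])
  }
  as_adjacency(am, labels = labels, symmetrize = symmetrize)
}

#' Write an adjacency matrix to a CSV/TSV file
#'
#' Inverse of [read_adjacency()]: labels, if present, become the single
#' header row.
#'
#' @param am adjacency matrix.
#' @param path destination; `.csv` gets commas, anything else tabs.
#' @param delim optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(am, path, delim = NULL) {
  am <- as_adjacency(am)
  delim <- guess_delim(path, delim)
  out <- apply(am, 1L, paste, collapse = delim)
  if (!is.null(colnames(am))) {
    out <- c(paste(colnames(am), collapse = delim), out)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an undirected edge list
#'
#' One edge per line: two 1-based node indices separated by whitespace or
#' tabs. The node count is `n_nodes` if given, otherwise the largest index
#' seen. Self-loops are rejected; repeated edges are allowed (the entry is
#' simply 1).
#'
#' @param path file path.
#' @param n_nodes optional node count.
#' @return an adjacency matrix.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pairs <- lapply(seq_along(lines), function(k) {
    f <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1L]]
    if (length(f) != 2L || !all(grepl("^[0-9]+$", f))) {
      stop(sprintf("edge list line %d is not two 1-based node indices: '%s'",
                   k, lines[k]))
    }
    as.integer(f)
  })
  idx <- unlist(pairs)
  if (length(idx) > 0L && min(idx) < 1L) stop("node indices are 1-based")
  n <- if (is.null(n_nodes)) if (length(idx) == 0L) 1L else max(idx) else as.integer(n_nodes)
  if (length(idx) > 0L && max(idx) > n) {
    stop(sprintf("edge mentions node %d but n_nodes = %d", max(idx), n))
  }
  am <- matrix(0L, n, n)
  for (k in seq_along(pairs)) {
    e <- pairs[[k]]
    if (e[1L] == e[2L]) {
      stop(sprintf("edge list line %d is a self-loop (%d-%d); not allowed",
                   k, e[1L], e[2L]))
    }
    am[e[1L], e[2L]] <- 1L
    am[e[2L], e[1L]] <- 1L
  }
  as_adjacency(am)
}

#' Read a cohort manifest
#'
#' A tab-separated table with a header and columns `subject_id`, `group`
#' and `matrix_path`; matrix paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param path manifest file path.
#' @return a `ubnin_cohort`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "matrix_path")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(path)
  mats <- lapply(tab$matrix_path, function(p) {
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    read_adjacency(full)
  })
  ubnin_cohort(mats, tab$subject_id, tab$group)
}

#' Write a cohort encoding table
#'
#' Writes the data frame produced by [encode_cohort()] as TSV. The encoded
#' values stay exact decimal strings.
#'
#' @param results data frame from [encode_cohort()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# the worked 12-node example's column codes; the matrix is fully determined
# by them, so the example network ships as code, not data
.WORKED_DEC <- c(0, 1, 3, 6, 13, 20, 60, 67, 1, 321, 503, 996)

#' The 12-node worked-example network
#'
#' Reconstructs the canonical 12-node example from its published column-code
#' sequence `(0, 1, 3, 6, 13, 20, 60, 67, 1, 321, 503, 996)`. The network
#' has 35 edges, maximum degree 8, principal node 3, and no connection
#' between nodes 8 and 9 nor between 8 and 10.
#'
#' @return a 12-node adjacency matrix.
#' @examples
#' am <- make_worked_example()
#' column_code(am)
#' @export
make_worked_example <- function() {
  matrix_from_column_code(.WORKED_DEC)
}
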