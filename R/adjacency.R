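# largest node count whose column codes are exact in a double
# (column i has i - 1 strict-upper bits; 2^53 is the last exact integer)
.MAX_NODES <- 54L

#' Validate (and optionally coerce) a binary adjacency matrix
#'
#' A valid adjacency matrix is a square 0/1 matrix with a zero diagonal,
#' symmetric about the diagonal: entry `[i, j] = 1` records an undirected
#' connection between brain regions (nodes) `i` and `j`. Node indices are
#' 1-based throughout, matching the usual column numbering of connectome
#' tables. Invalid input is rejected with the offending coordinates; it is
#' never silently coerced unless `symmetrize = TRUE`, which fills both
#' triangles with the elementwise OR of the two.
#'
#' @param x a square numeric matrix with entries exactly 0 or 1.
#' @param labels optional character vector of region names, one per node;
#'   stored as the matrix `dimnames`.
#' @param symmetrize if `TRUE`, an asymmetric 0/1 matrix is symmetrized by
#'   OR instead of rejected. Off by default.
#' @return the validated matrix, entries stored as integers.
#' @examples
#' as_adjacency(matrix(0, 3, 3))
#' m <- matrix(0, 2, 2); m[1, 2] <- m[2, 1] <- 1
#' as_adjacency(m, labels = c("L_putamen", "R_putamen"))
#' @export
as_adjacency <- function(x, labels = NULL, symmetrize = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("adjacency matrix must be a numeric matrix")
  }
  if (nrow(x) != ncol(x)) {
    stop(sprintf("adjacency matrix must be square, got %d x %d",
                 nrow(x), ncol(x)))
  }
  n <- nrow(x)
  if (n > .MAX_NODES) {
    stop(sprintf("networks larger than %d nodes are not supported (got %d): %s",
                 .MAX_NODES, n,
                 "column codes would exceed exact double-precision integers"))
  }
  bad <- which(!(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("entries must be exactly 0 or 1; first offender at [%d, %d] = %s",
                 bad[1L, 1L], bad[1L, 2L], format(x[bad[1L, , drop = FALSE]])))
  }
  if (any(diag(x) != 0)) {
    i <- which(diag(x) != 0)[1L]
    stop(sprintf("diagonal must be zero (no self-loops); entry [%d, %d] is 1", i, i))
  }
  if (symmetrize) {
    x <- (x + t(x)) > 0
    storage.mode(x) <- "integer"
  } else {
    asym <- which(x != t(x), arr.ind = TRUE)
    if (nrow(asym) > 0L) {
      stop(sprintf(paste0("matrix is not symmetric at [%d, %d] vs [%d, %d]; ",
                          "an undirected network requires a symmetric matrix ",
                          "(use symmetrize = TRUE to coerce by OR)"),
                   asym[1L, 1L], asym[1L, 2L], asym[1L, 2L], asym[1L, 1L]))
    }
  }
  storage.mode(x) <- "integer"
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop(sprintf("labels must have length %d, got %d", n, length(labels)))
    }
    dimnames(x) <- list(labels, labels)
  }
  x
}

#' Node degrees of a binary network
#'
#' The degree of a node is its number of connections: the count of ones in
#' its column of the full symmetric adjacency matrix. Degrees sum to twice
#' the number of edges.
#'
#' @param am adjacency matrix (validated with [as_adjacency()]).
#' @return integer vector of length `n_nodes`.
#' @examples
#' node_degrees(make_worked_example())
#' @export
node_degrees <- function(am) {
  am <- as_adjacency(am)
  as.integer(colSums(am))
}

#' Principal node: the node of highest degree
#'
#' The most connected node of one subject's network. Ties are broken by the
#' smallest node index; see the methods vignette for why a deterministic tie
#' rule is needed.
#'
#' @inheritParams node_degrees
#' @return a single 1-based node index.
#' @examples
#' principal_node(make_worked_example()) # node 3
#' @export
principal_node <- function(am) {
  deg <- node_degrees(am)
  which.max(deg) # which.max returns the first (smallest-index) maximum
}

#' Read one strict-upper column as a decimal column code
#'
#' Column `i` of the zeroed-lower-triangle matrix holds `i - 1` bits (rows
#' `1..i-1`). Read from bottom to top, the bottom-most row (`i - 1`) is the
#' most significant bit and row 1 the least significant; the column is then
#' one binary number, returned in base 10. `DEC(1)` is always 0 (column 1
#' has no strict-upper entries).
#'
#' @inheritParams node_degrees
#' @param i 1-based node/column index.
#' @return a non-negative integer (as double), at most `2^(i-1) - 1`.
#' @examples
#' column_to_decimal(make_worked_example(), 10) # 321
#' @export
column_to_decimal <- function(am, i) {
  am <- as_adjacency(am)
  n <- nrow(am)
  if (length(i) != 1L || is.na(i) || i != floor(i) || i < 1 || i > n) {
    stop(sprintf("column index must be a single integer in 1..%d", n))
  }
  if (i == 1L) return(0)
  rows <- seq_len(i - 1L)
  sum(am[rows, i] * 2^(rows - 1)) # row r carries weight 2^(r-1)
}

#' All column codes of a network
#'
#' @inheritParams node_degrees
#' @return numeric vector `DEC(1..n)`; `DEC(1)` is always 0.
#' @examples
#' column_code(make_worked_example())
#' @export
column_code <- function(am) {
  am <- as_adjacency(am)
  vapply(seq_len(nrow(am)), function(i) column_to_decimal(am, i), numeric(1))
}

# shared validation for a column-code vector
validate_column_code <- function(dec) {
  if (!is.numeric(dec) || length(dec) < 1L) {
    stop("column code must be a non-empty numeric vector")
  }
  n <- length(dec)
  if (n > .MAX_NODES) {
    stop(sprintf("networks larger than %d nodes are not supported (got %d)",
                 .MAX_NODES, n))
  }
  if (anyNA(dec) || any(dec != floor(dec)) || any(dec < 0)) {
    stop("column code entries must be non-negative integers")
  }
  bound <- 2^(seq_len(n) - 1) - 1
  bad <- which(dec > bound)
  if (length(bad) > 0L) {
    stop(sprintf("DEC(%d) = %.0f exceeds its bound 2^%d - 1 = %.0f",
                 bad[1L], dec[bad[1L]], bad[1L] - 1L, bound[bad[1L]]))
  }
  dec
}

#' Expand a decimal column code back to its column bits
#'
#' Exact inverse of [column_to_decimal()] under the bottom-row-is-MSB
#' convention.
#'
#' @param dec a single non-negative integer, at most `2^(i-1) - 1`.
#' @param i 1-based node/column index the code belongs to.
#' @return integer vector of the strict-upper bits for rows `1..i-1`
#'   (length 0 for `i = 1`).
#' @examples
#' decimal_to_column(321, 10) # ones at rows 1, 7 and 9
#' @export
decimal_to_column <- function(dec, i) {
  if (length(i) != 1L || is.na(i) || i != floor(i) || i < 1 || i > .MAX_NODES) {
    stop(sprintf("column index must be a single integer in 1..%d", .MAX_NODES))
  }
  if (length(dec) != 1L || is.na(dec) || dec != floor(dec) || dec < 0 ||
      dec > 2^(i - 1) - 1) {
    stop(sprintf("DEC value for column %d must be an integer in 0..2^%d - 1 = %.0f",
                 i, i - 1L, 2^(i - 1) - 1))
  }
  if (i == 1L) return(integer(0))
  rows <- seq_len(i - 1L)
  as.integer(floor(dec / 2^(rows - 1)) %% 2)
}

#' Rebuild an adjacency matrix from its column codes
#'
#' Decodes every column, mirrors the strict upper triangle to the lower one
#' and zeroes the diagonal, so that `column_code(matrix_from_column_code(dec))`
#' reproduces `dec` exactly. Together with the number codec this realizes
#' full reconstruction of a network from its encoded number.
#'
#' @param dec numeric vector `DEC(1..n)` of column codes.
#' @param labels optional region names, length `n`.
#' @return adjacency matrix of size `length(dec)`.
#' @examples
#' dec <- c(0, 1, 3, 6, 13, 20, 60, 67, 1, 321, 503, 996)
#' am <- matrix_from_column_code(dec)
#' identical(column_code(am), dec)
#' @export
matrix_from_column_code <- function(dec, labels = NULL) {
  dec <- validate_column_code(dec)
  n <- length(dec)
  am <- matrix(0L, n, n)
  for (i in seq_len(n)[-1L]) {
    bits <- decimal_to_column(dec[i], i)
    am[seq_len(i - 1L), i] <- bits
  }
  am <- am + t(am)
  as_adjacency(am, labels = labels)
}
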