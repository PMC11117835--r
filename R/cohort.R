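# run code with a temporary, optionally seeded RNG state, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Assemble a cohort of subjects' networks
#'
#' A cohort bundles one adjacency matrix per subject with a subject ID and a
#' group label (e.g. healthy controls vs patients). All matrices must share
#' the same node count and the same node ordering/labels -- every subject's
#' nodes follow one common parcellation, so node `i` means the same brain
#' region in every matrix.
#'
#' @param matrices list of adjacency matrices (validated with
#'   [as_adjacency()]).
#' @param subject_ids character vector of unique subject identifiers.
#' @param groups group label per subject (a single label is recycled).
#' @return a `ubnin_cohort` object.
#' @examples
#' am <- make_worked_example()
#' ubnin_cohort(list(am, am), c("s1", "s2"), "HC")
#' @export
ubnin_cohort <- function(matrices, subject_ids = NULL, groups = "all") {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("a cohort needs a non-empty list of adjacency matrices")
  }
  matrices <- lapply(matrices, as_adjacency)
  n <- vapply(matrices, nrow, integer(1))
  if (length(unique(n)) != 1L) {
    stop(sprintf("all matrices in a cohort must share one node count; got %s",
                 paste(sort(unique(n)), collapse = ", ")))
  }
  labs <- lapply(matrices, colnames)
  if (length(unique(labs)) != 1L) {
    stop("all matrices in a cohort must share the same node labels/order")
  }
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("subject%03d", seq_along(matrices))
  }
  if (length(subject_ids) != length(matrices) || anyDuplicated(subject_ids)) {
    stop("subject_ids must be unique and match the number of matrices")
  }
  if (length(groups) == 1L) groups <- rep(groups, length(matrices))
  if (length(groups) != length(matrices)) {
    stop("groups must have length 1 or one label per subject")
  }
  structure(
    list(matrices = matrices,
         subject_id = as.character(subject_ids),
         group = as.character(groups),
         n_nodes = n[1L]),
    class = "ubnin_cohort"
  )
}

#' @export
print.ubnin_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects, %d nodes; groups: %s>\n",
              length(x$matrices), x$n_nodes,
              paste(sprintf("%s (%d)", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-subject principal nodes of a cohort
#'
#' @param cohort a `ubnin_cohort`.
#' @return integer vector, one principal node per subject.
#' @export
cohort_principal_nodes <- function(cohort) {
  stopifnot(inherits(cohort, "ubnin_cohort"))
  vapply(cohort$matrices, principal_node, integer(1))
}

#' Maximally occurring principal node of a cohort
#'
#' Computes each subject's principal node (highest-degree node,
#' smallest-index tie rule) and returns the node that is the principal node
#' most often across the cohort. Ties in the occurrence count are again
#' broken by the smallest node index.
#'
#' @param cohort a `ubnin_cohort`.
#' @return a single 1-based node index.
#' @examples
#' am <- make_worked_example()
#' maximally_occurring_principal_node(ubnin_cohort(list(am, am), c("a", "b")))
#' @export
maximally_occurring_principal_node <- function(cohort) {
  stopifnot(inherits(cohort, "ubnin_cohort"))
  counts <- tabulate(cohort_principal_nodes(cohort), nbins = cohort$n_nodes)
  which.max(counts)
}

#' Encode every subject of a cohort with one shared principal node
#'
#' The principal node used for encoding (`MN`) is chosen per group as the
#' group's maximally occurring principal node, so that all subjects of a
#' group are encoded against the same node and their values are comparable.
#' Alternatively `mn_override` fixes one node for the whole cohort -- the
#' literature-driven choice, e.g. a disease-relevant region such as the
#' substantia nigra's parcel in a Parkinson's study.
#'
#' @param cohort a `ubnin_cohort`.
#' @param mn_override optional single node index used for every subject.
#' @param scheme codec identifier, see [encode_modified()].
#' @return a data frame with columns `subject_id`, `group`, `n_nodes`, `mn`,
#'   `integer_part` and `ubnin_m` (the exact decimal string; values are
#'   never carried as floats).
#' @examples
#' cohort <- ubnin_cohort(list(make_worked_example()), "s1", "HC")
#' encode_cohort(cohort, mn_override = 3)
#' @export
encode_cohort <- function(cohort, mn_override = NULL, scheme = "worked-example") {
  stopifnot(inherits(cohort, "ubnin_cohort"))
  n <- cohort$n_nodes
  if (!is.null(mn_override)) {
    if (length(mn_override) != 1L || is.na(mn_override) ||
        mn_override != floor(mn_override) || mn_override < 1 || mn_override > n) {
      stop(sprintf("mn_override must be a single node index in 1..%d", n))
    }
    mn_by_subject <- rep(as.integer(mn_override), length(cohort$matrices))
  } else {
    mn_by_subject <- integer(length(cohort$matrices))
    for (g in unique(cohort$group)) {
      in_g <- cohort$group == g
      sub <- ubnin_cohort(cohort$matrices[in_g],
                          cohort$subject_id[in_g],
                          cohort$group[in_g])
      mn_by_subject[in_g] <- maximally_occurring_principal_node(sub)
    }
  }
  values <- character(length(cohort$matrices))
  int_part <- numeric(length(cohort$matrices))
  for (i in seq_along(cohort$matrices)) {
    v <- encode_modified(column_code(cohort$matrices[[i]]),
                         mn = mn_by_subject[i], scheme = scheme)
    values[i] <- to_decimal_string(v)
    int_part[i] <- ubnin_integer_part(v)
  }
  data.frame(subject_id = cohort$subject_id,
             group = cohort$group,
             n_nodes = rep(n, length(values)),
             mn = mn_by_subject,
             integer_part = int_part,
             ubnin_m = values,
             stringsAsFactors = FALSE)
}

# strict-upper cells in column-major order, the order in which random bits
# are assigned; shared by random_adjacency() and uniqueness_experiment()
upper_cells <- function(n) which(upper.tri(matrix(0, n, n)))

#' Random binary symmetric adjacency matrix
#'
#' Each strict-upper entry is an independent Bernoulli(`p`) draw, mirrored
#' to the lower triangle; the diagonal stays zero. The default `p = 0.5`
#' puts uniform probability on all `2^(n(n-1)/2)` networks, i.e. no sparsity
#' constraint.
#'
#' @param n_nodes node count.
#' @param p edge probability in `[0, 1]`.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return an adjacency matrix.
#' @examples
#' random_adjacency(10, seed = 1)
#' @export
random_adjacency <- function(n_nodes, p = 0.5, seed = NULL) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("edge probability p must be a single value in [0, 1]")
  }
  stopifnot(n_nodes >= 1, n_nodes == floor(n_nodes))
  m <- n_nodes * (n_nodes - 1) / 2
  bits <- with_seed(seed, as.integer(stats::runif(m) < p))
  am <- matrix(0L, n_nodes, n_nodes)
  am[upper_cells(n_nodes)] <- bits
  as_adjacency(am + t(am))
}

#' Uniqueness (collision) experiment over random networks
#'
#' Generates `n_iter` random binary symmetric matrices, encodes each with
#' the exact codec, and counts pairwise-distinct values. For a fixed node
#' count (and fixed principal node in the modified scheme) the codec is
#' injective -- the decoder's existence proves it -- so a collision can occur
#' only when two generated matrices are identical; any colliding pairs are
#' reported together with their matrices.
#'
#' The matrices are drawn exactly as by repeated [random_adjacency()] calls
#' on one seeded stream (the draws are batched internally for speed; a
#' regression test pins the equivalence), so the experiment is reproducible
#' bit-exactly under a fixed seed.
#'
#' @param n_iter number of random networks.
#' @param n_nodes node count (default 10).
#' @param p edge probability (default 0.5, no sparsity constraint).
#' @param seed optional integer seed.
#' @param scheme `"classic"` (default) or `"modified"`.
#' @param mn principal node, required for the modified scheme.
#' @param chunk_size internal batch size.
#' @return a `ubnin_uniqueness` list: `n_iter`, `n_distinct`, `collisions`
#'   (data frame of colliding iteration pairs), `collision_matrices`, and
#'   the generation parameters.
#' @examples
#' uniqueness_experiment(500, n_nodes = 10, seed = 42)
#' @export
uniqueness_experiment <- function(n_iter, n_nodes = 10, p = 0.5, seed = NULL,
                                  scheme = c("classic", "modified"), mn = NULL,
                                  chunk_size = 5000L) {
  scheme <- match.arg(scheme)
  stopifnot(n_iter >= 1, n_iter == floor(n_iter))
  if (scheme == "modified") {
    if (is.null(mn)) stop("the modified scheme needs a fixed mn")
    if (mn < 1 || mn > n_nodes) stop("mn out of range")
    mn <- as.integer(mn)
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("edge probability p must be a single value in [0, 1]")
  }
  m <- n_nodes * (n_nodes - 1) / 2
  # weight matrix turning a row of upper-triangle bits into column codes:
  # cell (r, i) of the strict upper triangle has weight 2^(r-1) in DEC(i)
  cells <- upper_cells(n_nodes)
  rows <- ((cells - 1) %% n_nodes) + 1
  cols <- ((cells - 1) %/% n_nodes) + 1
  wmat <- matrix(0, m, n_nodes)
  wmat[cbind(seq_len(m), cols)] <- 2^(rows - 1)

  keys <- character(n_iter)
  codes <- matrix(0, n_iter, n_nodes)
  with_seed(seed, {
    done <- 0L
    while (done < n_iter) {
      take <- min(chunk_size, n_iter - done)
      # one row per iteration, in draw order (matches random_adjacency)
      bits <- matrix(stats::runif(take * m) < p, nrow = take, byrow = TRUE)
      dec <- bits %*% wmat # exact: every entry is an integer < 2^(n-1)
      for (j in seq_len(take)) {
        raw <- if (scheme == "classic") encode_classic_raw(dec[j, ])
               else encode_modified_raw(dec[j, ], mn)
        keys[done + j] <- paste(c(raw$exp2, raw$num), collapse = ",")
      }
      codes[done + seq_len(take), ] <- dec
      done <- done + take
    }
  })

  dup <- duplicated(keys)
  collisions <- data.frame(first = integer(0), second = integer(0))
  collision_matrices <- list()
  if (any(dup)) {
    for (j in which(dup)) {
      i0 <- match(keys[j], keys)
      collisions <- rbind(collisions, data.frame(first = i0, second = j))
      collision_matrices[[length(collision_matrices) + 1L]] <-
        list(first = matrix_from_column_code(codes[i0, ]),
             second = matrix_from_column_code(codes[j, ]))
    }
  }
  structure(
    list(n_iter = as.integer(n_iter),
         n_distinct = as.integer(sum(!dup)),
         collisions = collisions,
         collision_matrices = collision_matrices,
         n_nodes = as.integer(n_nodes), p = p, seed = seed,
         scheme = scheme, mn = mn),
    class = "ubnin_uniqueness"
  )
}

#' @export
print.ubnin_uniqueness <- function(x, ...) {
  cat(sprintf("Uniqueness experiment: %d random %dx%d networks (p = %g, scheme = %s%s)\n",
              x$n_iter, x$n_nodes, x$n_nodes, x$p, x$scheme,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  cat(sprintf("  distinct encoded values: %d of %d\n", x$n_distinct, x$n_iter))
  if (nrow(x$collisions) == 0L) {
    cat("  no collisions\n")
  } else {
    cat(sprintf("  colliding pairs: %s\n",
                paste(sprintf("(%d, %d)", x$collisions$first, x$collisions$second),
                      collapse = " ")))
  }
  invisible(x)
}
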