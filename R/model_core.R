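# Shared domain types: data matrices and adjacency-matrix graphs.
#
# Graphs are represented everywhere as square logical adjacency matrices with
# a FALSE diagonal; entry [i, j] == TRUE means the directed edge i -> j (or,
# for undirected graphs, that {i, j} are adjacent, stored symmetrically).
# Neighbour and parent sets are derived views, never stored redundantly.

#' Construct a centred data matrix
#'
#' Validates a samples-by-variables table of continuous observations and
#' mean-centres every column. Centring is done once, at load time: the
#' per-node regressions of the BIC score have no intercept term, so centred
#' columns make ordinary least squares well-posed, and correlations are
#' unaffected.
#'
#' @param data A data frame or numeric matrix, one row per sample and one
#'   column per variable, with column names. At least 2 rows, 2 columns and
#'   no missing values.
#' @return An object of class `data_matrix`: a list with elements `values`
#'   (the centred numeric matrix), `m` (sample count), `n` (variable count)
#'   and `names` (variable labels).
#' @examples
#' dm <- as_data_matrix(data.frame(x = rnorm(50), y = rnorm(50)))
#' colMeans(dm$values) # ~ 0
#' @export
as_data_matrix <- function(data) {
  if (inherits(data, "data_matrix")) {
    return(data)
  }
  x <- as.matrix(data)
  if (!is.numeric(x)) {
    stop("`data` must be numeric (samples x variables)", call. = FALSE)
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("`data` needs at least 2 samples and 2 variables", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("`data` contains missing values", call. = FALSE)
  }
  nms <- colnames(x)
  if (is.null(nms)) {
    nms <- paste0("V", seq_len(ncol(x)))
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  attr(x, "scaled:center") <- NULL
  dimnames(x) <- list(NULL, nms)
  structure(
    list(values = x, m = nrow(x), n = ncol(x), names = nms),
    class = "data_matrix"
  )
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("<data_matrix> ", x$m, " samples x ", x$n, " variables\n", sep = "")
  cat("  variables: ", paste(head(x$names, 8L), collapse = ", "),
      if (x$n > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

empty_graph <- function(n, names = NULL) {
  g <- matrix(FALSE, n, n)
  if (!is.null(names)) dimnames(g) <- list(names, names)
  g
}

check_adjacency <- function(g) {
  if (!is.matrix(g) || nrow(g) != ncol(g)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  invisible(g)
}

parents_of <- function(g, j) which(g[, j])
children_of <- function(g, j) which(g[j, ])

#' Test a directed graph for acyclicity
#'
#' Kahn's algorithm: repeatedly peel off zero-in-degree vertices; the graph
#' is acyclic iff every vertex can be peeled (a topological order exists).
#'
#' @param g Square logical (or 0/1) adjacency matrix; `g[i, j]` is the edge
#'   i -> j. The diagonal must be empty.
#' @return `TRUE` iff `g` has no directed cycle.
#' @examples
#' g <- matrix(FALSE, 3, 3); g[1, 2] <- g[2, 3] <- TRUE
#' is_acyclic(g)
#' @export
is_acyclic <- function(g) {
  !is.null(topological_order(g))
}

# Topological order of a directed adjacency matrix, or NULL if cyclic.
topological_order <- function(g) {
  check_adjacency(g)
  n <- nrow(g)
  if (n == 0L) return(integer(0))
  indeg <- colSums(g)
  order <- integer(n)
  queue <- which(indeg == 0)
  k <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    k <- k + 1L
    order[[k]] <- v
    ch <- which(g[v, ])
    for (w in ch) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0) queue <- c(queue, w)
    }
  }
  if (k < n) NULL else order
}

# TRUE iff a directed path from `from` to `to` exists in g (BFS).
has_path <- function(g, from, to) {
  if (from == to) return(TRUE)
  n <- nrow(g)
  seen <- logical(n)
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(g[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

# Would adding the edge from -> to close a directed cycle?
creates_cycle <- function(g, from, to) {
  has_path(g, to, from)
}

#' Hamming distance between two directed graphs
#'
#' Counts the ordered adjacency cells on which the two graphs differ, so a
#' reversed edge contributes 2. Used by the engine's inbreeding-rate control
#' during migration.
#'
#' @param g1,g2 Square logical adjacency matrices of identical dimension.
#' @return A non-negative integer.
#' @export
hamming_distance <- function(g1, g2) {
  check_adjacency(g1)
  check_adjacency(g2)
  if (!all(dim(g1) == dim(g2))) {
    stop("graphs have different dimensions", call. = FALSE)
  }
  sum(g1 != g2)
}

# Edge list (parent, child index pairs) of a directed adjacency matrix,
# ordered row-major for determinism.
edge_indices <- function(g) {
  which(g, arr.ind = TRUE, useNames = FALSE)
}

#' Convert a directed graph to a tibble of edges
#'
#' @param g Logical adjacency matrix; `g[i, j]` is the edge i -> j.
#' @param names Optional variable names; defaults to the matrix dimnames.
#' @return A tibble with columns `parent` and `child`, sorted
#'   lexicographically.
#' @export
edges_tbl <- function(g, names = NULL) {
  check_adjacency(g)
  if (is.null(names)) names <- rownames(g)
  if (is.null(names)) names <- paste0("V", seq_len(nrow(g)))
  idx <- edge_indices(g)
  out <- tibble(parent = names[idx[, 1L]], child = names[idx[, 2L]])
  out[order(out$parent, out$child), ]
}
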