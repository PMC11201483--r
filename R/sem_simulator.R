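# Linear-SEM data generation over ground-truth DAGs.
#
# Three mechanisms are supported, differing in the weight and noise laws:
#   SEM 1: w = +-1 + N(0,1)/4 (sign equiprobable), noise N(0, 1)
#   SEM 2: w ~ Uniform(0.2, 1),                    noise N(0, 1)
#   SEM 3: w = +-1 + N(0,1)/4,                     noise Uniform(-1, 1)
# SEMs 1-2 are linear-Gaussian; SEM 3 is linear non-Gaussian. Weights are
# drawn once per dataset, not per observation. Because every node shares the
# same noise law (equal error variances), the DAG is identifiable from
# observational data, which is what lets the fixed-variance BIC prefer the
# true orientations.

#' Random DAG with a given expected average degree
#'
#' Draws a uniform random topological order and includes each forward pair
#' independently with probability `avg_degree / (n - 1)`, so the expected
#' undirected degree is `avg_degree` and the result is acyclic by
#' construction.
#'
#' @param n Number of variables (>= 2).
#' @param avg_degree Expected average (undirected) degree, < n - 1.
#' @param names Optional variable names.
#' @return Logical adjacency matrix.
#' @export
random_dag <- function(n, avg_degree = 2.5, names = NULL) {
  stopifnot(n >= 2, avg_degree < n - 1)
  ord <- sample.int(n)
  g <- empty_graph(n, names)
  p <- avg_degree / (n - 1)
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      if (runif(1) < p) g[ord[a], ord[b]] <- TRUE
    }
  }
  g
}

# Convenience fixtures used throughout the tests and examples.

#' @rdname random_dag
#' @export
chain_dag <- function(n = 3, names = NULL) {
  g <- empty_graph(n, names)
  for (a in seq_len(n - 1L)) g[a, a + 1L] <- TRUE
  g
}

#' @rdname random_dag
#' @export
collider_dag <- function(names = c("x", "y", "z")) {
  g <- empty_graph(3L, names)
  g[1L, 3L] <- TRUE # x -> z
  g[2L, 3L] <- TRUE # y -> z
  g
}

#' Attach mechanism weights to a DAG
#'
#' @param g Ground-truth DAG (logical adjacency).
#' @param sem_id Mechanism: 1, 2 or 3 (see the module description).
#' @param w Optional weight matrix overriding the mechanism's law (e.g.
#'   all-unit weights for worked examples); must be nonzero exactly on the
#'   DAG's edges.
#' @return An object of class `sem_spec`: list with `g`, `sem_id`, `w`
#'   (weight matrix, nonzero exactly on edges) and `noise_var` (1 for
#'   Gaussian noise, 1/3 for Uniform(-1, 1)).
#' @export
sem_spec <- function(g, sem_id = 1, w = NULL) {
  check_adjacency(g)
  stopifnot(sem_id %in% 1:3, is_acyclic(g))
  n <- nrow(g)
  if (!is.null(w)) {
    stopifnot(all(dim(w) == dim(g)), all((w != 0) == g))
  } else {
    w <- matrix(0, n, n, dimnames = dimnames(g))
    ne <- sum(g)
    if (ne > 0) {
      w[g] <- if (sem_id == 2) {
        runif(ne, 0.2, 1)
      } else {
        sample(c(-1, 1), ne, replace = TRUE) + rnorm(ne) / 4
      }
    }
  }
  structure(
    list(g = g, sem_id = sem_id, w = w,
         noise_var = if (sem_id == 3) 1 / 3 else 1),
    class = "sem_spec"
  )
}

#' Sample observations from a linear SEM
#'
#' Samples in topological order: each node is the weighted sum of its
#' parents plus an independent noise draw from the mechanism's law.
#'
#' @param spec A `sem_spec`.
#' @param m Number of samples (>= 2).
#' @return A `data_matrix` (columns mean-centred at load).
#' @export
simulate_sem <- function(spec, m) {
  stopifnot(inherits(spec, "sem_spec"), m >= 2)
  n <- nrow(spec$g)
  u <- if (spec$sem_id == 3) {
    matrix(runif(m * n, -1, 1), m, n)
  } else {
    matrix(rnorm(m * n), m, n)
  }
  x <- u
  for (j in topological_order(spec$g)) {
    pa <- which(spec$g[, j])
    if (length(pa)) {
      x[, j] <- x[, pa, drop = FALSE] %*% spec$w[pa, j] + u[, j]
    }
  }
  nms <- rownames(spec$g)
  if (is.null(nms)) nms <- paste0("V", seq_len(n))
  colnames(x) <- nms
  as_data_matrix(x)
}

#' Population covariance of a linear SEM
#'
#' Sigma = (I - W)^-T D (I - W)^-1 with W the weight matrix (W\[i, j\] the
#' weight of i -> j) and D the diagonal of noise variances. Serves as the
#' population oracle for the CI-test and constraint-phase property suites.
#'
#' @param spec A `sem_spec`.
#' @return The n x n covariance matrix.
#' @export
analytic_covariance <- function(spec) {
  n <- nrow(spec$g)
  a <- solve(diag(n) - spec$w) # x = u %*% A, row-vector convention
  sig <- crossprod(a * sqrt(spec$noise_var))
  dimnames(sig) <- dimnames(spec$g)
  sig
}
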