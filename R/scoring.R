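# Decomposable BIC fitness under OLS parameter estimation.
#
# Each node contributes -(nll_factor * RSS_j + |pa(j)|/2 * ln m), where
# RSS_j is the residual sum of squares of the no-intercept least-squares
# regression of the (centred) node column on its parent columns. With
# nll_factor = 1/2 this is the unit-variance Gaussian log-density without
# constants; higher scores are better. Because columns are centred once at
# load, every regression reduces to solves against the Gram matrix
# S = X'X, so a node score costs O(|pa|^3) regardless of m.

#' Scoring context with per-node cache
#'
#' Precomputes the Gram matrix of the centred data and holds the score
#' cache. The cache key is (node, sorted parent set); cached entries always
#' equal fresh recomputation.
#'
#' @param data A `data_matrix` or data frame.
#' @param nll_factor Multiplier on the residual sum of squares in the
#'   negative log-likelihood: 0.5 (default, Gaussian log-density) or 1
#'   (literal RSS).
#' @param ridge Fallback diagonal ridge for collinear parent sets.
#' @return An environment of class `score_context`.
#' @export
score_context <- function(data, nll_factor = 0.5, ridge = 1e-10) {
  dm <- as_data_matrix(data)
  ctx <- new.env(parent = emptyenv())
  ctx$s <- crossprod(dm$values)
  ctx$m <- dm$m
  ctx$n <- dm$n
  ctx$logm <- log(dm$m)
  ctx$names <- dm$names
  ctx$nll_factor <- nll_factor
  ctx$ridge <- ridge
  ctx$cache <- new.env(parent = emptyenv())
  ctx$hits <- 0L
  ctx$misses <- 0L
  class(ctx) <- "score_context"
  ctx
}

#' Ordinary least-squares fit of a node on its parents
#'
#' Solves the no-intercept normal equations over the parent columns via the
#' precomputed Gram matrix; an empty parent set yields the column's total
#' sum of squares as RSS.
#'
#' @param ctx A `score_context`.
#' @param j Node index.
#' @param parents Integer vector of parent indices (may be empty).
#' @return List with `theta` (coefficients, one per parent) and `rss`.
#' @export
ols_fit <- function(ctx, j, parents) {
  s <- ctx$s
  if (length(parents) == 0L) {
    return(list(theta = numeric(0), rss = s[j, j]))
  }
  spp <- s[parents, parents, drop = FALSE]
  spj <- s[parents, j]
  theta <- tryCatch(solve(spp, spj), error = function(e) NULL)
  if (is.null(theta)) {
    warning("collinear parent set for node ", j, "; using ridge fallback",
            call. = FALSE)
    theta <- solve(spp + diag(ctx$ridge, length(parents)), spj)
  }
  rss <- s[j, j] - sum(spj * theta)
  list(theta = theta, rss = max(rss, 0))
}

#' Per-node BIC contribution
#'
#' -(nll_factor * RSS + |parents| / 2 * ln m); memoised in the context's
#' cache.
#'
#' @inheritParams ols_fit
#' @return The node's score contribution (higher is better).
#' @export
node_score <- function(ctx, j, parents) {
  parents <- sort(as.integer(parents))
  key <- paste0(j, "|", paste(parents, collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) {
    ctx$hits <- ctx$hits + 1L
    return(hit)
  }
  ctx$misses <- ctx$misses + 1L
  fit <- ols_fit(ctx, j, parents)
  val <- -(ctx$nll_factor * fit$rss + length(parents) / 2 * ctx$logm)
  ctx$cache[[key]] <- val
  val
}

#' BIC fitness of a DAG
#'
#' Sum of per-node contributions; decomposable, so incremental moves touch
#' only the affected nodes (see [delta_score()]). The score of the reference
#' ("standard") network on the same data — the SBS of the evaluation report
#' — is this same function applied to that network.
#'
#' @param ctx A `score_context`.
#' @param g Directed acyclic adjacency matrix.
#' @return The fitness (higher is better).
#' @export
graph_score <- function(ctx, g) {
  check_adjacency(g)
  if (!is_acyclic(g)) {
    stop("graph_score requires an acyclic graph", call. = FALSE)
  }
  tot <- 0
  for (j in seq_len(ncol(g))) {
    tot <- tot + node_score(ctx, j, which(g[, j]))
  }
  tot
}

# A move is list(type = "add" | "delete" | "reverse", from, to), referring
# to the directed edge from -> to (for "reverse", the currently present
# edge from -> to becomes to -> from).

#' Incremental score change of a single-edge move
#'
#' Exploits decomposability: add/delete touch only the child's term,
#' reversal touches both endpoints. Legality (space membership, acyclicity
#' of the result) is the caller's contract; presence/absence of the edge is
#' checked.
#'
#' @param ctx A `score_context`.
#' @param g Current adjacency matrix.
#' @param move List with `type` ("add", "delete", "reverse"), `from`, `to`.
#' @return `graph_score(after) - graph_score(before)`.
#' @export
delta_score <- function(ctx, g, move) {
  from <- move$from
  to <- move$to
  pa_to <- which(g[, to])
  switch(
    move$type,
    add = {
      if (g[from, to]) stop("edge already present", call. = FALSE)
      node_score(ctx, to, c(pa_to, from)) - node_score(ctx, to, pa_to)
    },
    delete = {
      if (!g[from, to]) stop("edge not present", call. = FALSE)
      node_score(ctx, to, setdiff(pa_to, from)) - node_score(ctx, to, pa_to)
    },
    reverse = {
      if (!g[from, to]) stop("edge not present", call. = FALSE)
      pa_from <- which(g[, from])
      (node_score(ctx, to, setdiff(pa_to, from)) -
         node_score(ctx, to, pa_to)) +
        (node_score(ctx, from, c(pa_from, to)) -
           node_score(ctx, from, pa_from))
    },
    stop("unknown move type: ", move$type, call. = FALSE)
  )
}

# Apply a legal move in place (returns the modified matrix).
apply_move <- function(g, move) {
  switch(
    move$type,
    add = g[move$from, move$to] <- TRUE,
    delete = g[move$from, move$to] <- FALSE,
    reverse = {
      g[move$from, move$to] <- FALSE
      g[move$to, move$from] <- TRUE
    }
  )
  g
}
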