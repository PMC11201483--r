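# Independent oracles used across the suite. These deliberately take the
# slow, direct route (graph reachability, explicit regression, exhaustive
# enumeration) so they share no code with the implementation they check.

# d-separation by moralised ancestral graph: i and j are d-separated by z
# iff they are disconnected in the moralisation of the subgraph induced on
# the ancestors of {i, j} union z, after removing z.
dsep_oracle <- function(g, i, j, z = integer(0)) {
  n <- nrow(g)
  seen <- logical(n)
  seen[c(i, j, z)] <- TRUE
  repeat {
    pa <- which(rowSums(g[, seen, drop = FALSE]) > 0)
    new <- pa[!seen[pa]]
    if (!length(new)) break
    seen[new] <- TRUE
  }
  keep <- which(seen)
  sub <- g[keep, keep, drop = FALSE]
  und <- sub | t(sub)
  for (v in seq_along(keep)) {
    pa <- which(sub[, v])
    if (length(pa) > 1L) {
      pairs <- t(combn(pa, 2L))
      und[pairs] <- TRUE
      und[pairs[, 2:1, drop = FALSE]] <- TRUE
    }
  }
  ii <- match(i, keep)
  jj <- match(j, keep)
  avoid <- logical(length(keep))
  avoid[match(z, keep)] <- TRUE
  frontier <- ii
  reach <- logical(length(keep))
  reach[ii] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(und[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!reach[nxt] & !avoid[nxt]]
    if (jj %in% nxt) return(FALSE)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  TRUE
}

# Recursive DFS cycle detection (grey/black colouring), independent of the
# Kahn-style implementation under test.
cyclic_dfs_oracle <- function(g) {
  n <- nrow(g)
  colour <- integer(n)
  found <- FALSE
  visit <- function(v) {
    if (found) return()
    colour[v] <<- 1L
    for (w in which(g[v, ])) {
      if (colour[w] == 1L) {
        found <<- TRUE
        return()
      }
      if (colour[w] == 0L) visit(w)
    }
    colour[v] <<- 2L
  }
  for (v in seq_len(n)) if (colour[v] == 0L && !found) visit(v)
  found
}

# Partial correlation by the definition: correlate the residuals of the
# two explicit least-squares regressions on the conditioning columns.
residual_partial_oracle <- function(x, i, j, z = integer(0)) {
  if (length(z) == 0L) {
    return(cor(x[, i], x[, j]))
  }
  zc <- x[, z, drop = FALSE]
  ri <- stats::lm.fit(zc, x[, i])$residuals
  rj <- stats::lm.fit(zc, x[, j])$residuals
  cor(ri, rj)
}

# All DAGs on n labelled nodes by filtering every directed graph (feasible
# for n = 4: 543 of 4096).
enumerate_dags <- function(n = 4L) {
  cells <- which(row(diag(n)) != col(diag(n)))
  out <- list()
  for (code in 0:(2^length(cells) - 1L)) {
    g <- matrix(FALSE, n, n)
    g[cells] <- bitwAnd(bitwShiftR(code, seq_along(cells) - 1L), 1L) == 1L
    if (!cyclic_dfs_oracle(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# Exhaustive subset search for a separating set: does any subset of `z0`
# render (i, j) independent under the context's CI decision? Subsets are
# enumerated by bitmask to sidestep combn's scalar-expansion trap.
subset_sepset_exists <- function(ctx, i, j, z0) {
  nz <- length(z0)
  for (code in 0:(2^nz - 1L)) {
    s <- z0[bitwAnd(bitwShiftR(code, seq_len(nz) - 1L), 1L) == 1L]
    if (!ci_decision(ctx, i, j, as.integer(s))$dependent) return(TRUE)
  }
  FALSE
}

# Population-limit CI context for a SEM spec.
population_ctx <- function(spec, m = 10000L, k = 0.01) {
  ci_context_cov(analytic_covariance(spec), m = m, k = k)
}

# A random subgroup of valid individuals confined to a search space.
random_subgroup <- function(sctx, space, size = 6L, steps = 8L) {
  n <- ncol(space)
  lapply(seq_len(size), function(i) {
    g <- causalhh:::empty_graph(n)
    for (s in seq_len(steps)) {
      mv <- causalhh:::random_move(g, space)
      if (!is.null(mv)) g <- causalhh:::apply_move(g, mv)
    }
    causalhh:::new_individual(g, graph_score(sctx, g))
  })
}

# Assert the shared operator postconditions: acyclic graphs, fitness in
# sync with graph_score, and unordered edge pairs confined to `space`.
expect_operator_contract <- function(subgroup, sctx, space) {
  for (ind in subgroup) {
    expect_true(is_acyclic(ind$g))
    expect_equal(ind$fitness, graph_score(sctx, ind$g), tolerance = 1e-8)
    sk <- ind$g | t(ind$g)
    expect_true(all(space[sk]))
  }
}
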