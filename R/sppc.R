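# The three-stage constraint phase:
#   1. full partial correlations -> Markov random field (the GSS);
#   2. per-edge greedy search for a d-separating set, guided by open simple
#      paths (OSPs), removing spurious links caused by v-structure effects
#      (the surviving edges form the LSS);
#   3. collider identification on the removed edges -> directed prior edges.
#
# Under faithfulness the MRF of stage 1 approximates the moral graph: every
# true skeleton edge is present, plus spouse links between co-parents. The
# point of stages 2-3 is that those spouse links are exactly the removable
# edges, and the node whose conditioning re-opens them is a collider.

#' Build the Markov random field from full partial correlations
#'
#' An undirected edge \{i, j\} is present iff the full partial correlation
#' (conditioning on all remaining variables) is significantly nonzero by the
#' Bayes-factor test. This graph seeds both the global and the local search
#' space.
#'
#' @param ctx A `ci_context`.
#' @return Symmetric logical adjacency matrix.
#' @export
build_mrf <- function(ctx) {
  rho <- full_partial_matrix(ctx$r)
  dep <- if (is.null(ctx$limit_tol)) {
    dependent_matrix(rho, ctx$m, ctx$n, ctx$k)
  } else {
    d <- abs(rho) > ctx$limit_tol
    diag(d) <- FALSE
    d
  }
  dep <- dep | t(dep) # numerically symmetric already; be explicit
  dimnames(dep) <- dimnames(ctx$r)
  dep
}

#' Open-simple-path members of a conditioning set
#'
#' Z_m in Z has an open simple path to (i, j) on Z when both
#' rho_{i,Zm | Z+j-Zm} and rho_{j,Zm | Z+i-Zm} are significantly nonzero.
#' Such members sit on still-active paths; the d-separation search only ever
#' removes OSP members.
#'
#' @inheritParams local_partial
#' @return Integer vector: the subset of `z` with an OSP to (i, j).
#' @export
osp_members <- function(ctx, i, j, z) {
  if (length(z) == 0L) {
    return(integer(0))
  }
  keep <- vapply(z, function(zm) {
    zi <- setdiff(c(z, j), zm)
    if (!ci_decision(ctx, i, zm, zi)$dependent) return(FALSE)
    zj <- setdiff(c(z, i), zm)
    ci_decision(ctx, j, zm, zj)$dependent
  }, logical(1))
  z[keep]
}

#' Greedy search for a d-separating set
#'
#' Starts from the smaller of the two Markov blankets (minus the endpoints),
#' which is guaranteed to contain a d-separating set when one exists, and
#' greedily removes the OSP member whose removal leaves the fewest OSP
#' members, re-testing independence after every removal. Stops successfully
#' as soon as (i, j) test independent, and unsuccessfully when no member of
#' the current set has an OSP.
#'
#' @inheritParams local_partial
#' @param mrf The Markov random field from [build_mrf()].
#' @return A list of class `sepset_record` with elements `i`, `j`, `found`,
#'   `z` (final separating set when found), `z0` (initial set) and `removed`
#'   (removal order).
#' @export
find_dsep <- function(ctx, i, j, mrf) {
  if (!mrf[i, j]) {
    stop("find_dsep expects an MRF edge {i, j}", call. = FALSE)
  }
  mb_i <- setdiff(which(mrf[i, ]), c(i, j))
  mb_j <- setdiff(which(mrf[j, ]), c(i, j))
  z <- if (length(mb_i) <= length(mb_j)) mb_i else mb_j
  z0 <- z
  removed <- integer(0)
  repeat {
    if (!ci_decision(ctx, i, j, z)$dependent) {
      return(structure(
        list(i = i, j = j, found = TRUE, z = z, z0 = z0, removed = removed),
        class = "sepset_record"
      ))
    }
    osp <- osp_members(ctx, i, j, z)
    if (length(osp) == 0L) {
      return(structure(
        list(i = i, j = j, found = FALSE, z = z, z0 = z0, removed = removed),
        class = "sepset_record"
      ))
    }
    counts <- vapply(osp, function(zm) {
      length(osp_members(ctx, i, j, setdiff(z, zm)))
    }, integer(1))
    pick <- osp[which.min(counts)] # which.min: first minimum = lowest index
    z <- setdiff(z, pick)
    removed <- c(removed, pick)
  }
}

#' Identify colliders behind removed edges
#'
#' For each edge (i, j) removed in stage 2, candidate colliders are the
#' common MRF neighbours of i and j that are outside the final separating
#' set; U is declared a collider when conditioning on it re-opens the path,
#' i.e. (i, j) are independent given Z but dependent given Z + U. Each
#' collider contributes the directed prior edges i -> U and j -> U; a pair
#' whose insertion would make the prior edge set cyclic is dropped with a
#' warning.
#'
#' @param ctx A `ci_context`.
#' @param records List of `sepset_record`s with `found = TRUE`.
#' @param mrf The Markov random field.
#' @return Logical adjacency matrix of prior (parent -> collider) edges.
#' @export
identify_vstructures <- function(ctx, records, mrf) {
  n <- ctx$n
  v <- empty_graph(n, ctx$names)
  for (rec in records) {
    stopifnot(rec$found)
    i <- rec$i
    j <- rec$j
    cand <- setdiff(intersect(which(mrf[i, ]), which(mrf[j, ])),
                    c(i, j, rec$z))
    for (u in cand) {
      if (ci_decision(ctx, i, j, c(rec$z, u))$dependent) {
        g2 <- v
        g2[i, u] <- TRUE
        g2[j, u] <- TRUE
        if (is_acyclic(g2)) {
          v <- g2
        } else {
          warning("v-structure ", i, "->", u, "<-", j,
                  " dropped: would make the prior edge set cyclic",
                  call. = FALSE)
        }
      }
    }
  }
  v
}

#' Run the full constraint phase
#'
#' Executes the three stages in order and packages the results: the MRF
#' (= global search space GSS), the local search space LSS (the MRF minus
#' every edge for which a d-separating set was found), the separating-set
#' records and the v-structure prior.
#'
#' @param data A `data_matrix`, data frame, or an existing `ci_context`.
#' @param k Bayes-factor threshold (ignored when `data` is a context).
#' @return An object of class `sppc_result`: list with `gss`, `lss`, `mrf`,
#'   `priors` (directed adjacency), `sepsets`, `k`, `names`.
#' @examples
#' spec <- sem_spec(chain_dag(3), sem_id = 1)
#' ctx <- ci_context_cov(analytic_covariance(spec), m = 5000)
#' res <- run_sppc(ctx)
#' tidy(res)
#' @export
run_sppc <- function(data, k = 0.01) {
  ctx <- if (inherits(data, "ci_context")) data else ci_context(data, k)
  mrf <- build_mrf(ctx)
  n <- ctx$n
  records <- list()
  pairs <- which(upper.tri(mrf) & mrf, arr.ind = TRUE, useNames = FALSE)
  if (nrow(pairs)) {
    records <- lapply(seq_len(nrow(pairs)), function(r) {
      find_dsep(ctx, pairs[r, 1L], pairs[r, 2L], mrf)
    })
  }
  lss <- mrf
  found <- Filter(function(rec) rec$found, records)
  for (rec in found) {
    lss[rec$i, rec$j] <- FALSE
    lss[rec$j, rec$i] <- FALSE
  }
  priors <- identify_vstructures(ctx, found, mrf)
  structure(
    list(gss = mrf, lss = lss, mrf = mrf, priors = priors,
         sepsets = records, k = ctx$k, names = ctx$names),
    class = "sppc_result"
  )
}

#' @export
print.sppc_result <- function(x, ...) {
  cat("<sppc_result> ", length(x$names), " variables\n", sep = "")
  cat("  GSS edges: ", sum(x$gss) / 2L,
      "; LSS edges: ", sum(x$lss) / 2L,
      "; prior (v-structure) edges: ", sum(x$priors), "\n", sep = "")
  invisible(x)
}

#' @describeIn run_sppc Tidy the constraint-phase output into a tibble of
#'   edges with a `space` column (`"gss"`, `"lss"`, `"prior"`).
#' @param x An `sppc_result`.
#' @param ... Unused.
#' @method tidy sppc_result
#' @export
tidy.sppc_result <- function(x, ...) {
  und <- function(g) {
    idx <- which(upper.tri(g) & g, arr.ind = TRUE, useNames = FALSE)
    tibble(parent = x$names[idx[, 1L]], child = x$names[idx[, 2L]])
  }
  out <- rbind(
    cbind(und(x$gss), space = if (sum(x$gss)) "gss" else character(0)),
    cbind(und(x$lss), space = if (sum(x$lss)) "lss" else character(0)),
    cbind(edges_tbl(x$priors, x$names),
          space = if (sum(x$priors)) "prior" else character(0))
  )
  as_tibble(out)
}
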