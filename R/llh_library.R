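# The low-level heuristic library: 13 operators derived from swarm
# meta-heuristics (PSO, bacterial foraging, artificial bee colony,
# moth-flame, teaching-learning), plus prior-injection, pruning and
# local perturbation.
#
# Shared contract: an operator maps (subgroup, context) -> subgroup. Every
# produced graph is acyclic (cycle-creating proposals are skipped, never
# repaired), every proposed edge's unordered pair lies in the operator's
# designated search space, and each individual's `fitness` field is kept in
# sync through incremental score deltas. The move-acceptance regime of the
# hyper-heuristic is accept-all-moves: operators may worsen an individual;
# personal bests are maintained by the engine.
#
# "Global" operators (mutation, elimination-dispersal, scout bees) switch
# from the GSS to the complete search space once the engine's one-shot
# switching operator fires; all other operators stay on GSS/LSS.

#' Operator context
#'
#' Mutable bookkeeping shared by all low-level heuristics.
#'
#' @param sctx A `score_context`.
#' @param sppc An `sppc_result` (supplies GSS, LSS and the v-structure
#'   prior).
#' @param mu Pruning threshold (defaults to ln m).
#' @param lm Scout trigger: iterations of personal-best stagnation.
#' @param zj Proportion of a subgroup receiving expert guidance.
#' @param strict_mu_improvement If `TRUE`, greedy operator loops require a
#'   score gain above `mu` instead of above 0.
#' @return An environment of class `op_context`. Fields `c` (acceleration
#'   coefficient, scheduled 0.1 to 0.5 by the engine), `c3`
#'   (elimination-dispersal firing probability, 0.1 + 0.9 L/Lmax)
#'   and `css_active` are updated by the engine each iteration.
#' @export
op_context <- function(sctx, sppc, mu = NULL, lm = 20L, zj = 0.5,
                       strict_mu_improvement = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$sctx <- sctx
  ctx$gss <- sppc$gss
  ctx$lss <- sppc$lss
  ctx$priors <- sppc$priors
  ctx$css_active <- FALSE
  ctx$n <- ncol(sppc$gss)
  ctx$mu <- if (is.null(mu)) sctx$logm else mu
  ctx$lm <- as.integer(lm)
  ctx$zj <- zj
  ctx$strict <- isTRUE(strict_mu_improvement)
  ctx$c <- 0.1
  ctx$c3 <- 0.1
  # |full partial correlation|, used to sort candidate parents during the
  # elimination-dispersal restart
  r <- ctx$sctx$s / sqrt(tcrossprod(diag(ctx$sctx$s)))
  ctx$pc_abs <- abs(full_partial_matrix(r))
  class(ctx) <- "op_context"
  ctx
}

accept_thr <- function(ctx) if (ctx$strict) ctx$mu else 0

# Unordered-pair constraint matrix for an operator.
move_space <- function(ctx, global) {
  if (global && ctx$css_active) {
    sp <- matrix(TRUE, ctx$n, ctx$n)
    diag(sp) <- FALSE
    sp
  } else if (global) {
    ctx$gss
  } else {
    ctx$gss
  }
}

new_individual <- function(g, fitness) {
  list(g = g, fitness = fitness, pbest_g = g, pbest_fitness = fitness,
       stagnation = 0L)
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

# Propose one random move of a uniformly chosen type within `space`;
# infeasible proposals (no candidate, or cycle) return NULL.
random_move <- function(g, space) {
  type <- sample1(c("add", "delete", "reverse"))
  if (type == "add") {
    cand <- which(space & !g & !t(g))
    if (!length(cand)) return(NULL)
    cell <- sample1(cand)
    from <- (cell - 1L) %% nrow(g) + 1L
    to <- (cell - 1L) %/% nrow(g) + 1L
    if (creates_cycle(g, from, to)) return(NULL)
    list(type = "add", from = from, to = to)
  } else {
    cand <- which(g)
    if (!length(cand)) return(NULL)
    cell <- sample1(cand)
    from <- (cell - 1L) %% nrow(g) + 1L
    to <- (cell - 1L) %/% nrow(g) + 1L
    if (type == "reverse") {
      g2 <- g
      g2[from, to] <- FALSE
      if (has_path(g2, from, to)) return(NULL) # reversal would close a cycle
      list(type = "reverse", from = from, to = to)
    } else {
      list(type = "delete", from = from, to = to)
    }
  }
}

# Apply one random move to an individual. accept = "all" applies
# unconditionally; "better" keeps the old graph unless the move improves.
step_individual <- function(ind, ctx, space, accept = "all") {
  mv <- random_move(ind$g, space)
  if (is.null(mv)) return(ind)
  d <- delta_score(ctx$sctx, ind$g, mv)
  if (accept == "better" && d <= 0) return(ind)
  ind$g <- apply_move(ind$g, mv)
  ind$fitness <- ind$fitness + d
  ind
}

# Edge-difference adoption: make the individual's graph agree with `guide`
# on each differing ordered cell independently with probability `prob`,
# visiting the differences in random order and skipping cycle-creating
# adoptions. Shared learning rule of the cognitive, cooperative, moth-flame
# and TLBO operators.
adopt_from_guide <- function(ind, guide, prob, ctx) {
  diffs <- which(ind$g != guide)
  if (!length(diffs) || prob <= 0) return(ind)
  diffs <- diffs[sample.int(length(diffs))]
  n <- nrow(ind$g)
  for (cell in diffs) {
    if (runif(1) >= prob) next
    from <- (cell - 1L) %% n + 1L
    to <- (cell - 1L) %/% n + 1L
    if (ind$g[from, to] == guide[from, to]) next # fixed by an earlier step
    if (!guide[from, to]) {
      d <- delta_score(ctx$sctx, ind$g, list(type = "delete",
                                             from = from, to = to))
      ind$g[from, to] <- FALSE
      ind$fitness <- ind$fitness + d
    } else if (ind$g[to, from]) {
      # opposite edge present: adopting means reversing to -> from
      g2 <- ind$g
      g2[to, from] <- FALSE
      if (has_path(g2, to, from)) next
      d <- delta_score(ctx$sctx, ind$g, list(type = "reverse",
                                             from = to, to = from))
      ind$g[to, from] <- FALSE
      ind$g[from, to] <- TRUE
      ind$fitness <- ind$fitness + d
    } else {
      if (creates_cycle(ind$g, from, to)) next
      d <- delta_score(ctx$sctx, ind$g, list(type = "add",
                                             from = from, to = to))
      ind$g[from, to] <- TRUE
      ind$fitness <- ind$fitness + d
    }
  }
  ind
}

best_index <- function(subgroup) {
  which.max(vapply(subgroup, `[[`, numeric(1), "fitness"))
}

# ---- greedy node-local passes (chemotaxis building blocks) ----------------

greedy_add_pass <- function(g, fit, v, ctx, space, collect = FALSE) {
  thr <- accept_thr(ctx)
  added <- integer(0)
  repeat {
    cand <- which(space[, v] & !g[, v] & !g[v, ])
    cand <- setdiff(cand, v)
    if (!length(cand)) break
    deltas <- vapply(cand, function(u) {
      if (creates_cycle(g, u, v)) return(-Inf)
      delta_score(ctx$sctx, g, list(type = "add", from = u, to = v))
    }, numeric(1))
    b <- which.max(deltas)
    if (deltas[[b]] <= thr) break
    u <- cand[[b]]
    g[u, v] <- TRUE
    fit <- fit + deltas[[b]]
    if (collect) added <- c(added, u)
  }
  list(g = g, fit = fit, added = added)
}

greedy_delete_pass <- function(g, fit, v, ctx, among = NULL) {
  thr <- accept_thr(ctx)
  repeat {
    pars <- which(g[, v])
    if (!is.null(among)) pars <- intersect(pars, among)
    if (!length(pars)) break
    deltas <- vapply(pars, function(u) {
      delta_score(ctx$sctx, g, list(type = "delete", from = u, to = v))
    }, numeric(1))
    b <- which.max(deltas)
    if (deltas[[b]] <= thr) break
    g[pars[[b]], v] <- FALSE
    fit <- fit + deltas[[b]]
  }
  list(g = g, fit = fit)
}

greedy_reverse_pass <- function(g, fit, v, ctx) {
  thr <- accept_thr(ctx)
  repeat {
    pars <- which(g[, v])
    if (!length(pars)) break
    deltas <- vapply(pars, function(u) {
      g2 <- g
      g2[u, v] <- FALSE
      if (has_path(g2, u, v)) return(-Inf)
      delta_score(ctx$sctx, g, list(type = "reverse", from = u, to = v))
    }, numeric(1))
    b <- which.max(deltas)
    if (deltas[[b]] <= thr) break
    u <- pars[[b]]
    g[u, v] <- FALSE
    g[v, u] <- TRUE
    fit <- fit + deltas[[b]]
  }
  list(g = g, fit = fit)
}

chemotaxis_passes <- function(g, fit, v, ctx, space) {
  st <- greedy_add_pass(g, fit, v, ctx, space)
  st <- greedy_delete_pass(st$g, st$fit, v, ctx)
  greedy_reverse_pass(st$g, st$fit, v, ctx)
}

# ---- the 13 operators ------------------------------------------------------

op_mutation <- function(subgroup, ctx) {
  space <- move_space(ctx, global = TRUE)
  lapply(subgroup, step_individual, ctx = ctx, space = space, accept = "all")
}

op_cognitive_personal <- function(subgroup, ctx) {
  lapply(subgroup, function(ind) {
    adopt_from_guide(ind, ind$pbest_g, ctx$c, ctx)
  })
}

op_cooperative_global <- function(subgroup, ctx) {
  guide <- subgroup[[best_index(subgroup)]]$g
  lapply(subgroup, adopt_from_guide, guide = guide, prob = ctx$c, ctx = ctx)
}

op_chemotactic <- function(subgroup, ctx) {
  lapply(subgroup, function(ind) {
    v <- sample.int(ctx$n, 1L)
    st <- chemotaxis_passes(ind$g, ind$fitness, v, ctx, ctx$gss)
    ind$g <- st$g
    ind$fitness <- st$fit
    ind
  })
}

# Local restart of the subgroup's best structure around one node: strip the
# node's parents, collect a potential parent set by a scratch addition
# chemotaxis, sort it by |full partial correlation| with the node, re-add
# improving candidates one by one, greedily drop the worst added parent
# while the score improves, and finish with one reversion pass. Fires with
# probability c3.
op_elimination_dispersal <- function(subgroup, ctx) {
  if (runif(1) >= ctx$c3) return(subgroup)
  space <- move_space(ctx, global = TRUE)
  b <- best_index(subgroup)
  ind <- subgroup[[b]]
  v <- sample.int(ctx$n, 1L)
  g <- ind$g
  fit <- ind$fitness
  for (u in which(g[, v])) {
    fit <- fit + delta_score(ctx$sctx, g, list(type = "delete",
                                               from = u, to = v))
    g[u, v] <- FALSE
  }
  # scratch pass: find the potential parent set without updating g
  pot <- greedy_add_pass(g, fit, v, ctx, space, collect = TRUE)$added
  if (length(pot)) {
    pot <- pot[order(ctx$pc_abs[pot, v], decreasing = TRUE)]
    thr <- accept_thr(ctx)
    added <- integer(0)
    for (u in pot) {
      if (g[u, v] || g[v, u] || creates_cycle(g, u, v)) next
      d <- delta_score(ctx$sctx, g, list(type = "add", from = u, to = v))
      if (d > thr) {
        g[u, v] <- TRUE
        fit <- fit + d
        added <- c(added, u)
      }
    }
    st <- greedy_delete_pass(g, fit, v, ctx, among = added)
    st <- greedy_reverse_pass(st$g, st$fit, v, ctx)
    g <- st$g
    fit <- st$fit
  }
  ind$g <- g
  ind$fitness <- fit
  subgroup[[b]] <- ind
  subgroup
}

op_worker_bees <- function(subgroup, ctx) {
  lapply(subgroup, step_individual, ctx = ctx, space = ctx$gss,
         accept = "better")
}

op_onlooker_bees <- function(subgroup, ctx) {
  fits <- vapply(subgroup, `[[`, numeric(1), "fitness")
  w <- rank(fits, ties.method = "average")
  draws <- sample.int(length(subgroup), length(subgroup), replace = TRUE,
                      prob = w / sum(w))
  for (i in draws) {
    subgroup[[i]] <- step_individual(subgroup[[i]], ctx, ctx$gss,
                                     accept = "better")
  }
  subgroup
}

# Parent-child transformation restart, fired per individual once its
# personal best has stagnated for lm iterations: each recorded parent of a
# chosen node is reversed in turn and polished by the three chemotaxis
# passes; the result replaces the working structure only when it beats the
# best seen so far in the restart.
op_scout_bees <- function(subgroup, ctx) {
  space <- move_space(ctx, global = TRUE)
  lapply(subgroup, function(ind) {
    if (ind$stagnation < ctx$lm) return(ind)
    v <- sample.int(ctx$n, 1L)
    pars <- which(ind$g[, v])
    ind$stagnation <- 0L
    if (!length(pars)) return(ind)
    cur_g <- ind$g
    cur_fit <- ind$fitness
    for (p in pars) {
      if (!cur_g[p, v]) next
      g2 <- cur_g
      g2[p, v] <- FALSE
      if (has_path(g2, p, v)) next
      d <- delta_score(ctx$sctx, cur_g, list(type = "reverse",
                                             from = p, to = v))
      g2[v, p] <- TRUE
      st <- chemotaxis_passes(g2, cur_fit + d, v, ctx, space)
      if (st$fit > cur_fit) {
        cur_g <- st$g
        cur_fit <- st$fit
      }
    }
    ind$g <- cur_g
    ind$fitness <- cur_fit
    ind
  })
}

op_moth_flame <- function(subgroup, ctx) {
  flames <- lapply(subgroup, `[[`, "pbest_g")
  flames <- flames[sample.int(length(flames))]
  Map(function(ind, flame) adopt_from_guide(ind, flame, ctx$c, ctx),
      subgroup, flames)
}

op_tlbo_learner <- function(subgroup, ctx) {
  ns <- length(subgroup)
  if (ns < 2L) return(subgroup)
  lapply(seq_len(ns), function(i) {
    partner <- sample1(setdiff(seq_len(ns), i))
    if (subgroup[[partner]]$fitness > subgroup[[i]]$fitness) {
      adopt_from_guide(subgroup[[i]], subgroup[[partner]]$g, ctx$c, ctx)
    } else {
      subgroup[[i]]
    }
  })
}

# Force all identified v-structure edges into a random zj-proportion of the
# subgroup. Opposing edges are deleted; a cycle created by an insertion is
# broken by deleting the cycle edge whose removal costs the least fitness
# (prior edges are spared when any other cycle edge exists).
op_expert_knowledge <- function(subgroup, ctx) {
  pe <- which(ctx$priors, arr.ind = TRUE, useNames = FALSE)
  if (!nrow(pe)) return(subgroup)
  nsel <- ceiling(ctx$zj * length(subgroup))
  sel <- sample.int(length(subgroup), nsel)
  for (s in sel) {
    ind <- subgroup[[s]]
    for (r in seq_len(nrow(pe))) {
      u <- pe[r, 1L]
      v <- pe[r, 2L]
      if (ind$g[u, v]) next
      if (ind$g[v, u]) {
        d <- delta_score(ctx$sctx, ind$g, list(type = "delete",
                                               from = v, to = u))
        ind$g[v, u] <- FALSE
        ind$fitness <- ind$fitness + d
      }
      guard <- 0L
      while (has_path(ind$g, v, u) && guard < ctx$n^2) {
        guard <- guard + 1L
        path <- directed_path(ind$g, v, u)
        cells <- cbind(path[-length(path)], path[-1L])
        is_prior <- ctx$priors[cells]
        if (any(!is_prior)) cells <- cells[!is_prior, , drop = FALSE]
        deltas <- vapply(seq_len(nrow(cells)), function(rr) {
          delta_score(ctx$sctx, ind$g,
                      list(type = "delete", from = cells[rr, 1L],
                           to = cells[rr, 2L]))
        }, numeric(1))
        bb <- which.max(deltas) # least fitness loss
        ind$g[cells[bb, 1L], cells[bb, 2L]] <- FALSE
        ind$fitness <- ind$fitness + deltas[[bb]]
      }
      d <- delta_score(ctx$sctx, ind$g, list(type = "add",
                                             from = u, to = v))
      ind$g[u, v] <- TRUE
      ind$fitness <- ind$fitness + d
    }
    subgroup[[s]] <- ind
  }
  subgroup
}

op_pruning <- function(subgroup, ctx) {
  lapply(subgroup, function(ind) {
    edges <- which(ind$g) # fixed column-major scan order
    n <- nrow(ind$g)
    for (cell in edges) {
      from <- (cell - 1L) %% n + 1L
      to <- (cell - 1L) %/% n + 1L
      if (!ind$g[from, to]) next
      d <- delta_score(ctx$sctx, ind$g, list(type = "delete",
                                             from = from, to = to))
      if (-d < ctx$mu) { # edge's score contribution below the threshold
        ind$g[from, to] <- FALSE
        ind$fitness <- ind$fitness + d
      }
    }
    ind
  })
}

op_neighborhood_perturbation <- function(subgroup, ctx) {
  lapply(subgroup, function(ind) {
    for (b in seq_len(sample.int(3L, 1L))) {
      ind <- step_individual(ind, ctx, ctx$lss, accept = "all")
    }
    ind
  })
}

# Extract one directed path from `from` to `to` (BFS predecessor chain);
# assumes such a path exists.
directed_path <- function(g, from, to) {
  n <- nrow(g)
  pred <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      ch <- which(g[u, ] & !seen)
      pred[ch] <- u
      seen[ch] <- TRUE
      nxt <- c(nxt, ch)
    }
    if (seen[to]) break
    frontier <- nxt
  }
  stopifnot(seen[to])
  path <- to
  while (path[[1L]] != from) path <- c(pred[[path[[1L]]]], path)
  path
}

#' Registry of the 13 low-level heuristics
#'
#' @return A named list; each entry has `fn` (the operator) and `global`
#'   (`TRUE` for the restart/randomisation operators that move to the
#'   complete search space after switching).
#' @export
llh_registry <- function() {
  list(
    mutation = list(fn = op_mutation, global = TRUE),
    cognitive_personal = list(fn = op_cognitive_personal, global = FALSE),
    cooperative_global = list(fn = op_cooperative_global, global = FALSE),
    chemotactic = list(fn = op_chemotactic, global = FALSE),
    elimination_dispersal = list(fn = op_elimination_dispersal,
                                 global = TRUE),
    worker_bees = list(fn = op_worker_bees, global = FALSE),
    onlooker_bees = list(fn = op_onlooker_bees, global = FALSE),
    scout_bees = list(fn = op_scout_bees, global = TRUE),
    moth_flame = list(fn = op_moth_flame, global = FALSE),
    tlbo_learner = list(fn = op_tlbo_learner, global = FALSE),
    expert_knowledge = list(fn = op_expert_knowledge, global = FALSE),
    pruning = list(fn = op_pruning, global = FALSE),
    neighborhood_perturbation = list(fn = op_neighborhood_perturbation,
                                     global = FALSE)
  )
}
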