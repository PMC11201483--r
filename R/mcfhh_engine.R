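# The multi-population choice-function hyper-heuristic engine.
#
# The population is initialised from the v-structure prior, split evenly
# into subgroups, and each subgroup runs its own choice function over the
# 13-operator library under accept-all-moves. A ring migration (throttled
# by the inbreeding rate) couples the subgroups, and a one-shot search-space
# switch widens the global operators from the GSS to the complete graph
# once the global best stagnates; a second stagnation of the same length
# (or the iteration cap) terminates the run.

#' Engine configuration
#'
#' Defaults reproduce the method's standard parameterisation: Bayes-factor
#' threshold k = 0.01, population 50 in 5 subgroups, stagnation window
#' Lmax = 2n, iteration cap 5000, scout trigger lm = 20, expert proportion
#' zj = 0.5, pruning threshold mu = ln m, migration every min(100, n)
#' iterations, inbreeding distance 4 with cap 0.6.
#'
#' @param n Number of variables (sets `Lmax` and the migration interval).
#' @param m Sample size (sets `mu = ln m`).
#' @param ... Overrides for any of the fields listed above, plus
#'   `nll_factor` (see [score_context()]), `strict_mu_improvement`,
#'   `switch_enabled` (set `FALSE` for the no-switching ablation) and
#'   `f3_time` ("seconds" or "iteration"; iteration mode makes runs fully
#'   deterministic under a seed).
#' @return A list of class `mcfhh_config`.
#' @export
mcfhh_config <- function(n, m, ...) {
  cfg <- list(
    k = 0.01, n_pop = 50L, sn = 5L, l_max = 2L * n, max_it = 5000L,
    lm = 20L, zj = 0.5, mu = log(m),
    migration_interval = min(100L, n), inbreed_dist = 4L, inbreed_cap = 0.6,
    nll_factor = 0.5, strict_mu_improvement = FALSE,
    switch_enabled = TRUE, f3_time = "seconds"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(cfg, dots)
  if (cfg$n_pop %% cfg$sn != 0L) {
    pad <- cfg$sn - cfg$n_pop %% cfg$sn
    warning("n_pop padded from ", cfg$n_pop, " to ", cfg$n_pop + pad,
            " to divide evenly into ", cfg$sn, " subgroups", call. = FALSE)
    cfg$n_pop <- cfg$n_pop + pad
  }
  structure(cfg, class = "mcfhh_config")
}

# All improving single-edge moves (add/delete/reverse) within `space`,
# with their score deltas. Used by the hill-climbing initialisation.
improving_moves <- function(g, ctx, space) {
  thr <- accept_thr(ctx)
  n <- nrow(g)
  moves <- list()
  deltas <- numeric(0)
  push <- function(mv, d) {
    moves[[length(moves) + 1L]] <<- mv
    deltas <<- c(deltas, d)
  }
  for (cell in which(space & !g & !t(g))) {
    from <- (cell - 1L) %% n + 1L
    to <- (cell - 1L) %/% n + 1L
    if (creates_cycle(g, from, to)) next
    d <- delta_score(ctx$sctx, g, list(type = "add", from = from, to = to))
    if (d > thr) push(list(type = "add", from = from, to = to), d)
  }
  for (cell in which(g)) {
    from <- (cell - 1L) %% n + 1L
    to <- (cell - 1L) %/% n + 1L
    d <- delta_score(ctx$sctx, g, list(type = "delete",
                                       from = from, to = to))
    if (d > thr) push(list(type = "delete", from = from, to = to), d)
    g2 <- g
    g2[from, to] <- FALSE
    if (!has_path(g2, from, to)) {
      d <- delta_score(ctx$sctx, g, list(type = "reverse",
                                         from = from, to = to))
      if (d > thr) push(list(type = "reverse", from = from, to = to), d)
    }
  }
  list(moves = moves, deltas = deltas)
}

#' Initialise the population from the v-structure prior
#'
#' Every individual starts as the DAG of prior edges and then performs
#' r ~ Uniform\{1..n\} single-edge hill-climbing moves within the GSS, each
#' drawn uniformly from the currently improving moves (accepting only
#' improvements). Randomising both the depth r and the climbing path is
#' what diversifies the population; a deterministic steepest-ascent climb
#' would collapse all individuals onto one local optimum and neutralise
#' every guide-learning operator. Personal bests start at the individual
#' itself.
#'
#' @param ctx An `op_context`.
#' @param cfg An `mcfhh_config`.
#' @return List of `n_pop` individuals.
#' @export
init_population <- function(ctx, cfg) {
  g0 <- ctx$priors
  if (!is_acyclic(g0)) {
    stop("prior edge set is cyclic", call. = FALSE)
  }
  fit0 <- graph_score(ctx$sctx, g0)
  lapply(seq_len(cfg$n_pop), function(i) {
    g <- g0
    fit <- fit0
    for (step in seq_len(sample.int(ctx$n, 1L))) {
      im <- improving_moves(g, ctx, ctx$gss)
      if (!length(im$moves)) break
      pick <- sample.int(length(im$moves), 1L)
      g <- apply_move(g, im$moves[[pick]])
      fit <- fit + im$deltas[[pick]]
    }
    new_individual(g, fit)
  })
}

#' Ring migration with inbreeding control
#'
#' The inbreeding rate is the fraction of subgroups whose best individual
#' lies within Hamming distance `inbreed_dist` of the global best; when it
#' exceeds `inbreed_cap` the whole round is skipped. Otherwise a copy of
#' each subgroup's best replaces the worst individual of the next subgroup
#' in the ring.
#'
#' @param subgroups List of subgroups (lists of individuals).
#' @param cfg An `mcfhh_config`.
#' @return List with `subgroups` (possibly updated) and `rate`.
#' @export
migrate <- function(subgroups, cfg) {
  sn <- length(subgroups)
  bests <- lapply(subgroups, function(sg) sg[[best_index(sg)]])
  gfit <- vapply(bests, `[[`, numeric(1), "fitness")
  gbest <- bests[[which.max(gfit)]]
  close <- vapply(bests, function(b) {
    hamming_distance(b$g, gbest$g) < cfg$inbreed_dist
  }, logical(1))
  rate <- sum(close) / sn
  if (rate > cfg$inbreed_cap) {
    return(list(subgroups = subgroups, rate = rate, skipped = TRUE))
  }
  for (s in seq_len(sn)) {
    dst <- s %% sn + 1L
    fits <- vapply(subgroups[[dst]], `[[`, numeric(1), "fitness")
    worst <- which.min(fits)
    subgroups[[dst]][[worst]] <- bests[[s]]
  }
  list(subgroups = subgroups, rate = rate, skipped = FALSE)
}

#' Run the hyper-heuristic search
#'
#' Runs the constraint phase (unless an `sppc_result` is supplied), builds
#' the scoring and operator contexts, and iterates the per-subgroup
#' choice-function loops with migration, one-shot search-space switching
#' and stagnation-based termination.
#'
#' @param data A `data_matrix` or data frame.
#' @param cfg An `mcfhh_config`; defaults to `mcfhh_config(n, m)` for the
#'   data at hand.
#' @param sppc Optional precomputed `sppc_result`.
#' @param seed Optional integer seed (set once, up front).
#' @return An object of class `mcfhh_fit`: `best` (adjacency),
#'   `best_fitness`, `trace` (per-iteration global best), `operator_log`
#'   (tibble), `switched_at`, `iterations`, `names`, `sppc`, `config`.
#' @examples
#' spec <- sem_spec(collider_dag(), sem_id = 1)
#' dm <- simulate_sem(spec, 2000)
#' fit <- mcfhh(dm, mcfhh_config(3, 2000, f3_time = "iteration"), seed = 1)
#' tidy(fit)
#' @export
mcfhh <- function(data, cfg = NULL, sppc = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dm <- as_data_matrix(data)
  if (is.null(cfg)) cfg <- mcfhh_config(dm$n, dm$m)
  if (is.null(sppc)) sppc <- run_sppc(dm, cfg$k)
  sctx <- score_context(dm, nll_factor = cfg$nll_factor)
  ctx <- op_context(sctx, sppc, mu = cfg$mu, lm = cfg$lm, zj = cfg$zj,
                    strict_mu_improvement = cfg$strict_mu_improvement)
  registry <- llh_registry()
  n_ops <- length(registry)
  iter_time <- identical(cfg$f3_time, "iteration")

  pop <- init_population(ctx, cfg)
  sizes <- rep(cfg$n_pop %/% cfg$sn, cfg$sn)
  subgroups <- split(pop, rep(seq_len(cfg$sn), times = sizes))
  states <- lapply(seq_len(cfg$sn), function(s) cf_state(n_ops))

  sg_best <- function(sg) max(vapply(sg, `[[`, numeric(1), "fitness"))
  gbest_fit <- max(vapply(subgroups, sg_best, numeric(1)))
  gbest_g <- NULL
  for (sg in subgroups) {
    b <- sg[[best_index(sg)]]
    if (b$fitness >= gbest_fit) gbest_g <- b$g
  }

  l_stag <- 0L
  switched_at <- NA_integer_
  trace <- numeric(0)
  log_iter <- integer(0)
  log_sub <- integer(0)
  log_op <- character(0)
  log_delta <- numeric(0)
  log_dur <- numeric(0)
  log_phi <- numeric(0)
  it <- 0L

  while (it < cfg$max_it) {
    it <- it + 1L
    ctx$c <- 0.1 + 0.4 * it / cfg$max_it
    ctx$c3 <- 0.1 + 0.9 * min(l_stag, cfg$l_max) / cfg$l_max
    for (s in seq_len(cfg$sn)) {
      st <- states[[s]]
      op <- cf_select(st)
      entry <- registry[[op]]
      before <- sg_best(subgroups[[s]])
      t0 <- proc.time()[["elapsed"]]
      subgroups[[s]] <- entry$fn(subgroups[[s]], ctx)
      dur <- if (iter_time) 1 else
        max(proc.time()[["elapsed"]] - t0, .Machine$double.eps)
      after <- sg_best(subgroups[[s]])
      dfit <- after - before
      cf_record(st, op, dfit, dur)
      cf_update_weights(st, improved = dfit > 0)
      # personal bests and stagnation
      subgroups[[s]] <- lapply(subgroups[[s]], function(ind) {
        if (ind$fitness > ind$pbest_fitness) {
          ind$pbest_fitness <- ind$fitness
          ind$pbest_g <- ind$g
          ind$stagnation <- 0L
        } else {
          ind$stagnation <- ind$stagnation + 1L
        }
        ind
      })
      log_iter <- c(log_iter, it)
      log_sub <- c(log_sub, s)
      log_op <- c(log_op, names(registry)[[op]])
      log_delta <- c(log_delta, dfit)
      log_dur <- c(log_dur, dur)
      log_phi <- c(log_phi, st$phi)
    }
    new_best <- max(vapply(subgroups, sg_best, numeric(1)))
    if (new_best > gbest_fit) {
      gbest_fit <- new_best
      for (sg in subgroups) {
        b <- sg[[best_index(sg)]]
        if (b$fitness >= gbest_fit) gbest_g <- b$g
      }
      l_stag <- 0L
    } else {
      l_stag <- l_stag + 1L
    }
    trace <- c(trace, gbest_fit)
    if (it %% cfg$migration_interval == 0L) {
      subgroups <- migrate(subgroups, cfg)$subgroups
    }
    if (l_stag >= cfg$l_max) {
      if (cfg$switch_enabled && !ctx$css_active) {
        ctx$css_active <- TRUE
        switched_at <- it
        l_stag <- 0L
      } else {
        break
      }
    }
  }

  structure(
    list(
      best = gbest_g, best_fitness = gbest_fit, trace = trace,
      operator_log = tibble(
        iteration = log_iter, subgroup = log_sub, operator = log_op,
        delta = log_delta, duration = log_dur, phi = log_phi
      ),
      switched_at = switched_at, iterations = it,
      names = dm$names, sppc = sppc, config = cfg
    ),
    class = "mcfhh_fit"
  )
}

#' @export
print.mcfhh_fit <- function(x, ...) {
  cat("<mcfhh_fit> ", length(x$names), " variables, ",
      sum(x$best), " edges\n", sep = "")
  cat("  best fitness: ", format(x$best_fitness), " after ",
      x$iterations, " iterations",
      if (!is.na(x$switched_at)) {
        paste0(" (search space switched at ", x$switched_at, ")")
      }, "\n", sep = "")
  invisible(x)
}

#' @describeIn mcfhh Learned edges as a tibble (`parent`, `child`).
#' @param x An `mcfhh_fit`.
#' @param ... Unused.
#' @method tidy mcfhh_fit
#' @export
tidy.mcfhh_fit <- function(x, ...) {
  edges_tbl(x$best, x$names)
}

#' @describeIn mcfhh One-row run summary.
#' @method glance mcfhh_fit
#' @export
glance.mcfhh_fit <- function(x, ...) {
  tibble(
    n_vars = length(x$names), n_edges = sum(x$best),
    best_fitness = x$best_fitness, iterations = x$iterations,
    switched_at = x$switched_at,
    gss_edges = sum(x$sppc$gss) / 2L, lss_edges = sum(x$sppc$lss) / 2L,
    prior_edges = sum(x$sppc$priors)
  )
}

#' @describeIn mcfhh Convergence trace (global best fitness per iteration).
#' @param object An `mcfhh_fit`.
#' @method autoplot mcfhh_fit
#' @export
autoplot.mcfhh_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$trace),
               best_fitness = object$trace)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Best BIC fitness")
  if (!is.na(object$switched_at)) {
    p <- p + ggplot2::geom_vline(xintercept = object$switched_at,
                                 linetype = "dashed")
  }
  p
}
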