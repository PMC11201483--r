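test_that("configuration defaults mirror the standard parameterisation", {
  cfg <- mcfhh_config(37, 1000)
  expect_equal(cfg$k, 0.01)
  expect_equal(cfg$n_pop, 50L)
  expect_equal(cfg$sn, 5L)
  expect_equal(cfg$l_max, 74L)
  expect_equal(cfg$max_it, 5000L)
  expect_equal(cfg$lm, 20L)
  expect_equal(cfg$zj, 0.5)
  expect_equal(cfg$mu, log(1000))
  expect_equal(cfg$migration_interval, 37L)
  expect_equal(mcfhh_config(150, 1000)$migration_interval, 100L)
  expect_warning(cfg2 <- mcfhh_config(5, 100, n_pop = 7L, sn = 5L),
                 "padded")
  expect_equal(cfg2$n_pop, 10L)
  expect_error(mcfhh_config(5, 100, bogus = 1), "unknown config")
})

test_that("initial individuals contain all prior edges and beat the empty
           graph", {
  set.seed(51)
  spec <- sem_spec(collider_dag(), 1, w = collider_dag() * 1)
  dm <- simulate_sem(spec, 2000)
  sppc <- run_sppc(dm, 0.01)
  sctx <- score_context(dm)
  ctx <- op_context(sctx, sppc)
  cfg <- mcfhh_config(3, 2000, n_pop = 10L, sn = 5L)
  pop <- init_population(ctx, cfg)
  expect_length(pop, 10)
  pe <- which(sppc$priors)
  empty_score <- graph_score(sctx, causalhh:::empty_graph(3))
  for (ind in pop) {
    expect_true(all(ind$g[pe]))
    expect_true(is_acyclic(ind$g))
    expect_gte(ind$fitness, empty_score)
    expect_equal(ind$fitness, graph_score(sctx, ind$g), tolerance = 1e-8)
    expect_identical(ind$pbest_g, ind$g)
  }
})

test_that("migration swaps ring-wise and is throttled by inbreeding", {
  set.seed(52)
  dm <- simulate_sem(sem_spec(random_dag(6, 2), 1), 300)
  sctx <- score_context(dm)
  cfg <- mcfhh_config(6, 300, sn = 5L)
  make_sg <- function(g, fit = 0) {
    lapply(1:2, function(i) causalhh:::new_individual(g, fit - i + 1))
  }
  g0 <- causalhh:::empty_graph(6)
  # all subgroup bests identical: rate 1 > 0.6, skipped
  sgs <- replicate(5, make_sg(g0), simplify = FALSE)
  out <- migrate(sgs, cfg)
  expect_true(out$skipped)
  expect_equal(out$rate, 1)
  # distant bests migrate; subgroup sizes unchanged
  far_g <- function(i) {
    g <- g0
    g[i, 3:6] <- TRUE # 4+ ordered cells away from every other best
    g[i, i] <- FALSE
    g
  }
  # the highest-fitness best is the true-structure-like graph; three copies
  # of it (distance 0) against two far graphs puts the rate exactly at the
  # 0.6 cap, which the strictly-greater skip rule lets through
  best_g <- g0
  best_g[1, 2] <- TRUE
  gs3 <- c(replicate(3, best_g, simplify = FALSE),
           list(far_g(1), far_g(2)))
  sgs3 <- Map(make_sg, gs3, fit = c(10, 9, 8, 2, 1))
  out3 <- migrate(sgs3, cfg)
  expect_equal(out3$rate, 0.6)
  expect_false(out3$skipped)
  expect_true(all(lengths(out3$subgroups) == 2))
  # ring copy: the worst of subgroup 5 becomes a copy of subgroup 4's best
  expect_identical(out3$subgroups[[5]][[2]]$g, far_g(1))
  expect_equal(out3$subgroups[[5]][[2]]$fitness, 2)
})

test_that("the engine recovers the collider exactly", {
  set.seed(53)
  spec <- sem_spec(collider_dag(), 1, w = collider_dag() * 1)
  dm <- simulate_sem(spec, 5000)
  fit <- mcfhh(dm, mcfhh_config(3, 5000, f3_time = "iteration"), seed = 5)
  expect_identical(unname(fit$best), unname(collider_dag()))
  expect_true(all(diff(fit$trace) >= 0))
  expect_equal(fit$best_fitness, graph_score(score_context(dm), fit$best),
               tolerance = 1e-8)
})

test_that("identical seeds give bit-identical runs in iteration mode", {
  set.seed(54)
  g <- random_dag(8, 2)
  spec <- sem_spec(g, 1)
  dm <- simulate_sem(spec, 500)
  cfg <- mcfhh_config(8, 500, f3_time = "iteration", n_pop = 20L)
  f1 <- suppressWarnings(mcfhh(dm, cfg, seed = 99))
  f2 <- suppressWarnings(mcfhh(dm, cfg, seed = 99))
  expect_identical(f1$best, f2$best)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$operator_log, f2$operator_log)
  expect_identical(f1$switched_at, f2$switched_at)
})

test_that("the no-switching ablation terminates at the first stagnation", {
  set.seed(55)
  dm <- simulate_sem(sem_spec(random_dag(6, 2), 1), 500)
  cfg <- mcfhh_config(6, 500, f3_time = "iteration", n_pop = 20L,
                      switch_enabled = FALSE)
  fit <- mcfhh(dm, cfg, seed = 3)
  expect_true(is.na(fit$switched_at))
  cfg2 <- mcfhh_config(6, 500, f3_time = "iteration", n_pop = 20L)
  fit2 <- mcfhh(dm, cfg2, seed = 3)
  expect_false(is.na(fit2$switched_at)) # the latch fired exactly once
  expect_gte(fit2$iterations, fit$iterations)
})

test_that("fit accessors: tidy edges, glance row, convergence plot", {
  set.seed(56)
  spec <- sem_spec(collider_dag(), 1, w = collider_dag() * 1)
  dm <- simulate_sem(spec, 2000)
  fit <- mcfhh(dm, mcfhh_config(3, 2000, f3_time = "iteration"), seed = 1)
  tb <- tidy(fit)
  expect_s3_class(tb, "tbl_df")
  expect_setequal(tb$child, "z")
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$n_edges, 2L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  # operator log partitions all calls among the 13 registered heuristics
  expect_true(all(fit$operator_log$operator %in% names(llh_registry())))
  expect_equal(nrow(fit$operator_log), fit$iterations * 5)
})
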