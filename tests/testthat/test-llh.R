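# Operator-library fixture: a 6-node SEM dataset with its constraint-phase
# spaces, plus an operator context in the default (pre-switch) regime.

llh_fixture <- function(seed = 42, m = 800, n = 6) {
  set.seed(seed)
  g <- random_dag(n, 2)
  spec <- sem_spec(g, 1)
  dm <- simulate_sem(spec, m)
  sppc <- suppressWarnings(run_sppc(dm, 0.01))
  sctx <- score_context(dm)
  ctx <- op_context(sctx, sppc)
  ctx$c <- 0.3
  list(g = g, dm = dm, sppc = sppc, sctx = sctx, ctx = ctx)
}

test_that("the registry exposes exactly 13 operators", {
  reg <- llh_registry()
  expect_length(reg, 13)
  expect_true(all(vapply(reg, function(e) is.function(e$fn), logical(1))))
  expect_setequal(
    names(reg)[vapply(reg, `[[`, logical(1), "global")],
    c("mutation", "elimination_dispersal", "scout_bees")
  )
})

test_that("every operator preserves acyclicity, fitness sync and the GSS", {
  fx <- llh_fixture()
  set.seed(1)
  for (nm in names(llh_registry())) {
    entry <- llh_registry()[[nm]]
    sg <- random_subgroup(fx$sctx, fx$sppc$gss, size = 5)
    sg <- lapply(sg, function(ind) {
      ind$stagnation <- 25L # arm the scout
      ind
    })
    fx$ctx$c3 <- 1 # make elimination-dispersal always fire
    out <- entry$fn(sg, fx$ctx)
    expect_length(out, 5)
    expect_operator_contract(out, fx$sctx, fx$sppc$gss)
  }
})

test_that("random move proposals: uniform types, cycles rejected", {
  set.seed(2)
  # single-edge graph on 4 nodes: every move type is always feasible, so
  # accepted-type frequencies reflect the uniform type choice directly
  g <- causalhh:::empty_graph(4)
  g[1, 2] <- TRUE
  space <- matrix(TRUE, 4, 4)
  diag(space) <- FALSE
  types <- character(0)
  for (i in 1:1500) {
    mv <- causalhh:::random_move(g, space)
    expect_false(is.null(mv))
    types <- c(types, mv$type)
    expect_true(is_acyclic(causalhh:::apply_move(g, mv)))
  }
  tab <- table(types)
  expect_gt(min(tab), 1500 / 3 - 4 * sqrt(1500 * 2 / 9))
  # cycle-creating proposals on a chain are rejected, not repaired
  ch <- chain_dag(4)
  for (i in 1:300) {
    mv <- causalhh:::random_move(ch, space)
    if (!is.null(mv)) expect_true(is_acyclic(causalhh:::apply_move(ch, mv)))
  }
  # a saturated complete DAG never receives additions
  full <- upper.tri(matrix(0, 4, 4))
  for (i in 1:200) {
    mv <- causalhh:::random_move(full, space)
    if (!is.null(mv)) expect_true(mv$type %in% c("delete", "reverse"))
  }
})

test_that("guide-adoption learning: no-ops and convergence to the guide", {
  fx <- llh_fixture()
  set.seed(3)
  sg <- random_subgroup(fx$sctx, fx$sppc$gss, size = 4)
  # equal to its personal best, or zero coefficient: unchanged
  fx$ctx$c <- 0
  out <- op_cognitive <- llh_registry()$cognitive_personal$fn(sg, fx$ctx)
  expect_identical(lapply(out, `[[`, "g"), lapply(sg, `[[`, "g"))
  fx$ctx$c <- 0.5
  same <- lapply(sg, function(ind) {
    ind$pbest_g <- ind$g
    ind
  })
  out2 <- llh_registry()$cognitive_personal$fn(same, fx$ctx)
  expect_identical(lapply(out2, `[[`, "g"), lapply(same, `[[`, "g"))
  # repeated application shrinks the expected Hamming distance to the guide
  guide <- sg[[1]]$pbest_g
  ind <- sg[[2]]
  ind$pbest_g <- guide
  d0 <- hamming_distance(ind$g, guide)
  dists <- replicate(30, {
    x <- ind
    for (r in 1:6) x <- causalhh:::adopt_from_guide(x, guide, 0.5, fx$ctx)
    hamming_distance(x$g, guide)
  })
  expect_lt(mean(dists), d0)
})

test_that("worker bees never worsen an individual; onlookers favour rank", {
  fx <- llh_fixture()
  set.seed(4)
  sg <- random_subgroup(fx$sctx, fx$sppc$gss, size = 6)
  before <- vapply(sg, `[[`, numeric(1), "fitness")
  out <- llh_registry()$worker_bees$fn(sg, fx$ctx)
  after <- vapply(out, `[[`, numeric(1), "fitness")
  expect_true(all(after >= before - 1e-12))
  # single-individual subgroup: onlooker reduces to a worker step
  one <- sg[1]
  out1 <- llh_registry()$onlooker_bees$fn(one, fx$ctx)
  expect_gte(out1[[1]]$fitness, one[[1]]$fitness - 1e-12)
  # rank-proportional sampling frequencies
  fits <- c(1, 2, 3)
  w <- rank(fits)
  draws <- sample.int(3, 6000, replace = TRUE, prob = w / sum(w))
  freq <- tabulate(draws, 3) / 6000
  expect_equal(freq, w / sum(w), tolerance = 0.05)
})

test_that("scout bees: trigger guard, parentless no-op, never worsens", {
  fx <- llh_fixture()
  set.seed(5)
  sg <- random_subgroup(fx$sctx, fx$sppc$gss, size = 4)
  sg <- lapply(sg, function(ind) {
    ind$stagnation <- 5L
    ind
  })
  out <- llh_registry()$scout_bees$fn(sg, fx$ctx)
  expect_identical(lapply(out, `[[`, "g"), lapply(sg, `[[`, "g")) # below lm
  armed <- lapply(sg, function(ind) {
    ind$stagnation <- 20L
    ind
  })
  out2 <- llh_registry()$scout_bees$fn(armed, fx$ctx)
  for (i in seq_along(out2)) {
    expect_gte(out2[[i]]$fitness, armed[[i]]$fitness - 1e-12)
    expect_identical(out2[[i]]$stagnation, 0L)
  }
})

test_that("elimination-dispersal fires with probability c3 and never drops
           below the stripped structure", {
  fx <- llh_fixture()
  set.seed(6)
  sg <- random_subgroup(fx$sctx, fx$sppc$gss, size = 4)
  fx$ctx$c3 <- 0
  out <- llh_registry()$elimination_dispersal$fn(sg, fx$ctx)
  expect_identical(lapply(out, `[[`, "g"), lapply(sg, `[[`, "g"))
  fx$ctx$c3 <- 1
  for (rep in 1:10) {
    b <- causalhh:::best_index(sg)
    out <- llh_registry()$elimination_dispersal$fn(sg, fx$ctx)
    expect_operator_contract(out, fx$sctx, fx$sppc$gss)
  }
})

test_that("expert knowledge forces every prior edge into the selected
           proportion", {
  fx <- llh_fixture(seed = 7)
  # ensure a nonempty prior: use the collider fixture if needed
  if (sum(fx$sppc$priors) == 0) {
    spec <- sem_spec(collider_dag(), 1, w = collider_dag() * 1)
    set.seed(8)
    dm <- simulate_sem(spec, 2000)
    sppc <- run_sppc(dm, 0.01)
    fx <- list(sctx = score_context(dm), sppc = sppc,
               ctx = op_context(score_context(dm), sppc))
  }
  set.seed(9)
  sg <- random_subgroup(fx$sctx, fx$sppc$gss, size = 10)
  out <- llh_registry()$expert_knowledge$fn(sg, fx$ctx)
  pe <- which(fx$sppc$priors)
  holds_all <- vapply(out, function(ind) all(ind$g[pe]), logical(1))
  expect_identical(sum(holds_all) >= ceiling(0.5 * 10), TRUE)
  changed <- mapply(function(a, b) !identical(a$g, b$g), sg, out)
  expect_lte(sum(changed), ceiling(0.5 * 10)) # only the selected half move
  expect_operator_contract(out, fx$sctx, fx$sppc$gss)
  # empty prior: no-op
  fx$ctx$priors <- causalhh:::empty_graph(ncol(fx$sppc$gss))
  out0 <- llh_registry()$expert_knowledge$fn(sg, fx$ctx)
  expect_identical(out0, sg)
})

test_that("pruning removes only weak edges, scanning once", {
  set.seed(10)
  x <- matrix(rnorm(1000 * 3), 1000, 3)
  x[, 2] <- x[, 1] + rnorm(1000) # strong edge 1 -> 2
  dm <- as_data_matrix(x)
  sppc <- run_sppc(dm, 0.01)
  sctx <- score_context(dm)
  ctx <- op_context(sctx, sppc)
  expect_equal(ctx$mu, log(1000))
  g <- causalhh:::empty_graph(3)
  g[1, 2] <- TRUE # strong: contribution ~ m/2 >> ln m
  g[1, 3] <- TRUE # spurious: contribution < ln m
  sg <- list(causalhh:::new_individual(g, graph_score(sctx, g)))
  out <- llh_registry()$pruning$fn(sg, ctx)
  expect_true(out[[1]]$g[1, 2])
  expect_false(out[[1]]$g[1, 3])
  empty <- list(causalhh:::new_individual(causalhh:::empty_graph(3),
                                          graph_score(sctx,
                                                      causalhh:::empty_graph(3))))
  expect_identical(llh_registry()$pruning$fn(empty, ctx), empty)
})

test_that("neighbourhood perturbation stays inside the LSS", {
  fx <- llh_fixture(seed = 11)
  set.seed(12)
  sg <- random_subgroup(fx$sctx, fx$sppc$lss, size = 5)
  out <- llh_registry()$neighborhood_perturbation$fn(sg, fx$ctx)
  expect_operator_contract(out, fx$sctx, fx$sppc$lss)
})

test_that("TLBO learns only from strictly better collaborators", {
  fx <- llh_fixture(seed = 13)
  set.seed(14)
  sg <- random_subgroup(fx$sctx, fx$sppc$gss, size = 5)
  # uniform fitness: nobody learns
  flat <- lapply(sg, function(ind) {
    ind$g <- sg[[1]]$g
    ind$fitness <- sg[[1]]$fitness
    ind
  })
  out <- llh_registry()$tlbo_learner$fn(flat, fx$ctx)
  expect_identical(lapply(out, `[[`, "g"), lapply(flat, `[[`, "g"))
})

test_that("moth-flame equals the cognitive rule when all pbests coincide", {
  fx <- llh_fixture(seed = 15)
  set.seed(16)
  sg <- random_subgroup(fx$sctx, fx$sppc$gss, size = 4)
  shared <- sg[[1]]$g
  sg <- lapply(sg, function(ind) {
    ind$pbest_g <- shared
    ind
  })
  set.seed(17)
  out_mf <- llh_registry()$moth_flame$fn(sg, fx$ctx)
  expect_operator_contract(out_mf, fx$sctx, fx$sppc$gss)
  # permutation uniformity of flame assignment
  perms <- replicate(2000, paste(sample.int(3), collapse = ""))
  expect_gt(min(table(perms)), 2000 / 6 - 4 * sqrt(2000 * 5 / 36))
})

test_that("search-space switching widens only the global operators", {
  fx <- llh_fixture(seed = 18)
  expect_identical(causalhh:::move_space(fx$ctx, global = TRUE),
                   fx$ctx$gss)
  fx$ctx$css_active <- TRUE
  css <- causalhh:::move_space(fx$ctx, global = TRUE)
  expect_true(all(css[row(css) != col(css)]))
  expect_identical(causalhh:::move_space(fx$ctx, global = FALSE),
                   fx$ctx$gss)
})
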