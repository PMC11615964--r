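committed_states <- function(graph, element = "R1", n_verbs = 2) {
  fr <- make_frame(n_verbs)
  n <- igraph::vcount(beliefgame:::as_igraph(graph))
  m <- matrix(0, n, fr$n_subsets)
  m[, subset_mask(fr, element)] <- 1
  structure(m, frame = fr, class = c("agent_states", "matrix"))
}

test_that("configuration rejects out-of-range parameters", {
  expect_error(sim_config(f = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(p_f = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(phi = 0), "phi")
  expect_error(sim_config(eta = 0), "positive")
})

test_that("config files round-trip with flattened reliability keys", {
  cfg <- sim_config(f = 0.2, p_s = 0.9, alpha = 0.05,
                    influence = influence_params(r_max = 0.9))
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$f, 0.2)
  expect_equal(back$alpha, 0.05)
  expect_equal(back$influence$r_max, 0.9)

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(f = 0.1, nope = 3), bad, auto_unbox = TRUE)
  expect_error(read_config(bad), "unknown config key")
})

test_that("no activation means no learning; only forgetting can still act", {
  g <- make_ws(30, 4, 0.1)
  cfg <- sim_config(f = 0, p_f = 0)
  set.seed(10)
  st <- init_states(g, cfg)
  out <- sim_step(g, st, cfg)
  expect_equal(unclass(out), unclass(st), tolerance = 1e-15)

  # with forgetting on, unengaged agents may still drift towards ignorance
  cfg2 <- sim_config(f = 0, p_f = 1, beta = 0.5)
  set.seed(10)
  st2 <- init_states(g, cfg2)
  out2 <- sim_step(g, st2, cfg2)
  fr <- attr(st2, "frame")
  expect_true(all(out2[, fr$n_subsets] >= st2[, fr$n_subsets]))
})

test_that("committed consensus is an absorbing fixed point", {
  g <- make_ws(20, 4, 0.1)
  cfg <- sim_config(f = 1)
  st <- committed_states(g, "R1")
  set.seed(11)
  out <- sim_step(g, st, cfg)
  expect_equal(unclass(out), unclass(st), tolerance = 1e-12)

  res <- sim_run(g, cfg, seed = 12)
  # from a random start the run ends; from consensus it ends immediately
  two <- igraph::make_graph(c(1, 2), directed = FALSE)
  st2 <- committed_states(two, "R1")
  r2 <- beliefgame:::run_core(two, st2, cfg, cfg$t_max, cfg$stall_window, FALSE)
  expect_equal(r2$t, 1)
  expect_equal(r2$termination, "all_stable")
})

test_that("trajectories are reproducible from (seed, config, graph)", {
  set.seed(20); g <- make_ws(40, 6, 0.1)
  cfg <- sim_config(t_max = 300L, stall_window = 100L)
  a <- suppressWarnings(sim_run(g, cfg, seed = 5))
  b <- suppressWarnings(sim_run(g, cfg, seed = 5))
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(unclass(a$states), unclass(b$states))
  c <- suppressWarnings(sim_run(g, cfg, seed = 6))
  expect_false(identical(unclass(a$states), unclass(c$states)))
})

test_that("one compiled round equals the R-level composition of operators", {
  set.seed(30)
  g <- make_er(12, 0.4)
  cfg <- sim_config(f = 0.8, p_s = 0.7, alpha = 0.05, p_f = 0.5, beta = 0.1)
  st <- init_states(g, cfg)
  for (trial in 1:5) {
    seed <- 1000 + trial
    set.seed(seed)
    fast <- sim_step(g, st, cfg)
    set.seed(seed)
    slow <- replay_round(g, st, cfg)
    expect_equal(unclass(fast), unclass(slow), tolerance = 1e-9)
    st <- fast
  }
})

test_that("snapshot semantics hold: folds read round-start beliefs only", {
  # two hearers on a path; whichever processing order, each fold must use the
  # round-start belief of its speaker, so results match the R composition in
  # which all folds read the same snapshot
  set.seed(31)
  g <- igraph::make_graph(~ a - b, b - c, c - d)
  cfg <- sim_config(f = 1, p_s = 1, p_f = 0)
  st <- init_states(g, cfg)
  set.seed(77)
  fast <- sim_step(g, st, cfg)
  set.seed(77)
  slow <- replay_round(g, st, cfg)
  expect_equal(unclass(fast), unclass(slow), tolerance = 1e-9)
})

test_that("stalled runs terminate and report their reason", {
  set.seed(40); g <- make_ws(30, 4, 0)
  cfg <- sim_config(t_max = 40L, stall_window = 10000L)
  expect_warning(res <- sim_run(g, cfg, seed = 3), "t_max")
  expect_equal(res$termination, "t_max")
  expect_equal(res$t, 40)
  expect_equal(nrow(res$trajectory), 40)
})

test_that("replication aggregates independent seeded runs", {
  set.seed(50); g <- make_ws(30, 4, 0.2)
  cfg <- sim_config(t_max = 2000L)
  agg1 <- sim_replicate(g, cfg, n_reps = 1, seed = 9)
  set.seed(9)
  s1 <- sample.int(.Machine$integer.max - 1L, 1)
  single <- suppressWarnings(sim_run(g, cfg, seed = s1, record = FALSE))
  expect_equal(unname(agg1$mean["L1"]), unname(single$summary["L1"]))
  expect_equal(unname(agg1$mean["R"]), unname(single$summary["R"]))

  agg <- sim_replicate(g, cfg, n_reps = 10, seed = 13)
  expect_equal(nrow(agg$reps), 10)
  # split-half consistency: disjoint seed batches agree within sampling error
  agg2 <- sim_replicate(g, cfg, n_reps = 10, seed = 14)
  pooled_se <- sqrt(agg$sd["R"]^2 / 10 + agg2$sd["R"]^2 / 10)
  expect_lt(abs(agg$mean["R"] - agg2$mean["R"]), 4 * pooled_se + 0.05)
})

test_that("round trajectories expose the event counts and observables", {
  set.seed(60); g <- make_ws(30, 6, 0.1)
  cfg <- sim_config(p_s = 0.8, alpha = 0.05, t_max = 50L,
                    stall_window = 10000L)
  res <- suppressWarnings(sim_run(g, cfg, seed = 2))
  tr <- res$trajectory
  expect_named(tr, c("t", "L1", "R", "rho_R", "r_local", "social_events",
                     "self_events", "forget_events"))
  expect_true(all(tr$L1 >= 0 & tr$L1 <= 1))
  expect_true(all(tr$R >= -1 & tr$R <= 1))
  expect_true(all(tr$rho_R >= 0 & tr$rho_R <= 1))
  expect_gt(sum(tr$self_events), 0)
})
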