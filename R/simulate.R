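#' Simulation configuration
#'
#' Bundles every model parameter with the study defaults: edge activation
#' probability `f = 0.1`; social learning always chosen over self-learning
#' (`p_s = 1`, `alpha = 0`); forgetting active (`p_f = 0.05`, `beta = 0.04`,
#' engagement threshold `eta = 2`); preference-free Dirichlet initialization
#' (`phi = 1`) on a two-verb frame; reliability mapping `r_max = 0.95`,
#' `r_eta = 0.2`, `r_fair = 0.5`. The horizon is `t_max` rounds with early
#' termination once every agent is stable or no agent's strongest proposition
#' has changed for `stall_window` consecutive rounds.
#'
#' @param f edge activation probability.
#' @param p_s probability an activated edge does social (vs self-) learning.
#' @param alpha self-learning rate.
#' @param p_f forgetting probability for eligible agents.
#' @param beta forgetting rate.
#' @param eta learning-event threshold below which an agent may forget.
#' @param phi Dirichlet concentration on irregular elements.
#' @param n_verbs number of verbs in the frame.
#' @param influence an [influence_params()].
#' @param t_max maximum number of rounds.
#' @param stall_window rounds of unchanged strongest propositions that count
#'   as stabilization.
#' @param n_reps default replicate count for [sim_replicate()].
#' @param seed default RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(f = 0.1, p_s = 1.0, alpha = 0, p_f = 0.05, beta = 0.04,
                       eta = 2L, phi = 1, n_verbs = 2L,
                       influence = influence_params(),
                       t_max = 5000L, stall_window = 200L,
                       n_reps = 200L, seed = 1L) {
  probs <- c(f = f, p_s = p_s, alpha = alpha, p_f = p_f, beta = beta)
  if (any(probs < 0 | probs > 1)) {
    stop("f, p_s, alpha, p_f, beta must all lie in [0, 1]")
  }
  if (phi <= 0) stop("`phi` must be > 0")
  if (t_max < 1 || n_reps < 1 || eta < 1) {
    stop("t_max, n_reps and eta must be positive")
  }
  stopifnot(inherits(influence, "influence_params"))
  structure(list(f = f, p_s = p_s, alpha = alpha, p_f = p_f, beta = beta,
                 eta = as.integer(eta), phi = phi,
                 n_verbs = as.integer(n_verbs), influence = influence,
                 t_max = as.integer(t_max),
                 stall_window = as.integer(stall_window),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Naming-game configuration:\n")
  cat(sprintf("  f=%.3g  p_s=%.3g  alpha=%.3g  p_f=%.3g  beta=%.3g  eta=%d\n",
              x$f, x$p_s, x$alpha, x$p_f, x$beta, x$eta))
  cat(sprintf("  phi=%.3g  n_verbs=%d  r_max=%.3g  r_eta=%.3g  r_fair=%.3g\n",
              x$phi, x$n_verbs, x$influence$r_max, x$influence$r_eta,
              x$influence$r_fair))
  cat(sprintf("  t_max=%d  stall_window=%d  n_reps=%d  seed=%d\n",
              x$t_max, x$stall_window, x$n_reps, x$seed))
  invisible(x)
}

#' Read/write a configuration as JSON or YAML
#'
#' Keys match the [sim_config()] fields (influence parameters flattened to
#' `r_max`, `r_eta`, `r_fair`); unknown keys are rejected.
#'
#' @param path file path (`.json`, `.yml`/`.yaml`).
#' @param config a `sim_config`.
#' @return `read_config()` a `sim_config`; `write_config()` `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("f", "p_s", "alpha", "p_f", "beta", "eta", "phi", "n_verbs",
             "r_max", "r_eta", "r_fair", "t_max", "stall_window", "n_reps",
             "seed")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  infl <- do.call(influence_params,
                  vals[intersect(names(vals), c("r_max", "r_eta", "r_fair"))])
  vals <- vals[setdiff(names(vals), c("r_max", "r_eta", "r_fair"))]
  do.call(sim_config, c(vals, list(influence = infl)))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  flat <- config[setdiff(names(config), "influence")]
  flat <- c(flat, config$influence)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Initial agent states
#'
#' Draws every agent's initial belief from the Dirichlet initialization (see
#' [init_belief_dirichlet()]) under the session RNG.
#'
#' @param graph a [labelled_graph()] or igraph graph.
#' @param config a [sim_config()].
#' @return An `agent_states` matrix (agents x subsets) with the frame
#'   attached.
#' @export
init_states <- function(graph, config) {
  fr <- make_frame(config$n_verbs)
  n <- igraph::vcount(as_igraph(graph))
  m <- init_mass_matrix(fr, n, config$phi)
  structure(m, frame = fr, class = c("agent_states", "matrix"))
}

#' Belief of one agent from a state matrix
#'
#' @param states an `agent_states` matrix.
#' @param i agent (row) index.
#' @return A `belief`.
#' @export
agent_belief <- function(states, i) {
  belief_function(attr(states, "frame"), states[i, ])
}

run_core <- function(graph, states, config, t_max, stall_window, record) {
  ig <- as_igraph(graph)
  comm <- graph_communities(graph)
  if (is.null(comm)) comm <- integer(0)
  el <- igraph::as_edgelist(ig, names = FALSE)
  storage.mode(el) <- "integer"
  cpp_run(el, as.integer(igraph::degree(ig)),
          unclass(states), config$n_verbs,
          config$f, config$p_s, config$alpha, config$p_f, config$beta,
          config$eta, config$influence$r_max, config$influence$r_eta,
          config$influence$r_fair, as.integer(t_max),
          as.integer(stall_window), record, as.integer(comm))
}

#' Advance the dynamics by one round
#'
#' Runs a single round of edge activation, social learning (ordered folds over
#' round-start beliefs), self-learning, and forgetting, under the session RNG.
#' Mainly useful for inspection and testing; [sim_run()] drives whole
#' trajectories.
#'
#' @param graph a [labelled_graph()] or igraph graph.
#' @param states an `agent_states` matrix.
#' @param config a [sim_config()].
#' @return The updated `agent_states` matrix.
#' @export
sim_step <- function(graph, states, config) {
  res <- run_core(graph, states, config, t_max = 1L,
                  stall_window = .Machine$integer.max, record = FALSE)
  structure(res$mass, frame = attr(states, "frame"),
            class = c("agent_states", "matrix"))
}

#' Run one replicate to stabilization
#'
#' Seeds the RNG, draws the initial beliefs, and iterates rounds until every
#' agent is stable (unit mass on one proposition), no agent's strongest
#' proposition has changed for `stall_window` consecutive rounds, or `t_max`
#' is reached (reported with a warning). Per-round observables are measured
#' against the round's own dominant singleton; the `(infinity)` values
#' reported in `$summary` come from the terminal states.
#'
#' @param graph a [labelled_graph()] or igraph graph.
#' @param config a [sim_config()].
#' @param seed RNG seed for this run (defaults to `config$seed`).
#' @param record keep the per-round time series.
#' @return An object of class `sim_result`: list with `states` (terminal
#'   `agent_states`), `trajectory` (data.frame `t, L1, R, rho_R, r_local,
#'   social_events, self_events, forget_events`), `t`, `termination`, and
#'   `summary` (named vector `L1, R, rho_R, r_local`).
#' @export
sim_run <- function(graph, config = sim_config(), seed = config$seed,
                    record = TRUE) {
  set.seed(seed)
  states <- init_states(graph, config)
  res <- run_core(graph, states, config, config$t_max, config$stall_window,
                  record)
  if (res$termination == "t_max") {
    warning("t_max = ", config$t_max, " reached before stabilization")
  }
  final <- structure(res$mass, frame = attr(states, "frame"),
                     class = c("agent_states", "matrix"))
  b1 <- dominant_element(final)
  comm <- graph_communities(graph)
  summ <- c(L1 = compute_L1(final, b1),
            R = compute_R(final, b1),
            rho_R = compute_rho_R(final),
            r_local = if (is.null(comm)) NA_real_ else
              compute_local_r(final, comm))
  traj <- NULL
  if (record) {
    traj <- as.data.frame(res$trajectory)
    names(traj) <- c("t", "L1", "R", "rho_R", "r_local",
                     "social_events", "self_events", "forget_events")
  }
  structure(list(states = final, trajectory = traj, t = res$t,
                 termination = res$termination, summary = summ,
                 seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Naming-game run:", x$t, "rounds, termination:", x$termination, "\n")
  cat(sprintf("  L1=%.4f  R=%.4f  rho_R=%.4f  r_local=%s\n",
              x$summary["L1"], x$summary["R"], x$summary["rho_R"],
              ifelse(is.na(x$summary["r_local"]), "NA",
                     sprintf("%.4f", x$summary["r_local"]))))
  invisible(x)
}

#' Replicate runs and aggregate the observables
#'
#' Runs `n_reps` independent replicates, each under its own seed derived from
#' the master seed, and aggregates the terminal observables by their plain
#' mean and standard deviation. If `graph` is a function it is called (with no
#' arguments) under each replicate's seed to draw a fresh network realization;
#' otherwise the same graph is reused.
#'
#' @param graph a [labelled_graph()], igraph graph, or generator function.
#' @param config a [sim_config()].
#' @param n_reps number of replicates (defaults to `config$n_reps`).
#' @param seed master seed (defaults to `config$seed`).
#' @return An object of class `sim_replicates`: list with `reps` (data.frame,
#'   one row per replicate), `mean` and `sd` (named vectors over `L1, R,
#'   rho_R, r_local`).
#' @export
sim_replicate <- function(graph, config = sim_config(),
                          n_reps = config$n_reps, seed = config$seed) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    g <- if (is.function(graph)) graph() else graph
    res <- suppressWarnings(
      sim_run(g, config, seed = rep_seeds[i], record = FALSE))
    rows[[i]] <- data.frame(rep = i, seed = rep_seeds[i], t = res$t,
                            termination = res$termination,
                            L1 = res$summary["L1"], R = res$summary["R"],
                            rho_R = res$summary["rho_R"],
                            r_local = res$summary["r_local"],
                            row.names = NULL)
  }
  reps <- do.call(rbind, rows)
  obs <- c("L1", "R", "rho_R", "r_local")
  structure(list(reps = reps,
                 mean = vapply(reps[obs], mean, numeric(1)),
                 sd = vapply(reps[obs], function(x) {
                   if (all(is.na(x))) NA_real_ else stats::sd(x)
                 }, numeric(1)),
                 n_reps = n_reps, seed = seed),
            class = "sim_replicates")
}

#' @export
print.sim_replicates <- function(x, ...) {
  cat("Aggregated naming-game replicates (n =", x$n_reps, "):\n")
  for (k in names(x$mean)) {
    cat(sprintf("  %-8s mean=%.4f  sd=%s\n", k, x$mean[k],
                ifelse(is.na(x$sd[k]), "NA", sprintf("%.4f", x$sd[k]))))
  }
  invisible(x)
}
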