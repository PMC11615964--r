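#' Sweep configuration parameters over a grid
#'
#' Runs [sim_replicate()] at every point of a parameter grid and returns the
#' per-replicate terminal observables in long (tidy) format: one row per
#' replicate per grid point, ready for statistical post-processing.
#'
#' @param graph a [labelled_graph()], igraph graph, or generator function
#'   (called afresh under each replicate's seed).
#' @param config base [sim_config()]; grid columns override its fields.
#' @param grid a data.frame whose columns name `sim_config` fields (e.g.
#'   `p_s`, `p_f`, `phi`, `alpha`) and whose rows are the sweep points, or a
#'   named list expanded via [expand.grid()].
#' @param n_reps replicates per grid point.
#' @param seed master seed; each grid point uses `seed + row - 1`.
#' @return A data.frame: grid columns, `rep`, `seed`, `t`, `termination`,
#'   `L1`, `R`, `rho_R`, `r_local`.
#' @export
sim_sweep <- function(graph, config = sim_config(), grid,
                      n_reps = 20L, seed = config$seed) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  bad <- setdiff(names(grid), names(config))
  if (length(bad)) stop("unknown config field(s) in grid: ",
                        paste(bad, collapse = ", "))
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    for (nm in names(grid)) cfg[[nm]] <- grid[g, nm]
    cfg <- do.call(sim_config, c(cfg[setdiff(names(cfg), "influence")],
                                 list(influence = cfg$influence)))
    agg <- sim_replicate(graph, cfg, n_reps = n_reps, seed = seed + g - 1L)
    out[[g]] <- cbind(grid[rep(g, n_reps), , drop = FALSE], agg$reps,
                      row.names = NULL)
  }
  do.call(rbind, out)
}
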