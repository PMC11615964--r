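# R-level replay of one simulation round, composed from the exported
# operations (degree_weight, recursive_reliability, map_reliability,
# social_learn, self_learn, forget) and mirroring the documented order of
# random draws. Used to check that the compiled driver and the R operation
# layer implement the same round.

replay_round <- function(graph, states, config) {
  ig <- beliefgame:::as_igraph(graph)
  fr <- attr(states, "frame")
  el <- igraph::as_edgelist(ig, names = FALSE)
  deg <- igraph::degree(ig)
  n <- igraph::vcount(ig)
  snapshot <- lapply(seq_len(n), function(i) belief_function(fr, states[i, ]))
  current <- snapshot
  learnset <- vector("list", n)
  self_nodes <- integer(0)

  for (m in seq_len(nrow(el))) {
    if (runif(1) >= config$f) next
    u <- el[m, 1]; v <- el[m, 2]
    if (runif(1) < config$p_s) {
      if (runif(1) < 0.5) { sp <- u; he <- v } else { sp <- v; he <- u }
      learnset[[he]] <- c(learnset[[he]], sp)
    } else {
      self_nodes <- c(self_nodes, u, v)
    }
  }

  learn_count <- integer(n)
  for (i in seq_len(n)) {
    src <- learnset[[i]]
    if (is.null(src)) next
    src <- src[order(-deg[src], src)]
    sources <- lapply(seq_along(src), function(k) {
      r_raw <- recursive_reliability(snapshot[[i]], snapshot[src[seq_len(k)]], k)
      list(belief = snapshot[[src[k]]],
           w = degree_weight(ig, i, src[k]),
           r = map_reliability(r_raw, config$influence))
    })
    current[[i]] <- social_learn(snapshot[[i]], sources)
    learn_count[i] <- learn_count[i] + 1L
  }

  for (i in self_nodes) {
    verb <- floor(runif(1) * fr$n_verbs) + 1
    before <- current[[i]]
    current[[i]] <- self_learn(before, verb, config$alpha)
    committed_irregular <-
      mass_of(before, fr$elements[fr$n_verbs + verb]) >= 1 - 1e-9
    if (!committed_irregular) learn_count[i] <- learn_count[i] + 1L
  }

  for (i in seq_len(n)) {
    if (learn_count[i] >= config$eta) next
    if (is_stable(current[[i]])) next
    if (runif(1) >= config$p_f) next
    current[[i]] <- forget(current[[i]], config$beta)
  }

  out <- do.call(rbind, lapply(current, unclass))
  structure(out, frame = fr, class = c("agent_states", "matrix"))
}
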