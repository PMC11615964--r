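#' Discount a belief by a combined coefficient
#'
#' Scales every subset mass of the communicated belief by `c` and parks the
#' remainder `1 - c` in a separate "unassigned" slot. The unassigned slot is
#' bookkeeping for the combination rule, distinct from ignorance mass on the
#' whole frame \eqn{\Theta}.
#'
#' @param m a `belief` (what the source communicates).
#' @param c combined discounting coefficient in `[0, 1]`.
#' @return An object of class `discounted_belief`: list with `mass` (numeric
#'   vector over non-empty subsets), `unassigned`, and `frame`.
#' @export
discount <- function(m, c) {
  check_belief(m)
  if (length(c) != 1L || is.na(c) || c < 0 || c > 1) {
    stop("`c` must be a scalar in [0, 1]")
  }
  structure(list(mass = c * unclass(m), unassigned = 1 - c,
                 frame = belief_frame(m)),
            class = "discounted_belief")
}

#' @export
print.discounted_belief <- function(x, digits = 4, ...) {
  cat("Discounted belief; unassigned =", round(x$unassigned, digits), "\n")
  focal <- which(x$mass > 0)
  if (length(focal)) {
    lab <- subset_label(x$frame, focal)
    for (i in seq_along(focal)) {
      cat(sprintf("  m(%s) = %.*f\n", lab[i], digits, x$mass[focal[i]]))
    }
  }
  invisible(x)
}

check_discounted <- function(x, name = "discounted belief") {
  if (!inherits(x, "discounted_belief")) {
    stop(name, " must be a `discounted_belief` (see discount())")
  }
  invisible(x)
}

#' One weighted-evidential-reasoning combination step
#'
#' Combines an accumulated discounted belief with the next source. For each
#' non-empty subset the unnormalized mass is the two cross-unassigned terms
#' plus the sum of all mass products whose subset intersection is exactly that
#' subset; the unassigned slots multiply. Everything is then renormalized so
#' masses plus unassigned total 1, which silently discards the conflicting
#' products whose intersection is empty.
#'
#' @param acc,next_src `discounted_belief` objects on one frame.
#' @return A `discounted_belief`.
#' @examples
#' fr <- make_frame(1)
#' ego <- discount(belief_function(fr, c(R1 = 1)), 1)
#' src <- discount(belief_function(fr, c(I1 = 1)), 1 / 3)
#' wer_combine_step(ego, src)  # ego unchanged; the conflict is discarded
#' @export
wer_combine_step <- function(acc, next_src) {
  check_discounted(acc, "acc"); check_discounted(next_src, "next_src")
  if (acc$frame$n_verbs != next_src$frame$n_verbs) {
    stop("discounted beliefs are on different frames")
  }
  res <- cpp_wer_step(acc$mass, acc$unassigned, next_src$mass,
                      next_src$unassigned)
  if (!res$ok) {
    stop("total conflict: the combined unnormalized mass is zero")
  }
  structure(list(mass = res$mass, unassigned = res$unassigned,
                 frame = acc$frame),
            class = "discounted_belief")
}

#' Social learning: ordered fold of discounted neighbour beliefs
#'
#' The ego's belief is combined with each source in learning-sequence order
#' (descending weight): the ego enters first, undiscounted (self-trust
#' `w = r = 1`), and every source enters discounted by its combined
#' coefficient `c = w / (1 + w - r)`. After the fold, the residual unassigned
#' mass is redistributed proportionally so the result is again a belief
#' function. With the coefficients held fixed the fold itself is a
#' commutative conjunctive rule; the learning sequence matters because the
#' recursive reliabilities (hence the coefficients) depend on each source's
#' position, which is why the sequence is fixed by weight.
#'
#' If every source is totally conflicting and undiscounted the fold has no
#' normalizer; the ego then keeps its prior belief with a warning (this cannot
#' happen for coefficients below 1).
#'
#' @param ego the ego's `belief`.
#' @param sources list of sources, each a list with elements `belief`, `w`
#'   (weight) and `r` (mapped reliability), ordered by descending `w`.
#' @return The updated `belief`.
#' @export
social_learn <- function(ego, sources) {
  check_belief(ego, "ego")
  if (length(sources) == 0L) return(ego)
  fr <- belief_frame(ego)
  ws <- vapply(sources, function(s) s$w, numeric(1))
  if (is.unsorted(rev(ws), strictly = FALSE)) {
    stop("`sources` must be ordered by descending weight")
  }
  cs <- numeric(length(sources))
  mat <- matrix(0, length(sources), fr$n_subsets)
  for (k in seq_along(sources)) {
    s <- sources[[k]]
    check_belief(s$belief); check_same_frame(ego, s$belief)
    cs[k] <- combined_coefficient(s$w, s$r)
    mat[k, ] <- unclass(s$belief)
  }
  res <- cpp_social_learn(unclass(ego), mat, cs)
  if (!res$ok) {
    warning("total conflict in social learning; ego keeps its prior belief")
    return(ego)
  }
  belief_function(fr, res$mass)
}

#' Self-learning with regular preference
#'
#' Reinforces the regular form of one verb: an `alpha`-fraction of the mass on
#' the chosen verb's irregular singleton moves to its regular singleton; all
#' other subsets are untouched. An agent already committed to that verb's
#' irregular form (`m(I) = 1`) no longer engages in self-learning and is
#' returned unchanged.
#'
#' @param m a `belief`.
#' @param verb verb index in `1..n_verbs` (drawn uniformly by the simulator).
#' @param alpha self-learning rate in `[0, 1]`.
#' @return The updated `belief`.
#' @export
self_learn <- function(m, verb, alpha) {
  check_belief(m)
  fr <- belief_frame(m)
  if (verb < 1 || verb > fr$n_verbs) stop("`verb` out of range")
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  mass <- unclass(m)
  Rbit <- bitwShiftL(1L, as.integer(verb) - 1L)
  Ibit <- bitwShiftL(1L, fr$n_verbs + as.integer(verb) - 1L)
  mI <- mass[Ibit]
  if (mI >= 1 - MASS_TOL) return(m)
  mass[Rbit] <- mass[Rbit] + alpha * mI
  mass[Ibit] <- (1 - alpha) * mI
  belief_function(fr, mass)
}

#' Forgetting under memory constraints
#'
#' Moves a `beta`-fraction of the agent's strongest non-\eqn{\Theta} focal
#' mass to total ignorance \eqn{\Theta} (ties broken towards the lowest
#' subset bitmask). If all mass already sits on \eqn{\Theta} there is nothing
#' to forget and the belief is returned unchanged. Eligibility (not stable,
#' under-engaged this round, Bernoulli(`pf`) success) is the simulator's
#' responsibility.
#'
#' @param m a `belief`.
#' @param beta forgetting rate in `[0, 1]`.
#' @return The updated `belief`.
#' @export
forget <- function(m, beta) {
  check_belief(m)
  if (beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]")
  fr <- belief_frame(m)
  mass <- unclass(m)
  full <- fr$n_subsets
  cand <- mass[-full]
  if (all(cand <= 0)) return(m)
  bf <- which.max(cand)  # which.max takes the first (lowest-bitmask) maximum
  moved <- beta * mass[bf]
  mass[full] <- mass[full] + moved
  mass[bf] <- mass[bf] - moved
  belief_function(fr, mass)
}
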