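states_matrix <- function(states) {
  if (inherits(states, "sim_result")) states <- states$states
  if (!inherits(states, "agent_states")) {
    stop("`states` must be an `agent_states` matrix or a `sim_result`")
  }
  states
}

#' Singleton each agent adheres to
#'
#' An agent "adheres to" the singleton verb-form proposition carrying its
#' largest singleton mass (ties to the lowest bitmask, i.e. the earliest
#' element in R1..Rn, I1..In order). Adherence is weaker than commitment:
#' it is defined even for agents whose mass is spread out.
#'
#' @param states an `agent_states` matrix or `sim_result`.
#' @return Integer vector of element indices (1..2n) into the frame's
#'   elements.
#' @export
adhered_elements <- function(states) {
  st <- states_matrix(states)
  fr <- attr(st, "frame")
  sing <- st[, singleton_masks(fr), drop = FALSE]
  apply(sing, 1, which.max)
}

#' Dominant singleton proposition
#'
#' The singleton adhered to by the largest number of agents (ties to the
#' lowest bitmask).
#'
#' @param states an `agent_states` matrix or `sim_result`.
#' @return The element index (1..2n) of the dominant singleton; its label is
#'   `attr(,"label")`.
#' @export
dominant_element <- function(states) {
  st <- states_matrix(states)
  fr <- attr(st, "frame")
  counts <- tabulate(adhered_elements(st), nbins = length(fr$elements))
  b1 <- which.max(counts)
  structure(b1, label = fr$elements[b1])
}

#' Convergence index L1
#'
#' Fraction of agents whose belief has unit mass exactly on the dominant
#' singleton `b1`. `L1 = 1` means full linguistic consensus: every agent is
#' committed to the same verb form.
#'
#' @param states an `agent_states` matrix or `sim_result`.
#' @param b1 element index of the dominant singleton (defaults to
#'   [dominant_element()]).
#' @return Numeric scalar in `[0, 1]`.
#' @export
compute_L1 <- function(states, b1 = dominant_element(states)) {
  st <- states_matrix(states)
  fr <- attr(st, "frame")
  mask <- singleton_masks(fr)[as.integer(b1)]
  mean(st[, mask] >= 1 - MASS_TOL)
}

#' Belief index R
#'
#' Mean over agents of the mass on the dominant singleton minus the summed
#' mass on every other singleton; composite subsets contribute to neither
#' term. `R = 1` is consensus; `R = 0` corresponds to half the population on
#' the same proposition; negative values indicate fragmentation.
#'
#' @inheritParams compute_L1
#' @return Numeric scalar in `[-1, 1]`.
#' @export
compute_R <- function(states, b1 = dominant_element(states)) {
  st <- states_matrix(states)
  fr <- attr(st, "frame")
  sing <- st[, singleton_masks(fr), drop = FALSE]
  b1 <- as.integer(b1)
  mean(sing[, b1] - (rowSums(sing) - sing[, b1]))
}

#' Local belief index r
#'
#' The belief index computed inside each community against that community's
#' own dominant singleton, then averaged over communities (each community
#' contributes its within-community mean with equal weight `1/|C|`). With a
#' single community this equals [compute_R()]. Values well above the global
#' `R` reveal within-community consensus coexisting with between-community
#' disagreement.
#'
#' @param states an `agent_states` matrix or `sim_result`.
#' @param communities integer community id per agent.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
compute_local_r <- function(states, communities) {
  st <- states_matrix(states)
  if (is.null(communities)) stop("`communities` is required")
  if (length(communities) != nrow(st)) {
    stop("`communities` must have one entry per agent")
  }
  fr <- attr(st, "frame")
  sing <- st[, singleton_masks(fr), drop = FALSE]
  adhere <- adhered_elements(st)
  comm_ids <- sort(unique(communities))
  vals <- vapply(comm_ids, function(k) {
    in_k <- communities == k
    counts <- tabulate(adhere[in_k], nbins = length(fr$elements))
    b1k <- which.max(counts)
    mean(sing[in_k, b1k] - (rowSums(sing[in_k, , drop = FALSE]) - sing[in_k, b1k]))
  }, numeric(1))
  mean(vals)
}

#' Regularization fraction rho_R
#'
#' For each verb, the fraction of agents whose adhered singleton is that
#' verb's regular form, summed over verbs. Equivalently: the fraction of
#' agents adhering to any regular form.
#'
#' @param states an `agent_states` matrix or `sim_result`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
compute_rho_R <- function(states) {
  st <- states_matrix(states)
  fr <- attr(st, "frame")
  mean(adhered_elements(st) <= fr$n_verbs)
}
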