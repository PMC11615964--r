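#' Reliability-mapping parameters
#'
#' Parameters of the mapping that turns a raw belief similarity into the
#' reliability an ego assigns to a source. Connected individuals share a
#' baseline of friendship, so a similarity at or above the threshold `r_eta`
#' is rescaled onto `[r_fair, r_max]`: it never falls below the fair
#' reliability `r_fair` (belief considered half right, half wrong) and never
#' reaches full trust (`r_max < 1`, nobody is omniscient). Below `r_eta` the
#' raw similarity is kept as-is.
#'
#' @param r_max upper reliability limit, in `(r_fair, 1]`; default 0.95.
#' @param r_eta similarity threshold for fair reliability, in `(0, 1)`;
#'   default 0.2.
#' @param r_fair fair reliability; default 0.5.
#' @return An object of class `influence_params`.
#' @export
influence_params <- function(r_max = 0.95, r_eta = 0.2, r_fair = 0.5) {
  if (!(r_eta > 0 && r_eta < 1)) stop("`r_eta` must lie in (0, 1)")
  if (!(r_fair <= r_max && r_max <= 1)) stop("need r_fair <= r_max <= 1")
  structure(list(r_max = r_max, r_eta = r_eta, r_fair = r_fair),
            class = "influence_params")
}

#' Degree-based weight of a neighbour
#'
#' The extrinsic influence attribute: the weight agent `i` assigns to its
#' neighbour `j` is `j`'s degree share within `i`'s neighbourhood,
#' \eqn{w_{ij} = d_j / \sum_{l \in \Gamma(i)} d_l}. Weights over a
#' neighbourhood sum to 1 and are generally asymmetric (`w_ij != w_ji`).
#'
#' @param graph an igraph graph or a [labelled_graph()].
#' @param i,j vertex ids (1-based); `j` must be a neighbour of `i`.
#' @return Numeric scalar in `(0, 1]`.
#' @export
degree_weight <- function(graph, i, j) {
  g <- as_igraph(graph)
  nb <- as.integer(igraph::neighbors(g, i))
  if (length(nb) == 0L) stop("vertex ", i, " is isolated")
  if (!(j %in% nb)) stop("vertex ", j, " is not a neighbour of ", i)
  deg <- igraph::degree(g)
  unname(deg[j] / sum(deg[nb]))
}

#' Map raw reliability onto the trust scale
#'
#' Applies the reliability mapping: the identity below `r_eta`, and the affine
#' rescale `r_fair + (r_max - r_fair) (r' - r_eta) / (1 - r_eta)` at and above
#' it. Non-decreasing on `[0, 1]` with a jump from `r_eta` up to `r_fair` at
#' the threshold.
#'
#' @param r_prime raw reliability (a belief similarity) in `[0, 1]`.
#' @param params an [influence_params()] object.
#' @return Mapped reliability in `[0, r_max]`.
#' @examples
#' map_reliability(0.2, influence_params())  # 0.5, the fair reliability
#' map_reliability(1, influence_params())    # 0.95, the upper limit
#' @export
map_reliability <- function(r_prime, params = influence_params()) {
  stopifnot(inherits(params, "influence_params"))
  if (any(r_prime < 0 | r_prime > 1)) stop("`r_prime` must lie in [0, 1]")
  vapply(r_prime, cpp_map_reliability, numeric(1),
         r_fair = params$r_fair, r_eta = params$r_eta, r_max = params$r_max)
}

#' In-group recursive raw reliability
#'
#' Raw reliability of the k-th source in an ego's ordered learning sequence.
#' For `k = 1` it is the plain ego-source similarity. For `k > 1` the ego
#' also weighs how much the sources agree among themselves: the value is half
#' the ego/k-th-source similarity plus the sum of all C(k,2) pairwise
#' source similarities divided by `k (k - 1)`. A source that conflicts with
#' the ego thus gains reliability once other sources back it up, which keeps
#' the ego from clinging to a belief the group rejects.
#'
#' @param m_i the ego's `belief`.
#' @param neighbours_so_far list of the first `k` sources' `belief`s, in
#'   learning-sequence order (the k-th entry is the source being assessed).
#' @param k positive integer; must equal `length(neighbours_so_far)`.
#' @return Raw reliability in `[0, 1]`.
#' @export
recursive_reliability <- function(m_i, neighbours_so_far,
                                  k = length(neighbours_so_far)) {
  check_belief(m_i, "m_i")
  if (k < 1 || length(neighbours_so_far) != k) {
    stop("`neighbours_so_far` must hold exactly k >= 1 beliefs")
  }
  for (b in neighbours_so_far) {
    check_belief(b); check_same_frame(m_i, b)
  }
  s_ego <- cosine_similarity(m_i, neighbours_so_far[[k]])
  if (k == 1L) return(s_ego)
  pair_sum <- 0
  for (a in seq_len(k - 1L)) {
    for (b in seq(a + 1L, k)) {
      pair_sum <- pair_sum +
        cosine_similarity(neighbours_so_far[[a]], neighbours_so_far[[b]])
    }
  }
  s_ego / 2 + pair_sum / (k * (k - 1))
}

#' Combined discounting coefficient
#'
#' Merges the extrinsic weight and intrinsic reliability into the single
#' coefficient `c = w / (1 + w - r)` that discounts a communicated belief.
#' Equals 1 for the ego's self-trust (`w = r = 1`) and 0 for a weightless
#' source; weakly increasing in both arguments on `[0, 1]^2`.
#'
#' @param w weight in `[0, 1]`.
#' @param r mapped reliability in `[0, 1]`.
#' @return Coefficient in `[0, 1]`.
#' @export
combined_coefficient <- function(w, r) {
  if (any(w < 0 | w > 1) || any(r < 0 | r > 1)) {
    stop("`w` and `r` must lie in [0, 1]")
  }
  mapply(cpp_combined_coefficient, w, r)
}

#' Dump the influence attributes of one ego's learning sequence
#'
#' Debug helper: for an ego and an ordered list of source vertices, tabulates
#' the weight, raw (recursive) reliability, mapped reliability, and combined
#' coefficient of each source, given the agents' current beliefs.
#'
#' @param graph an igraph graph or [labelled_graph()].
#' @param beliefs list of `belief` objects indexed by vertex id.
#' @param ego ego vertex id.
#' @param sources source vertex ids in learning-sequence order.
#' @param params an [influence_params()].
#' @return A data.frame with columns i, j, k, w, r_raw, r_mapped, c.
#' @export
influence_dump <- function(graph, beliefs, ego, sources,
                           params = influence_params()) {
  rows <- lapply(seq_along(sources), function(k) {
    j <- sources[k]
    w <- degree_weight(graph, ego, j)
    r_raw <- recursive_reliability(beliefs[[ego]], beliefs[sources[seq_len(k)]], k)
    r_m <- map_reliability(r_raw, params)
    data.frame(i = ego, j = j, k = k, w = w, r_raw = r_raw, r_mapped = r_m,
               c = combined_coefficient(w, r_m))
  })
  do.call(rbind, rows)
}
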