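# Brute-force oracle for the weighted-evidential-reasoning combination,
# written against a label-set representation (character vectors of element
# names) with no code shared with the package's bitmask implementation.
#
# An oracle belief is a list(mass = <named numeric, name = comma-joined
# sorted element labels>, unassigned = <numeric>).

oracle_all_subsets <- function(elements) {
  n <- length(elements)
  out <- list()
  for (code in 1:(2^n - 1)) {
    keep <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)))
    out[[length(out) + 1]] <- elements[keep]
  }
  out
}

oracle_key <- function(set) paste(sort(set), collapse = ",")

oracle_from_belief <- function(b, c_coef = 1) {
  fr <- attr(b, "frame")
  subsets <- oracle_all_subsets(fr$elements)
  mass <- c_coef * as.numeric(unclass(b))
  names(mass) <- vapply(seq_along(subsets), function(i) {
    # package order is bitmask order; re-derive the label set independently
    oracle_key(subsets[[i]])
  }, character(1))
  list(mass = mass[mass > 0], unassigned = 1 - c_coef,
       elements = fr$elements)
}

# One combination step per the unnormalized cross-product rule followed by
# renormalization over non-empty subsets plus the unassigned product.
oracle_wer_step <- function(acc, src) {
  un <- list()
  add <- function(key, v) {
    un[[key]] <<- (if (is.null(un[[key]])) 0 else un[[key]]) + v
  }
  for (ka in names(acc$mass)) {
    for (kb in names(src$mass)) {
      inter <- intersect(strsplit(ka, ",")[[1]], strsplit(kb, ",")[[1]])
      if (length(inter) == 0) next
      add(oracle_key(inter), acc$mass[[ka]] * src$mass[[kb]])
    }
  }
  for (ka in names(acc$mass)) add(ka, src$unassigned * acc$mass[[ka]])
  for (kb in names(src$mass)) add(kb, acc$unassigned * src$mass[[kb]])
  uP <- acc$unassigned * src$unassigned
  tot <- sum(unlist(un)) + uP
  if (tot <= 0) stop("oracle: total conflict")
  list(mass = vapply(un, function(v) v / tot, numeric(1)),
       unassigned = uP / tot, elements = acc$elements)
}

# Full social-learning fold: ego (undiscounted) then each (belief, c) source,
# with the final unassigned slot redistributed proportionally.
oracle_social_learn <- function(ego, sources_with_c) {
  acc <- oracle_from_belief(ego, 1)
  for (s in sources_with_c) {
    acc <- oracle_wer_step(acc, oracle_from_belief(s$belief, s$c))
  }
  if (acc$unassigned > 0 && acc$unassigned < 1) {
    acc$mass <- vapply(acc$mass, function(v) v / (1 - acc$unassigned),
                       numeric(1))
    acc$unassigned <- 0
  }
  acc
}

# Convert a package belief/discounted belief into the oracle's keyed form for
# comparison.
as_oracle_map <- function(mass_vec, frame) {
  subsets <- oracle_all_subsets(frame$elements)
  out <- numeric(0)
  for (i in seq_along(mass_vec)) {
    if (mass_vec[i] > 0) out[oracle_key(subsets[[i]])] <- mass_vec[i]
  }
  out
}

expect_oracle_equal <- function(mass_vec, frame, oracle_mass, tol = 1e-10) {
  got <- as_oracle_map(mass_vec, frame)
  keys <- union(names(got), names(oracle_mass))
  for (k in keys) {
    g <- if (k %in% names(got)) got[[k]] else 0
    o <- if (k %in% names(oracle_mass)) oracle_mass[[k]] else 0
    expect_equal(g, o, tolerance = tol,
                 label = paste0("mass(", k, ") = ", g),
                 expected.label = o)
  }
}

random_belief <- function(frame, n_focal = NULL) {
  S <- frame$n_subsets
  if (is.null(n_focal)) n_focal <- sample(1:min(4, S), 1)
  idx <- sample.int(S, n_focal)
  m <- numeric(S)
  m[idx] <- runif(n_focal)
  belief_function(frame, m / sum(m))
}
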