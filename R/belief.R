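MASS_TOL <- 1e-9

#' Belief function over a frame
#'
#' A belief function assigns non-negative mass to the non-empty subsets of the
#' frame; the empty set carries exactly zero and the total is 1 (within
#' `1e-9`). Internally a belief is the numeric vector of subset masses in
#' ascending bitmask order with the frame attached as an attribute; subsets
#' with positive mass are the focal elements.
#'
#' @param frame a [make_frame()] frame.
#' @param mass either a full numeric vector of length `frame$n_subsets`
#'   (ascending bitmask order) or a named vector whose names are subset labels
#'   such as `"R1"` or `"R1+I1"`; all unnamed subsets get zero mass.
#' @return An object of class `belief`.
#' @examples
#' fr <- make_frame(1)
#' belief_function(fr, c(R1 = 0.6, "R1+I1" = 0.4))
#' @export
belief_function <- function(frame, mass) {
  stopifnot(inherits(frame, "ds_frame"))
  S <- frame$n_subsets
  if (!is.null(names(mass))) {
    full <- numeric(S)
    full[subset_mask(frame, names(mass))] <- as.numeric(mass)
    mass <- full
  }
  if (length(mass) != S) {
    stop("mass vector must have length ", S, " (one entry per non-empty subset)")
  }
  mass <- as.numeric(mass)
  if (any(mass < -MASS_TOL)) stop("belief masses must be non-negative")
  mass[mass < 0] <- 0
  if (abs(sum(mass) - 1) > MASS_TOL) {
    stop("belief masses must sum to 1 (got ", format(sum(mass)), ")")
  }
  structure(mass, frame = frame, class = "belief")
}

#' @export
print.belief <- function(x, digits = 4, ...) {
  fr <- attr(x, "frame")
  focal <- which(unclass(x) > 0)
  cat("Belief function on", length(fr$elements), "verb forms;",
      length(focal), "focal element(s)\n")
  if (length(focal)) {
    lab <- subset_label(fr, focal)
    for (i in seq_along(focal)) {
      cat(sprintf("  m(%s) = %.*f\n", lab[i], digits, x[focal[i]]))
    }
  }
  invisible(x)
}

belief_frame <- function(m) attr(m, "frame")

check_belief <- function(m, name = "belief") {
  if (!inherits(m, "belief")) stop(name, " must be a `belief` object")
  invisible(m)
}

check_same_frame <- function(m1, m2) {
  f1 <- belief_frame(m1); f2 <- belief_frame(m2)
  if (f1$n_verbs != f2$n_verbs) stop("belief functions are on different frames")
  invisible(TRUE)
}

#' Mass assigned to a subset
#'
#' @param m a `belief`.
#' @param subset subset label (e.g. `"R1+I1"`) or integer bitmask.
#' @return The mass as a numeric scalar.
#' @export
mass_of <- function(m, subset) {
  check_belief(m)
  fr <- belief_frame(m)
  idx <- if (is.character(subset)) subset_mask(fr, subset) else as.integer(subset)
  unclass(m)[idx]
}

#' Cosine similarity of two belief functions
#'
#' The normalized dot product between the two subset-mass vectors. Because
#' masses are non-negative the value lies in `[0, 1]`; it equals 1 exactly
#' when the two mass vectors are proportional (hence equal, as both sum to 1)
#' and 0 when their focal elements are disjoint subsets of the frame.
#'
#' @param m1,m2 `belief` objects on the same frame.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' fr <- make_frame(1)
#' a <- belief_function(fr, c(R1 = 0.5, I1 = 0.5))
#' b <- belief_function(fr, c(R1 = 1))
#' cosine_similarity(a, b)  # 1/sqrt(2)
#' @export
cosine_similarity <- function(m1, m2) {
  check_belief(m1, "m1"); check_belief(m2, "m2")
  check_same_frame(m1, m2)
  cpp_cosine(unclass(m1), unclass(m2))
}

#' Dirichlet initial belief
#'
#' Draws the initial belief of one agent: the masses of all `2^(2n) - 1`
#' non-empty subsets come from a Dirichlet distribution whose concentration
#' for a subset is the mean of its element concentrations — 1 for every
#' regular form and `phi` for every irregular form. `phi = 1` is the
#' preference-free start (equal concentration on every proposition of the
#' power set); smaller `phi` shrinks the mass of every subset containing
#' irregular forms, so the population starts biased towards regular forms.
#'
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param frame a [make_frame()] frame.
#' @param phi positive real, concentration of each irregular element.
#' @return A `belief` supported on the full power set.
#' @export
init_belief_dirichlet <- function(frame, phi) {
  stopifnot(inherits(frame, "ds_frame"))
  if (length(phi) != 1L || is.na(phi) || phi <= 0) stop("`phi` must be > 0")
  belief_function(frame, dirichlet_draw(frame, phi))
}

#' Dirichlet concentration of every non-empty subset
#'
#' The concentration vector used by [init_belief_dirichlet()]: for each
#' subset, the mean of its element concentrations (1 per regular element,
#' `phi` per irregular one). Exposed so the initialization is inspectable.
#'
#' @inheritParams init_belief_dirichlet
#' @return Numeric vector of length `frame$n_subsets` in bitmask order.
#' @export
dirichlet_concentration <- function(frame, phi) {
  stopifnot(inherits(frame, "ds_frame"))
  n <- frame$n_verbs
  elem_conc <- c(rep(1, n), rep(phi, n))
  bits <- bitwShiftL(1L, seq_len(2L * n) - 1L)
  vapply(seq_len(frame$n_subsets), function(s) {
    keep <- bitwAnd(s, bits) != 0L
    mean(elem_conc[keep])
  }, numeric(1))
}

dirichlet_draw <- function(frame, phi, conc = dirichlet_concentration(frame, phi)) {
  g <- rgamma(frame$n_subsets, shape = conc, rate = 1)
  while (sum(g) == 0) g <- rgamma(frame$n_subsets, shape = conc, rate = 1)
  g / sum(g)
}

# Dirichlet draws for all agents at once (rows = agents), used by the
# simulator. Same per-agent draw order as init_belief_dirichlet.
init_mass_matrix <- function(frame, n_agents, phi) {
  conc <- dirichlet_concentration(frame, phi)
  out <- matrix(0, n_agents, frame$n_subsets)
  for (i in seq_len(n_agents)) {
    out[i, ] <- dirichlet_draw(frame, phi, conc)
  }
  out
}

#' Has a belief reached stability?
#'
#' An agent is stable when its maximum subset mass equals 1 (within `1e-9`),
#' i.e. all support is committed to a single proposition. Per the model's
#' forgetting rule this includes full commitment to the whole frame
#' \eqn{\Theta} (total ignorance), which in any case has no non-Theta focal
#' mass left to forget.
#'
#' @param m a `belief`.
#' @return Logical scalar.
#' @export
is_stable <- function(m) {
  check_belief(m)
  max(unclass(m)) >= 1 - MASS_TOL
}

#' Serialize belief functions to a label->mass list or JSON file
#'
#' Belief functions serialize as flat maps from subset label (sorted element
#' names joined by `"+"`) to mass, keeping only focal elements.
#' `write_beliefs()`/`read_beliefs()` store a list of such maps as JSON.
#'
#' @param m a `belief`.
#' @param beliefs a list of `belief` objects on one frame.
#' @param path file path for the JSON serialization.
#' @param frame the frame to attach on reading.
#' @return `belief_to_map()` a named numeric vector; `belief_from_map()` a
#'   `belief`; `read_beliefs()` a list of `belief` objects.
#' @export
belief_to_map <- function(m) {
  check_belief(m)
  fr <- belief_frame(m)
  focal <- which(unclass(m) > 0)
  stats::setNames(unclass(m)[focal], subset_label(fr, focal))
}

#' @rdname belief_to_map
#' @param map named numeric vector, subset label -> mass.
#' @export
belief_from_map <- function(frame, map) {
  belief_function(frame, map)
}

#' @rdname belief_to_map
#' @export
write_beliefs <- function(beliefs, path) {
  maps <- lapply(beliefs, function(b) as.list(belief_to_map(b)))
  jsonlite::write_json(maps, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname belief_to_map
#' @export
read_beliefs <- function(path, frame) {
  maps <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(maps, function(mp) belief_function(frame, unlist(mp)))
}
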