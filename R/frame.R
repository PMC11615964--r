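#' Frame of discernment for n verbs
#'
#' Builds the frame of discernment \eqn{\Theta = \{R_1..R_n, I_1..I_n\}}: the
#' mutually exclusive, collectively exhaustive set of verb-form elements, one
#' regular (R) and one irregular (I) form per verb. Non-empty subsets of the
#' frame are encoded as integer bitmasks over the fixed element order
#' R1..Rn, I1..In, so the power set has `2^(2n)` members (including the empty
#' set, bitmask 0, which can carry no mass) and valid subset codes run from 1
#' to `2^(2n) - 1`.
#'
#' @param n_verbs positive integer, number of verbs.
#' @return An object of class `ds_frame` with fields `n_verbs`, `elements`
#'   (the 2n element labels) and `n_subsets` (`2^(2n) - 1`).
#' @examples
#' fr <- make_frame(2)
#' fr$elements          # "R1" "R2" "I1" "I2"
#' subset_label(fr, 5L) # "R1+I1"
#' @export
make_frame <- function(n_verbs) {
  if (length(n_verbs) != 1L || is.na(n_verbs) || n_verbs < 1 ||
      n_verbs != as.integer(n_verbs)) {
    stop("`n_verbs` must be a positive integer")
  }
  n_verbs <- as.integer(n_verbs)
  if (n_verbs > 8L) {
    stop("frames with more than 8 verbs (65535+ subsets) are not supported")
  }
  elements <- c(paste0("R", seq_len(n_verbs)), paste0("I", seq_len(n_verbs)))
  structure(
    list(n_verbs = n_verbs,
         elements = elements,
         n_subsets = bitwShiftL(1L, 2L * n_verbs) - 1L),
    class = "ds_frame"
  )
}

#' @export
print.ds_frame <- function(x, ...) {
  cat("Frame of discernment:", length(x$elements), "verb forms (",
      x$n_verbs, "verbs ),", x$n_subsets + 1L, "propositions incl. the empty set\n")
  cat("  elements:", paste(x$elements, collapse = ", "), "\n")
  invisible(x)
}

#' Subset bitmask codec
#'
#' `subset_label()` turns a bitmask into the "+"-joined element labels (in the
#' fixed frame order); `subset_mask()` inverts it. The codec is total and
#' invertible on 1..`2^(2n)-1`.
#'
#' @param frame a `ds_frame`.
#' @param mask integer bitmask in 1..`frame$n_subsets`.
#' @param label character like `"R1"` or `"R1+I1"` (order of parts is free).
#' @return `subset_label()` a character scalar; `subset_mask()` an integer.
#' @examples
#' fr <- make_frame(2)
#' subset_mask(fr, subset_label(fr, 11L)) == 11L
#' @export
subset_label <- function(frame, mask) {
  stopifnot(inherits(frame, "ds_frame"))
  mask <- as.integer(mask)
  if (any(mask < 1L | mask > frame$n_subsets)) {
    stop("subset bitmask out of range 1..", frame$n_subsets)
  }
  n2 <- length(frame$elements)
  vapply(mask, function(m) {
    keep <- bitwAnd(m, bitwShiftL(1L, seq_len(n2) - 1L)) != 0L
    paste(frame$elements[keep], collapse = "+")
  }, character(1))
}

#' @rdname subset_label
#' @export
subset_mask <- function(frame, label) {
  stopifnot(inherits(frame, "ds_frame"))
  vapply(label, function(lb) {
    parts <- strsplit(lb, "+", fixed = TRUE)[[1]]
    idx <- match(parts, frame$elements)
    if (anyNA(idx) || length(idx) == 0L) {
      stop("unknown element in subset label: ", lb)
    }
    sum(bitwShiftL(1L, unique(idx) - 1L))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname subset_label
#' @param element single element label, e.g. `"I2"`.
#' @export
singleton_mask <- function(frame, element) {
  subset_mask(frame, element)
}

# bitmasks of all 2n singletons, in element order R1..Rn, I1..In
singleton_masks <- function(frame) {
  bitwShiftL(1L, seq_along(frame$elements) - 1L)
}
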