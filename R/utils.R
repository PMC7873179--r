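#' Clamp values to a range
#' @param x numeric vector
#' @param lo,hi range limits
#' @return `x` with values outside `[lo, hi]` replaced by the nearer limit
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half up to the nearest integer
#'
#' Unlike [base::round()] (round-half-even), ties are always rounded away
#' from zero towards the next integer, matching the convention used when
#' reporting integer percentages (e.g. 7/11 -> 64).
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @export
round_half_up <- function(x) floor(x + 0.5)

## stopifnot-style validation with a user-facing message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## First index (per row) where a logical matrix is TRUE, NA if none.
## Used to locate the first half-maximum crossing along an intensity
## profile, vectorised over all midline positions of one frame.
first_true_col <- function(m) {
  m[is.na(m)] <- FALSE
  any_true <- rowSums(m) > 0
  idx <- max.col(m, ties.method = "first")
  idx[!any_true] <- NA_integer_
  idx
}
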