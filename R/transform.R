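#' Baillie-Pilcher log-ratio normalization
#'
#' Converts raw ring widths into the dimensionless index series on which the
#' crossdating t-statistic is computed: each ring's width is divided by the
#' mean width of the centred 5-year window around it and the natural
#' logarithm is taken. The two boundary years at each end, where no full
#' 5-year window exists, are dropped rather than computed from a shrunken
#' window, so every index is a true 5-year ratio. The transform removes the
#' age trend and the absolute growth level: it is exactly invariant under
#' multiplicative rescaling of the widths.
#'
#' @param series a [ring_series] with at least 5 rings.
#' @return an object of class `bp_series`: a list with `values` (indices),
#'   `first_year` (year of the first index, i.e. the parent's first year
#'   + 2), `parent_id` and `parent_last_year`.
#' @examples
#' s <- ring_series(c(1, 1, 1, 2, 1, 1, 1), last_year = 1500)
#' bp_transform(s)$values  # log(5/6), log(10/6), log(5/6)
#' @export
bp_transform <- function(series) {
  stopifnot(inherits(series, "ring_series"))
  w <- series$widths
  n <- length(w)
  if (n < 5L)
    stop("the Baillie-Pilcher transform needs at least 5 rings",
         call. = FALSE)
  idx <- seq.int(3L, n - 2L)
  # direct 5-term window sum: exact zeros for a constant series
  m5 <- (w[idx - 2L] + w[idx - 1L] + w[idx] + w[idx + 1L] + w[idx + 2L]) / 5
  structure(
    list(values = log(w[idx] / m5),
         first_year = first_year(series) + 2L,
         parent_id = series$series_id,
         parent_last_year = series$last_year),
    class = "bp_series")
}

#' Sign series of year-to-year growth changes
#'
#' The ternary sign (+1 / 0 / -1) of each first difference of the ring
#' widths. This is the ingredient of the percentage of parallel variation
#' (Gleichlaeufigkeit): two series "agree" in an interval when both grew
#' wider or both grew narrower. Ties (equal consecutive widths) are encoded
#' 0 here; how a tie scores against the other series is decided by
#' [glk_statistic()].
#'
#' @param series a [ring_series] with at least 2 rings.
#' @return an object of class `sign_series`: `values` (one per interval),
#'   `first_interval_year` (calendar year of the earlier ring of the first
#'   interval), `parent_id`, `parent_last_year`.
#' @export
sign_series <- function(series) {
  stopifnot(inherits(series, "ring_series"))
  if (length(series$widths) < 2L)
    stop("a sign series needs at least 2 rings", call. = FALSE)
  structure(
    list(values = sign(diff(series$widths)),
         first_interval_year = first_year(series),
         parent_id = series$series_id,
         parent_last_year = series$last_year),
    class = "sign_series")
}

#' @export
print.bp_series <- function(x, ...) {
  cat(sprintf("Baillie-Pilcher index series of '%s': %d values, %d-%d CE\n",
              x$parent_id, length(x$values), x$first_year,
              x$first_year + length(x$values) - 1L))
  invisible(x)
}

#' @export
print.sign_series <- function(x, ...) {
  cat(sprintf("Sign series of '%s': %d intervals from %d CE\n",
              x$parent_id, length(x$values), x$first_interval_year))
  invisible(x)
}

# Shift the calendar anchoring of a transformed/sign series by d years
# (used when scanning a floating sample over a dated reference).
shift_years <- function(x, d) {
  d <- as.integer(d)
  if (inherits(x, "bp_series")) {
    x$first_year <- x$first_year + d
  } else if (inherits(x, "sign_series")) {
    x$first_interval_year <- x$first_interval_year + d
  } else stop("unsupported type")
  x$parent_last_year <- x$parent_last_year + d
  x
}

value_years <- function(x) {
  if (inherits(x, "bp_series"))
    seq.int(x$first_year, length.out = length(x$values))
  else seq.int(x$first_interval_year, length.out = length(x$values))
}
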