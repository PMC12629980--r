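#' Regional sapwood statistics
#'
#' The number of sapwood rings an oak carries at felling varies within a
#' region-specific range; when sapwood has been trimmed from a board, that
#' range bounds how many rings separate the last preserved ring from the
#' felling year. The shipped default is the classic statistic for oaks grown
#' in Poland: between 9 and 24 sapwood rings (median 15, i.e. 15 -6/+9)
#' within a 90% confidence interval. Other regions can be supplied via the
#' arguments; none are shipped.
#'
#' @param region label of the region the statistic describes.
#' @param sw_min,sw_median,sw_max sapwood ring counts,
#'   `sw_min <= sw_median <= sw_max`.
#' @param confidence probability attached to the `[sw_min, sw_max]` range.
#' @return an object of class `sapwood_stats`.
#' @export
sapwood_stats <- function(region = "Poland (Wazny)", sw_min = 9L,
                          sw_median = 15L, sw_max = 24L, confidence = 0.90) {
  sw_min <- as.integer(sw_min); sw_median <- as.integer(sw_median)
  sw_max <- as.integer(sw_max)
  if (sw_min < 0L || sw_min > sw_median || sw_median > sw_max)
    stop("need 0 <= sw_min <= sw_median <= sw_max", call. = FALSE)
  if (!(confidence > 0 && confidence < 1))
    stop("confidence must lie in (0, 1)", call. = FALSE)
  structure(list(region = as.character(region), sw_min = sw_min,
                 sw_median = sw_median, sw_max = sw_max,
                 confidence = confidence),
            class = "sapwood_stats")
}

#' @export
print.sapwood_stats <- function(x, ...) {
  cat(sprintf("Sapwood statistics, %s: %d-%d rings (median %d), %.0f%% CI\n",
              x$region, x$sw_min, x$sw_max, x$sw_median,
              100 * x$confidence))
  invisible(x)
}

#' Seasoning allowance between felling and use of a board
#'
#' Time for transport and drying of the wood, added to felling bounds to
#' estimate when a panel could have been painted. Two presets reflect the
#' literature: `"klein_1990s"` is the fixed 2-year allowance used in
#' 1990s-era reports, `"replication"` the modern 2-to-5-year allowance.
#'
#' @param s_min,s_max seasoning years, `0 <= s_min <= s_max`.
#' @param preset `NULL`, `"klein_1990s"` (2, 2) or `"replication"` (2, 5);
#'   when given it overrides `s_min`/`s_max`.
#' @return an object of class `seasoning_policy`.
#' @export
seasoning_policy <- function(s_min = 2L, s_max = 5L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("klein_1990s", "replication"))
    if (preset == "klein_1990s") { s_min <- 2L; s_max <- 2L }
    else { s_min <- 2L; s_max <- 5L }
  }
  s_min <- as.integer(s_min); s_max <- as.integer(s_max)
  if (s_min < 0L || s_max < s_min)
    stop("need 0 <= s_min <= s_max", call. = FALSE)
  structure(list(s_min = s_min, s_max = s_max), class = "seasoning_policy")
}

#' Calendar year of the heartwood/sapwood border
#'
#' The last heartwood ring of a series with `n_sapwood` sapwood rings at its
#' outer end dates to `last_ring_year - n_sapwood`.
#'
#' @param last_ring_year calendar year CE of the outermost ring.
#' @param n_sapwood number of sapwood rings (>= 0).
#' @return integer year CE of the last heartwood ring.
#' @examples
#' hw_sw_border_year(1614, 8) # 1606
#' @export
hw_sw_border_year <- function(last_ring_year, n_sapwood) {
  n_sapwood <- as.integer(n_sapwood)
  if (is.na(n_sapwood) || n_sapwood < 0L)
    stop("n_sapwood must be a non-negative integer", call. = FALSE)
  as.integer(last_ring_year) - n_sapwood
}

#' Estimate the felling date of a tree from its dated outermost ring
#'
#' Converts the calendar date of a board's outermost ring into a felling-date
#' estimate, depending on what that ring is:
#' \describe{
#'   \item{`hw_sw_border`}{the outermost ring is the last heartwood ring: the
#'     felling year lies in `[last + sw_min, last + sw_max]` with the
#'     statistic's confidence; the median estimate is `last + sw_median`.}
#'   \item{`heartwood_only`}{sapwood (and possibly heartwood) is missing: only
#'     a terminus post quem, `last + sw_min`, can be stated.}
#'   \item{`partial_sapwood`}{`k` sapwood rings are preserved: the border
#'     dates to `last - k`, giving `[last - k + sw_min, last - k + sw_max]`,
#'     with the lower bound clamped to `last + 1` (a tree cannot have been
#'     felled before its last existing ring grew).}
#'   \item{`bark_edge`}{the bark edge (waney edge) is present: the felling
#'     year equals the final ring's year exactly.}
#' }
#'
#' @param last_ring_year calendar year CE of the outermost measured ring.
#' @param context one of `"hw_sw_border"`, `"heartwood_only"`,
#'   `"partial_sapwood"`, `"bark_edge"`.
#' @param stats a [sapwood_stats()] object.
#' @param n_sapwood preserved sapwood ring count `k`; required (positive)
#'   for `context = "partial_sapwood"`.
#' @return an object of class `felling_estimate`: `kind` (`"interval"`,
#'   `"terminus_post_quem"` or `"exact"`), `lower`, `upper` (`NA` when the
#'   estimate is open above), `median_year` (`NA` unless applicable),
#'   `confidence`, `basis` (the statistics used).
#' @examples
#' estimate_felling(1606, "hw_sw_border", sapwood_stats())   # 1615-1630
#' estimate_felling(1602, "heartwood_only", sapwood_stats()) # after 1611
#' @export
estimate_felling <- function(last_ring_year,
                             context = c("hw_sw_border", "heartwood_only",
                                         "partial_sapwood", "bark_edge"),
                             stats = sapwood_stats(), n_sapwood = 0L) {
  context <- match.arg(context)
  stopifnot(inherits(stats, "sapwood_stats"))
  last <- as.integer(last_ring_year)
  k <- as.integer(n_sapwood)
  if (context == "partial_sapwood" && (is.na(k) || k <= 0L))
    stop("partial_sapwood requires a positive n_sapwood", call. = FALSE)
  if (!is.na(k) && k < 0L) stop("n_sapwood must be >= 0", call. = FALSE)
  est <- switch(context,
    hw_sw_border = list(kind = "interval",
                        lower = last + stats$sw_min,
                        upper = last + stats$sw_max,
                        median_year = last + stats$sw_median),
    heartwood_only = list(kind = "terminus_post_quem",
                          lower = last + stats$sw_min,
                          upper = NA_integer_,
                          median_year = NA_integer_),
    partial_sapwood = {
      border <- last - k
      lo <- max(last + 1L, border + stats$sw_min)
      list(kind = "interval", lower = lo,
           upper = border + stats$sw_max,
           median_year = max(lo, border + stats$sw_median))
    },
    bark_edge = list(kind = "exact", lower = last, upper = last,
                     median_year = last))
  structure(c(est, list(confidence = stats$confidence, basis = stats,
                        last_ring_year = last, context = context)),
            class = "felling_estimate")
}

#' @export
print.felling_estimate <- function(x, ...) {
  txt <- switch(x$kind,
    interval = sprintf("between %d and %d CE (median %d, %.0f%% CI)",
                       x$lower, x$upper, x$median_year,
                       100 * x$confidence),
    terminus_post_quem = sprintf("after %d CE (terminus post quem)",
                                 x$lower),
    exact = sprintf("in %d CE (bark edge present)", x$lower))
  cat("Estimated felling date:", txt, "\n")
  cat(sprintf("  basis: sapwood statistics %s, last ring %d (%s)\n",
              x$basis$region, x$last_ring_year, x$context))
  invisible(x)
}

#' Estimate the production window of an artwork from a felling estimate
#'
#' Adds the seasoning allowance to the felling bounds. For a felling interval
#' `[L, U]` the *earliest possible* production window is
#' `[L + s_min, L + s_max]` (the span the earliest-felled tree could have
#' reached the workshop in) and the *likely* production interval is
#' `[L + s_min, U + s_max]`. For a terminus post quem `F` the earliest
#' window is `[F + s_min, F + s_max]` and the likely estimate is open:
#' after `F + s_min`. Under the fixed 2-year 1990s-era preset the earliest
#' window degenerates to a single year.
#'
#' @param felling a [estimate_felling()] result.
#' @param seasoning a [seasoning_policy()].
#' @return an object of class `production_estimate`: `earliest_window`
#'   (`c(lower, upper)`), `likely_kind` (`"interval"` or
#'   `"terminus_post_quem"`), `likely_lower`, `likely_upper` (`NA` if open).
#' @examples
#' f <- estimate_felling(1606, "hw_sw_border", sapwood_stats())
#' estimate_production(f, seasoning_policy(preset = "replication"))
#' @export
estimate_production <- function(felling,
                                seasoning = seasoning_policy()) {
  stopifnot(inherits(felling, "felling_estimate"),
            inherits(seasoning, "seasoning_policy"))
  L <- felling$lower
  ew <- c(L + seasoning$s_min, L + seasoning$s_max)
  if (felling$kind == "terminus_post_quem") {
    lk <- "terminus_post_quem"; ll <- L + seasoning$s_min; lu <- NA_integer_
  } else {
    lk <- "interval"; ll <- L + seasoning$s_min
    lu <- felling$upper + seasoning$s_max
  }
  structure(list(earliest_window = as.integer(ew), likely_kind = lk,
                 likely_lower = as.integer(ll), likely_upper = as.integer(lu),
                 felling = felling, seasoning = seasoning),
            class = "production_estimate")
}

#' @export
print.production_estimate <- function(x, ...) {
  if (x$earliest_window[1L] == x$earliest_window[2L])
    cat(sprintf("Earliest possible production date: %d CE\n",
                x$earliest_window[1L]))
  else
    cat(sprintf("Earliest possible production date: between %d and %d CE\n",
                x$earliest_window[1L], x$earliest_window[2L]))
  if (x$likely_kind == "interval")
    cat(sprintf("Likely production date: between %d and %d CE\n",
                x$likely_lower, x$likely_upper))
  else
    cat(sprintf("Likely production date: after %d CE\n", x$likely_lower))
  cat(sprintf("  seasoning allowance: %d-%d years\n",
              x$seasoning$s_min, x$seasoning$s_max))
  invisible(x)
}
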