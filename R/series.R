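#' Construct a dated ring-width series
#'
#' A `ring_series` holds the annual ring widths of one measured radius (a
#' board, core or panel), in millimetres, anchored to the calendar by the year
#' of its outermost (last) ring. Sapwood, if preserved, sits at the outer end
#' of the sequence.
#'
#' @param widths numeric vector of ring widths in mm, oldest ring first.
#'   All widths must be strictly positive: absent (unmeasurable) rings are not
#'   represented by zeros in this package.
#' @param last_year calendar year CE of the final (outermost) ring.
#' @param series_id short identifier (at most 8 characters survive a Tucson
#'   round trip).
#' @param n_sapwood number of sapwood rings at the outer end; 0 if sapwood is
#'   absent.
#' @param pith_present logical; is the pith (tree centre) present?
#' @param hw_sw_border_is_last_ring logical; the outermost ring is the last
#'   heartwood ring (the heartwood/sapwood border). Incompatible with
#'   `n_sapwood > 0`.
#' @param units_raw storage unit of the source file, `"0.01 mm"` or
#'   `"0.001 mm"`. Widths are always held in mm; this only records the
#'   precision at which the series was (or will be) stored.
#'
#' @return an object of class `ring_series`.
#' @examples
#' s <- ring_series(c(1.2, 0.9, 1.4, 1.1), last_year = 1606, series_id = "EX")
#' first_year(s)
#' @export
ring_series <- function(widths, last_year, series_id = "SERIES",
                        n_sapwood = 0L, pith_present = FALSE,
                        hw_sw_border_is_last_ring = FALSE,
                        units_raw = c("0.01 mm", "0.001 mm")) {
  widths <- as.numeric(widths)
  units_raw <- match.arg(units_raw)
  if (length(widths) < 1L)
    stop("a ring series needs at least one ring", call. = FALSE)
  if (anyNA(widths) || any(!is.finite(widths)))
    stop("ring widths must be finite and non-missing", call. = FALSE)
  if (any(widths <= 0))
    stop("all ring widths must be strictly positive (series '", series_id,
         "'); width 0 marks an unmeasured ring, which this analysis rejects",
         call. = FALSE)
  last_year <- as.integer(last_year)
  if (is.na(last_year))
    stop("last_year must be an integer calendar year", call. = FALSE)
  n_sapwood <- as.integer(n_sapwood)
  if (is.na(n_sapwood) || n_sapwood < 0L || n_sapwood > length(widths))
    stop("n_sapwood must lie in 0..length(widths)", call. = FALSE)
  if (isTRUE(hw_sw_border_is_last_ring) && n_sapwood != 0L)
    stop("a series whose last ring is the heartwood/sapwood border has ",
         "n_sapwood = 0 by definition", call. = FALSE)
  structure(
    list(series_id = as.character(series_id),
         widths = widths,
         last_year = last_year,
         n_sapwood = n_sapwood,
         pith_present = isTRUE(pith_present),
         hw_sw_border_is_last_ring = isTRUE(hw_sw_border_is_last_ring),
         units_raw = units_raw),
    class = "ring_series")
}

#' Construct a reference chronology
#'
#' A chronology is a dated mean ring-width series for a region, consumed as a
#' crossdating reference. Shape-wise it is a `ring_series` with an optional
#' per-year replication depth (number of contributing trees) and a region
#' label.
#'
#' @inheritParams ring_series
#' @param region free-text region label (e.g. `"southern Baltic"`).
#' @param replication_depth optional integer vector, one entry per ring,
#'   giving the number of trees contributing to each year.
#' @return an object of class `c("chronology", "ring_series")`.
#' @export
chronology <- function(widths, last_year, series_id = "CHRON",
                       region = NA_character_, replication_depth = NULL,
                       units_raw = c("0.01 mm", "0.001 mm")) {
  x <- ring_series(widths, last_year, series_id = series_id,
                   units_raw = match.arg(units_raw))
  if (!is.null(replication_depth)) {
    replication_depth <- as.integer(replication_depth)
    if (length(replication_depth) != length(x$widths))
      stop("replication_depth needs one entry per ring", call. = FALSE)
  }
  x$region <- as.character(region)
  x$replication_depth <- replication_depth
  class(x) <- c("chronology", "ring_series")
  x
}

#' Number of rings spanned by an inclusive calendar interval
#'
#' @param first_year,last_year calendar years CE, `last_year >= first_year`.
#' @return integer ring count, `last_year - first_year + 1`.
#' @examples
#' year_span(1397, 1606) # 210
#' @export
year_span <- function(first_year, last_year) {
  first_year <- as.integer(first_year)
  last_year <- as.integer(last_year)
  if (anyNA(first_year) || anyNA(last_year))
    stop("years must be integers", call. = FALSE)
  if (any(last_year < first_year))
    stop("last_year must not precede first_year", call. = FALSE)
  last_year - first_year + 1L
}

#' Number of rings in a series
#' @param x a `ring_series`.
#' @return integer ring count.
#' @export
n_rings <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  length(x$widths)
}

#' Calendar year of the first (innermost) ring
#' @param x a `ring_series`.
#' @return integer year CE.
#' @export
first_year <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  x$last_year - length(x$widths) + 1L
}

#' Calendar years of all rings, oldest first
#' @param x a `ring_series`.
#' @return integer vector of years CE, one per ring.
#' @export
ring_years <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  seq.int(first_year(x), x$last_year)
}

#' @export
as.data.frame.ring_series <- function(x, ...) {
  data.frame(year = ring_years(x), width_mm = x$widths)
}

#' @export
print.ring_series <- function(x, ...) {
  kind <- if (inherits(x, "chronology")) "Chronology" else "Ring series"
  cat(sprintf("%s '%s': %d rings, %d-%d CE\n", kind, x$series_id,
              n_rings(x), first_year(x), x$last_year))
  if (x$n_sapwood > 0L)
    cat(sprintf("  sapwood rings: %d (outermost)\n", x$n_sapwood))
  if (x$hw_sw_border_is_last_ring)
    cat("  last ring is the heartwood/sapwood border\n")
  if (x$pith_present) cat("  pith present\n")
  if (inherits(x, "chronology") && !is.na(x$region))
    cat(sprintf("  region: %s\n", x$region))
  cat(sprintf("  width range %.2f-%.2f mm (stored at %s)\n",
              min(x$widths), max(x$widths), x$units_raw))
  invisible(x)
}

#' @export
plot.ring_series <- function(x, ..., log = "") {
  plot(ring_years(x), x$widths, type = "l", xlab = "year CE",
       ylab = "ring width (mm)", main = x$series_id, log = log, ...)
  if (x$n_sapwood > 0L)
    abline(v = x$last_year - x$n_sapwood + 0.5, lty = 2, col = "tan3")
  invisible(x)
}
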