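#' Match-classification policy for crossdating
#'
#' Thresholds used to classify candidate alignments. The defaults encode the
#' field's working rules: a Baillie-Pilcher t (TBP) above 3.5 over an overlap
#' of at least 100 rings marks a *potential* match; modern practice expects
#' TBP above 5 together with a percentage of parallel variation (%PV) above
#' 63 that is significant at p < 0.05 before a match is *accepted*. The
#' same-tree t threshold is a configuration default of this package, not a
#' published criterion: an exceptionally strong match (here TBP >= 10 with
#' %PV significant at p < 0.001) flags two boards as candidates for having
#' been sawn from one trunk.
#'
#' @param t_potential TBP threshold for a potential match (default 3.5).
#' @param min_overlap_potential minimum ring overlap for the potential class
#'   (default 100).
#' @param t_accepted TBP threshold for an accepted match (default 5.0).
#' @param glk_min minimum %PV for an accepted match (default 63).
#' @param glk_p_max maximum %PV significance probability for an accepted
#'   match (default 0.05).
#' @param t_same_tree TBP threshold for the same-tree verdict (default 10).
#' @param min_overlap_scan minimum ring overlap for an offset to be scanned
#'   at all (default 50).
#' @return an object of class `match_policy`.
#' @export
match_policy <- function(t_potential = 3.5, min_overlap_potential = 100L,
                         t_accepted = 5.0, glk_min = 63, glk_p_max = 0.05,
                         t_same_tree = 10.0, min_overlap_scan = 50L) {
  if (t_accepted < t_potential)
    stop("t_accepted must be >= t_potential", call. = FALSE)
  if (t_potential <= 0 || t_accepted <= 0 || t_same_tree <= 0)
    stop("t thresholds must be positive", call. = FALSE)
  if (min_overlap_scan < 6L)
    stop("min_overlap_scan below 6 rings leaves no transformed overlap",
         call. = FALSE)
  structure(list(t_potential = t_potential,
                 min_overlap_potential = as.integer(min_overlap_potential),
                 t_accepted = t_accepted, glk_min = glk_min,
                 glk_p_max = glk_p_max, t_same_tree = t_same_tree,
                 min_overlap_scan = as.integer(min_overlap_scan)),
            class = "match_policy")
}

# When r is numerically 1 (self-match, duplicate detection) the t formula
# overflows; report a fixed cap instead so that rankings stay total.
TBP_CAP <- 9999

as_bp <- function(x) if (inherits(x, "bp_series")) x else bp_transform(x)
as_sgn <- function(x) if (inherits(x, "sign_series")) x else sign_series(x)

# Pearson r and Student's t on two year-indexed value vectors, optionally
# excluding a span of calendar years from the statistics.
tbp_core <- function(a, b, exclude = NULL) {
  ya <- value_years(a); yb <- value_years(b)
  common <- intersect(ya, yb)
  if (!is.null(exclude))
    common <- common[common < exclude[1L] | common > exclude[2L]]
  n <- length(common)
  if (n < 3L)
    stop("overlap of transformed values below 3; cannot compute TBP",
         call. = FALSE)
  va <- a$values[match(common, ya)]
  vb <- b$values[match(common, yb)]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in an overlap segment; TBP undefined", call. = FALSE)
  r <- stats::cor(va, vb)
  t <- if (r >= 1 - 1e-12) TBP_CAP
       else if (r <= -1 + 1e-12) -TBP_CAP
       else max(-TBP_CAP, min(TBP_CAP, r * sqrt(n - 2) / sqrt(1 - r^2)))
  list(r = r, t = t, overlap = n)
}

#' Baillie-Pilcher t-statistic of two series at a given alignment
#'
#' Computes the Pearson correlation of the overlapping Baillie-Pilcher
#' indices of two series and the derived Student's t,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, where `n` is the number of
#' overlapping transformed values. The statistic is symmetric in its
#' arguments. When `r` is numerically 1 (a series against itself) `t` is
#' reported as the fixed cap 9999; `|t|` never exceeds that cap, so rankings
#' involving self-matches and duplicates stay total and bounded.
#'
#' @param a,b [ring_series] or [bp_transform()] outputs. `a` is the sample:
#'   if `end_year` is given, `a` is re-anchored so that its final ring falls
#'   in that calendar year before the overlap is formed.
#' @param end_year proposed calendar year of `a`'s final ring, or `NULL` to
#'   use the years as stated.
#' @return a list with elements `r`, `t` and `overlap` (the transformed-value
#'   overlap; 4 less than the raw ring overlap when one series is nested in
#'   the other).
#' @export
tbp_statistic <- function(a, b, end_year = NULL) {
  a <- as_bp(a); b <- as_bp(b)
  if (!is.null(end_year)) a <- shift_years(a, end_year - a$parent_last_year)
  tbp_core(a, b)
}

glk_core <- function(a, b, exclude = NULL) {
  ya <- value_years(a); yb <- value_years(b)
  common <- intersect(ya, yb)
  if (!is.null(exclude))
    common <- common[common < exclude[1L] | common > exclude[2L]]
  n <- length(common)
  if (n < 2L)
    stop("fewer than 2 overlapping intervals; %PV undefined", call. = FALSE)
  sa <- a$values[match(common, ya)]
  sb <- b$values[match(common, yb)]
  score <- abs(sa + sb) / 2     # 1 same nonzero sign, 1/2 one tie, 0 else
  glk <- 100 * mean(score)
  z <- (mean(score) - 0.5) / (0.5 / sqrt(n))
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(glk = glk, p = p, n = n, significance_class = glk_class(p))
}

glk_class <- function(p) {
  if (p < 0.001) "p001" else if (p < 0.01) "p01"
  else if (p < 0.05) "p05" else "none"
}

glk_marks <- c(none = "", p05 = "#", p01 = "##", p001 = "###")

#' Percentage of parallel variation (Gleichlaeufigkeit) and its significance
#'
#' Over the overlapping year-to-year intervals of two series, each interval
#' scores 1 when both series change width in the same (nonzero) direction,
#' 1/2 when exactly one of the two shows no change, and 0 otherwise; %PV is
#' 100 times the mean score. Under the null hypothesis of independent series
#' the mean score is 1/2 with standard deviation `1/(2*sqrt(n))` over `n`
#' intervals; the one-sided normal tail of the observed mean gives the
#' significance probability. Ties contribute 1/2 to the score but `n` is not
#' reduced, following the classic treatment.
#'
#' @param a,b [ring_series] or [sign_series()] outputs; `a` is re-anchored to
#'   `end_year` if given.
#' @param end_year proposed calendar year of `a`'s final ring, or `NULL`.
#' @return a list with `glk` (in \[0, 100\]), `p`, `n` (interval overlap) and
#'   `significance_class` (`"none"`, `"p05"`, `"p01"`, `"p001"`).
#' @export
glk_statistic <- function(a, b, end_year = NULL) {
  a <- as_sgn(a); b <- as_sgn(b)
  if (!is.null(end_year)) a <- shift_years(a, end_year - a$parent_last_year)
  glk_core(a, b)
}

classify_match <- function(t, ol, glk, p, policy) {
  if (t >= policy$t_accepted && glk >= policy$glk_min && p <= policy$glk_p_max)
    "accepted"
  else if (t >= policy$t_potential && ol >= policy$min_overlap_potential)
    "potential"
  else "no_match"
}

#' Scan all admissible end-dates of a sample against a reference
#'
#' Slides the (possibly undated) sample along the dated reference: every
#' calendar end-year giving a raw ring overlap of at least
#' `policy$min_overlap_scan` is evaluated, computing the Pearson r and TBP t
#' on the Baillie-Pilcher indices and the %PV with its significance on the
#' sign series. Results are ranked by t (descending), ties broken by %PV,
#' then overlap, then the earlier end-year, and classified against the
#' policy. Offsets whose overlap segment has zero variance are skipped.
#'
#' @param sample a [ring_series]; its own `last_year` is irrelevant to the
#'   scan (every admissible end-year is proposed).
#' @param reference a dated [ring_series] or [chronology].
#' @param policy a [match_policy()].
#' @return a `data.frame` with one row per scanned end-year: `sample_id`,
#'   `reference_id`, `end_year`, `overlap` (raw ring overlap Ol),
#'   `overlap_t` (transformed-value overlap entering the t formula), `r`,
#'   `t_bp`, `glk`, `glk_p`, `significance_class`, `match_class`. Empty (zero
#'   rows) when no offset is admissible.
#' @seealso [crossdate()] for the object-returning interface.
#' @export
scan_offsets <- function(sample, reference, policy = match_policy()) {
  stopifnot(inherits(sample, "ring_series"),
            inherits(reference, "ring_series"),
            inherits(policy, "match_policy"))
  if (n_rings(reference) < policy$min_overlap_scan)
    return(empty_scan_df())
  sv <- bp_transform(sample)$values
  rv <- bp_transform(reference)$values
  sg <- sign_series(sample)$values
  rg <- sign_series(reference)$values
  ns <- n_rings(sample)
  rf <- first_year(reference); rl <- reference$last_year
  m <- policy$min_overlap_scan
  ends <- seq.int(rf + m - 1L, rl + ns - m)
  ends <- ends[pmin(ends, rl) - pmax(ends - ns + 1L, rf) + 1L >= m]
  ne <- length(ends)
  if (ne == 0L) return(empty_scan_df())
  ol <- ot <- integer(ne)
  rr <- tt <- gl <- gp <- rep(NA_real_, ne)
  for (k in seq_len(ne)) {
    e <- ends[k]
    ol[k] <- min(e, rl) - max(e - ns + 1L, rf) + 1L
    # transformed values: sample spans years (e-ns+3)..(e-2), ref (rf+2)..(rl-2)
    lo <- max(e - ns + 3L, rf + 2L); hi <- min(e - 2L, rl - 2L)
    nt <- hi - lo + 1L
    ot[k] <- max(nt, 0L)
    if (nt >= 3L) {
      a <- sv[seq.int(lo - (e - ns + 3L) + 1L, length.out = nt)]
      b <- rv[seq.int(lo - (rf + 2L) + 1L, length.out = nt)]
      r <- suppressWarnings(stats::cor(a, b))
      if (!is.na(r)) {
        rr[k] <- r
        tt[k] <- if (r >= 1 - 1e-12) TBP_CAP
                 else if (r <= -1 + 1e-12) -TBP_CAP
                 else max(-TBP_CAP,
                          min(TBP_CAP, r * sqrt(nt - 2) / sqrt(1 - r^2)))
      }
    }
    # sign intervals: sample spans years (e-ns+1)..(e-1), ref rf..(rl-1)
    ilo <- max(e - ns + 1L, rf); ihi <- min(e - 1L, rl - 1L)
    ni <- ihi - ilo + 1L
    if (ni >= 2L) {
      sa <- sg[seq.int(ilo - (e - ns + 1L) + 1L, length.out = ni)]
      sb <- rg[seq.int(ilo - rf + 1L, length.out = ni)]
      sc <- mean(abs(sa + sb) / 2)
      gl[k] <- 100 * sc
      gp[k] <- stats::pnorm((sc - 0.5) / (0.5 / sqrt(ni)),
                            lower.tail = FALSE)
    }
  }
  keep <- !is.na(rr) & !is.na(gl)
  if (!any(keep)) return(empty_scan_df())
  df <- data.frame(
    sample_id = sample$series_id, reference_id = reference$series_id,
    end_year = ends[keep], overlap = ol[keep], overlap_t = ot[keep],
    r = rr[keep], t_bp = tt[keep], glk = gl[keep], glk_p = gp[keep],
    stringsAsFactors = FALSE)
  df$significance_class <- vapply(df$glk_p, glk_class, character(1))
  df$match_class <- mapply(classify_match, df$t_bp, df$overlap, df$glk,
                           df$glk_p, MoreArgs = list(policy = policy))
  df <- df[order(-df$t_bp, -df$glk, -df$overlap, df$end_year), ]
  rownames(df) <- NULL
  df
}

empty_scan_df <- function() {
  data.frame(sample_id = character(0), reference_id = character(0),
             end_year = integer(0), overlap = integer(0),
             overlap_t = integer(0), r = numeric(0), t_bp = numeric(0),
             glk = numeric(0), glk_p = numeric(0),
             significance_class = character(0), match_class = character(0),
             stringsAsFactors = FALSE)
}

#' Crossdate a sample series against a dated reference
#'
#' The main fitting interface: runs [scan_offsets()] and wraps the ranked
#' candidate table together with the inputs in a `crossdate` object with
#' `print`, `summary` and `plot` methods. The top-ranked end-year is the
#' proposed date of the sample's final ring.
#'
#' @inheritParams scan_offsets
#' @return an object of class `crossdate` with elements `results` (the
#'   ranked data frame of [scan_offsets()]), `sample_id`, `reference_id`,
#'   `policy` and `call`.
#' @examples
#' sc <- synthetic_scenario(seed = 42, master_span = c(1100, 1650))
#' ref <- generate_master(sc)
#' brd <- generate_boards(sc)$boards[[1]]
#' fit <- crossdate(brd, ref)
#' fit
#' @export
crossdate <- function(sample, reference, policy = match_policy()) {
  res <- scan_offsets(sample, reference, policy)
  structure(list(results = res, sample_id = sample$series_id,
                 reference_id = reference$series_id, policy = policy,
                 call = match.call()),
            class = "crossdate")
}

#' @export
print.crossdate <- function(x, n = 5L, ...) {
  cat(sprintf("Crossdating of '%s' against '%s': %d offsets scanned\n",
              x$sample_id, x$reference_id, nrow(x$results)))
  if (nrow(x$results) == 0L) {
    cat("  no admissible offset\n")
    return(invisible(x))
  }
  top <- utils::head(x$results, n)
  cat(sprintf("  %-9s %5s %7s %8s %7s %-4s %s\n",
              "end year", "Ol", "r", "TBP", "%PV", "sig", "class"))
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-9d %5d %7.3f %8.2f %7.1f %-4s %s\n",
                top$end_year[i], top$overlap[i], top$r[i], top$t_bp[i],
                top$glk[i],
                glk_marks[[top$significance_class[i]]],
                top$match_class[i]))
  invisible(x)
}

#' @export
summary.crossdate <- function(object, ...) {
  res <- object$results
  best <- if (nrow(res)) res[1L, ] else NULL
  out <- list(sample_id = object$sample_id,
              reference_id = object$reference_id,
              n_offsets = nrow(res),
              class_counts = if (nrow(res)) table(res$match_class)
                             else table(character(0)),
              best = best)
  class(out) <- "summary.crossdate"
  out
}

#' @export
print.summary.crossdate <- function(x, ...) {
  cat(sprintf("Crossdating summary: '%s' vs '%s'\n", x$sample_id,
              x$reference_id))
  cat(sprintf("  offsets scanned: %d\n", x$n_offsets))
  if (!is.null(x$best)) {
    b <- x$best
    cat(sprintf(paste0("  best: end year %d (Ol %d, r %.3f, TBP %.2f,",
                       " %%PV %.1f%s) -> %s\n"),
                b$end_year, b$overlap, b$r, b$t_bp, b$glk,
                glk_marks[[b$significance_class]], b$match_class))
    print(x$class_counts)
  }
  invisible(x)
}

#' @export
plot.crossdate <- function(x, ...) {
  res <- x$results
  if (nrow(res) == 0L) {
    warning("nothing to plot: no admissible offsets")
    return(invisible(x))
  }
  o <- order(res$end_year)
  plot(res$end_year[o], res$t_bp[o], type = "h", xlab = "proposed end year",
       ylab = "TBP t-value",
       main = sprintf("'%s' vs '%s'", x$sample_id, x$reference_id), ...)
  abline(h = c(x$policy$t_potential, x$policy$t_accepted), lty = c(3, 2),
         col = "grey40")
  invisible(x)
}

#' Assess whether two boards come from the same tree
#'
#' At a given (externally dated or scan-derived) alignment, computes the full
#' match statistics between two series and issues a same-tree verdict: the
#' boards are flagged `same_tree_candidate` when TBP is at least
#' `policy$t_same_tree` *and* %PV is significant at p < 0.001. A stated span
#' of calendar years can be excluded from the statistics (a `disregard`
#' window), the standard device when a known measurement problem contaminates
#' one end of a series.
#'
#' @param a,b [ring_series] objects. `b`'s calendar is taken as given.
#' @param aligned_end_year calendar year assigned to `a`'s final ring
#'   (default: `a$last_year`, i.e. both series dated already).
#' @param policy a [match_policy()].
#' @param disregard `NULL`, or `c(from, to)` calendar years (inclusive)
#'   excluded from both statistics.
#' @return a one-row `data.frame` in the [scan_offsets()] layout plus a
#'   logical column `same_tree`; `match_class` is `"same_tree_candidate"`
#'   when the verdict is positive, otherwise the ordinary policy class.
#' @export
assess_same_tree <- function(a, b, aligned_end_year = a$last_year,
                             policy = match_policy(), disregard = NULL) {
  stopifnot(inherits(a, "ring_series"), inherits(b, "ring_series"))
  if (!is.null(disregard)) {
    disregard <- as.integer(disregard)
    stopifnot(length(disregard) == 2L, disregard[1L] <= disregard[2L])
  }
  d <- as.integer(aligned_end_year) - a$last_year
  ab <- shift_years(bp_transform(a), d)
  as_ <- shift_years(sign_series(a), d)
  raw_ol <- length(intersect(ring_years(b),
                             seq.int(first_year(a), a$last_year) + d))
  if (raw_ol < policy$min_overlap_scan)
    stop("overlap (", raw_ol, " rings) below the policy minimum of ",
         policy$min_overlap_scan, call. = FALSE)
  st <- tbp_core(ab, bp_transform(b), exclude = disregard)
  gk <- glk_core(as_, sign_series(b), exclude = disregard)
  verdict <- st$t >= policy$t_same_tree && gk$p < 0.001
  data.frame(
    sample_id = a$series_id, reference_id = b$series_id,
    end_year = as.integer(aligned_end_year), overlap = raw_ol,
    overlap_t = st$overlap, r = st$r, t_bp = st$t, glk = gk$glk,
    glk_p = gk$p, significance_class = gk$significance_class,
    match_class = if (verdict) "same_tree_candidate"
                  else classify_match(st$t, raw_ol, gk$glk, gk$p, policy),
    same_tree = verdict, stringsAsFactors = FALSE)
}
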