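#' Construct a table of ring-measurement edit events
#'
#' An edit event localizes a single-ring measurement error in a "suspect"
#' series relative to a trusted reference of the same ring sequence:
#' `doubled_in_b` (one true ring was measured twice; correction merges the
#' two implicated widths by summation) or `missing_in_b` (one true ring was
#' skipped; correction inserts a reconstructed placeholder). Years refer to
#' the suspect's calendar at the moment the event is applied; events are
#' applied in the order given (the order [localize_edits()] returns them in).
#'
#' @param kind character vector, each `"missing_in_b"` or `"doubled_in_b"`.
#' @param year_estimate calendar year CE of the implicated ring (for a
#'   doubled ring, the first of the two duplicate measurements).
#' @param year_uncertainty non-negative integer; `1` marks the classic
#'   one-ring ambiguity where the adjacent position explains the data almost
#'   equally well.
#' @param delta_t improvement in whole-series TBP achieved by applying the
#'   correction (`NA` for hand-made events).
#' @return a `data.frame` of class `edit_events`.
#' @export
edit_events <- function(kind = character(0), year_estimate = integer(0),
                        year_uncertainty = 0L, delta_t = NA_real_) {
  kind <- as.character(kind)
  if (!all(kind %in% c("missing_in_b", "doubled_in_b")))
    stop("kind must be 'missing_in_b' or 'doubled_in_b'", call. = FALSE)
  df <- data.frame(kind = kind,
                   year_estimate = as.integer(year_estimate),
                   year_uncertainty = as.integer(rep_len(year_uncertainty,
                                                         length(kind))),
                   delta_t = as.numeric(rep_len(delta_t, length(kind))),
                   stringsAsFactors = FALSE)
  if (any(df$year_uncertainty < 0L))
    stop("year_uncertainty must be >= 0", call. = FALSE)
  class(df) <- c("edit_events", "data.frame")
  df
}

#' @export
print.edit_events <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No edit events.\n")
    return(invisible(x))
  }
  cat(nrow(x), "edit event(s):\n")
  for (i in seq_len(nrow(x))) {
    unc <- if (x$year_uncertainty[i] > 0L)
      sprintf(" (+/- %d ring)", x$year_uncertainty[i]) else ""
    dt <- if (is.na(x$delta_t[i])) "" else sprintf(", dt = +%.2f",
                                                   x$delta_t[i])
    cat(sprintf("  %s at %d%s%s\n", x$kind[i], x$year_estimate[i], unc, dt))
  }
  invisible(x)
}

#' Apply edit-event corrections to a series
#'
#' Corrections use the start-anchored calendar convention: the first ring's
#' year stays fixed and the last ring's year shifts by -1 per merged
#' (doubled) ring and +1 per inserted (missing) ring — the exact inverse of
#' [inject_errors()]. A doubled event at year `Y` merges the widths of years
#' `Y` and `Y + 1` by summation; a missing event at year `Y` inserts a
#' placeholder ring at `Y` whose width is the median of the up-to-5
#' surrounding measured rings. Reconstructed years are recorded in the
#' `reconstructed_years` attribute of the result.
#'
#' @param series a [ring_series].
#' @param events an [edit_events()] table; applied top to bottom.
#' @return the corrected [ring_series].
#' @export
apply_edits <- function(series, events) {
  stopifnot(inherits(series, "ring_series"), is.data.frame(events))
  out <- series
  recon <- attr(series, "reconstructed_years")
  for (i in seq_len(nrow(events))) {
    w <- out$widths; n <- length(w)
    j <- events$year_estimate[i] - first_year(out) + 1L
    if (events$kind[i] == "doubled_in_b") {
      if (j < 1L || j + 1L > n)
        stop("doubled event at ", events$year_estimate[i],
             " outside series '", out$series_id, "'", call. = FALSE)
      w <- c(w[seq_len(j - 1L)], w[j] + w[j + 1L],
             if (j + 2L <= n) w[seq.int(j + 2L, n)])
      out <- ring_series(w, out$last_year - 1L, out$series_id,
                         n_sapwood = out$n_sapwood,
                         pith_present = out$pith_present,
                         hw_sw_border_is_last_ring =
                           out$hw_sw_border_is_last_ring,
                         units_raw = out$units_raw)
    } else {
      if (j < 1L || j > n + 1L)
        stop("missing event at ", events$year_estimate[i],
             " outside series '", out$series_id, "'", call. = FALSE)
      local <- w[seq.int(max(1L, j - 2L), min(n, j + 2L))]
      w <- append(w, stats::median(local), after = j - 1L)
      out <- ring_series(w, out$last_year + 1L, out$series_id,
                         n_sapwood = out$n_sapwood,
                         pith_present = out$pith_present,
                         hw_sw_border_is_last_ring =
                           out$hw_sw_border_is_last_ring,
                         units_raw = out$units_raw)
      recon <- c(recon, events$year_estimate[i])
    }
  }
  attr(out, "reconstructed_years") <- recon
  out
}

# Best-lag profile: for sliding windows over the suspect's transformed
# values, the lag (suspect year + lag matched to reference year) maximizing
# the windowed correlation. A single-ring slip shows as a +/-1 step.
lag_profile <- function(ref_bp, sus_bp, window, max_lag, step) {
  ry <- value_years(ref_bp); sy <- value_years(sus_bp)
  starts <- seq.int(sy[1L], sy[length(sy)] - window + 1L, by = step)
  last_start <- sy[length(sy)] - window + 1L
  if (starts[length(starts)] != last_start)
    starts <- c(starts, last_start)   # keep a window flush with the end
  lags <- seq.int(-max_lag, max_lag)
  best <- rep(NA_integer_, length(starts))
  corr <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    yw <- seq.int(starts[i], length.out = window)
    sv <- sus_bp$values[match(yw, sy)]
    scores <- vapply(lags, function(L) {
      rv <- ref_bp$values[match(yw + L, ry)]
      ok <- !is.na(rv) & !is.na(sv)
      if (sum(ok) < max(8L, window %/% 2L)) return(NA_real_)
      if (stats::sd(sv[ok]) == 0 || stats::sd(rv[ok]) == 0) return(NA_real_)
      stats::cor(sv[ok], rv[ok])
    }, numeric(1))
    if (all(is.na(scores))) next
    best[i] <- lags[which.max(scores)]
    corr[i] <- max(scores, na.rm = TRUE)
  }
  list(starts = starts, best = best, corr = corr)
}

# Whole-series TBP of a (candidate-edited) suspect against the reference,
# maximized over a small global calendar shift. Re-anchoring mirrors what a
# dendrochronologist does after a trial correction — re-crossdate — and is
# what makes greedy one-edit-at-a-time search work when two slips offset
# each other (correcting the first one alone moves the stated end year off
# the reference until the second is corrected too). `exclude_year`
# (suspect calendar) drops a reconstructed placeholder ring from the
# correlation so that an arbitrary placeholder width cannot decide *where*
# an insertion goes.
eval_shift_t <- function(ref_bp, series, max_shift, exclude_year = NULL) {
  bp <- bp_transform(series)
  best <- -Inf
  for (d in seq.int(-max_shift, max_shift)) {
    ex <- if (!is.null(exclude_year)) rep(exclude_year + d, 2L) else NULL
    t <- tryCatch(tbp_core(shift_years(bp, d), ref_bp, exclude = ex)$t,
                  error = function(e) -Inf)
    if (t > best) best <- t
  }
  best
}

#' Localize missing and doubled rings in a suspect series
#'
#' Given a trusted reference series and a suspect series presumed to record
#' the same ring sequence (same tree, or a re-measurement of the same board),
#' locates single-ring deletions and duplications in the suspect. The
#' procedure: (1) a windowed best-lag profile over the Baillie-Pilcher
#' indices flags where the local alignment between suspect and reference
#' steps by one ring; (2) each step defines a candidate boundary region
#' whose flanking lags determine the event kind (the reference gaining a
#' ring across the step means a ring is missing in the suspect; losing one
#' means a ring was measured twice); (3) within each region the event
#' position is chosen by a local split-alignment score (head rings mapped at
#' the incoming lag, tail rings at the outgoing lag, the implicated rings
#' dropped), so neither far-field noise nor the arbitrary width of a
#' reconstructed placeholder decides the position; (4) the correction is
#' accepted if the realized whole-series TBP — re-anchored over a small
#' global shift, the way one re-crossdates after an edit — improves by at
#' least `min_gain`. The search is greedy, re-profiling after each accepted
#' edit. When two slips offset each other (one missing and one doubled ring,
#' the classic configuration) no single correction can improve the
#' whole-series match, so stalled single-edit searches fall back to
#' correcting two adjacent boundaries jointly; the joint TBP gain is then
#' shared equally between the two reported events. Every reported event
#' carries a non-negative `delta_t` and the full correction strictly
#' increases the whole-series TBP. When the adjacent position explains the
#' data nearly as well (the classic one-ring ambiguity next to
#' similar-width neighbours) `year_uncertainty` is set to 1.
#'
#' @param reference the trusted [ring_series].
#' @param suspect the [ring_series] under scrutiny; its stated end year must
#'   lie within `max_events` rings of an alignment with the reference (the
#'   calendars are taken as stated — they agree ahead of the first error
#'   under the start-anchored convention of [inject_errors()]).
#' @param max_events maximum number of single-ring events searched for.
#' @param window width (rings) of the sliding lag-profile window.
#' @param max_lag lag range scanned, `-max_lag..max_lag` rings.
#' @param min_gain minimum whole-series TBP improvement for a correction to
#'   be accepted; guards against chance "corrections" on clean pairs.
#' @return an [edit_events()] table (zero rows when nothing is found),
#'   ordered as accepted and to be applied in that order. If the lag profile
#'   shows more boundaries than `max_events`, a warning is attached and the
#'   result may be partial.
#' @seealso [apply_edits()] to obtain the corrected series.
#' @export
localize_edits <- function(reference, suspect, max_events = 3L,
                           window = 30L, max_lag = 3L, min_gain = 0.25) {
  stopifnot(inherits(reference, "ring_series"),
            inherits(suspect, "ring_series"))
  max_events <- as.integer(max_events)
  if (abs(suspect$last_year - reference$last_year) > max_events)
    stop("suspect and reference end years differ by more than max_events ",
         "rings; no approximate alignment", call. = FALSE)
  if (n_rings(suspect) < 3L * window || n_rings(reference) < 3L * window)
    stop("series shorter than 3 x window; lag profiling unreliable",
         call. = FALSE)
  ref_bp <- bp_transform(reference)
  cur <- suspect
  t_cur <- eval_shift_t(ref_bp, cur, max_events)
  if (!is.finite(t_cur))
    stop("no alignment with a finite TBP between '", reference$series_id,
         "' and '", suspect$series_id, "'", call. = FALSE)
  found <- edit_events()
  step <- max(1L, window %/% 6L)
  warned <- FALSE
  while (nrow(found) < max_events) {
    sus_bp <- bp_transform(cur)
    prof <- lag_profile(ref_bp, sus_bp, window, max_lag, step)
    bnds <- lag_boundaries(prof, window, cur, reference)
    if (!warned && length(bnds) > max_events) {
      warning("lag profile shows ", length(bnds), " boundaries but ",
              "max_events = ", max_events, "; result may be partial")
      warned <- TRUE
    }
    if (length(bnds) == 0L) {
      # two offsetting slips closer together than one profile window never
      # produce a lag step, only a dip in the windowed correlation: scan
      # joint two-event hypotheses across the dip
      vr <- find_valley(prof, window, cur)
      if (is.null(vr) || nrow(found) + 2L > max_events) break
      jp <- joint_pair_pick(cur, reference, vr)
      if (is.null(jp)) break
      ed <- tryCatch(apply_edits(cur, jp), error = function(e) NULL)
      if (is.null(ed)) break
      t2 <- eval_shift_t(ref_bp, ed, max_events)
      # a two-edit correction has twice the freedom to overfit: demand twice
      # the single-edit improvement
      if (!is.finite(t2) || t2 < t_cur + 2 * min_gain) break
      jp$delta_t <- rep((t2 - t_cur) / 2, 2L)
      found <- rbind(found, jp)
      class(found) <- c("edit_events", "data.frame")
      cur <- ed
      t_cur <- t2
      next
    }
    picks <- lapply(bnds, function(bn) {
      kind <- if (bn$b > bn$a) "missing_in_b" else "doubled_in_b"
      pick_position(cur, reference, bn, kind)
    })
    picks <- picks[!vapply(picks, is.null, logical(1))]
    if (length(picks) == 0L) break
    # single-edit acceptance on the realized, re-anchored whole-series TBP;
    # boundaries are tried earliest-first so an accepted edit always sits at
    # the first uncorrected slip, where the suspect's stated calendar still
    # agrees with the reference (incoming lag 0) and the reported year is a
    # reference-calendar estimate
    accepted <- FALSE
    for (k in seq_along(picks)) {
      p <- picks[[k]]
      ed <- tryCatch(apply_edits(cur, edit_events(p$kind, p$year)),
                     error = function(e) NULL)
      if (is.null(ed)) next
      realized <- eval_shift_t(ref_bp, ed, max_events)
      if (is.finite(realized) && realized >= t_cur + min_gain) {
        found <- rbind(found, edit_events(p$kind, p$year, p$unc,
                                          realized - t_cur))
        class(found) <- c("edit_events", "data.frame")
        cur <- ed
        t_cur <- realized
        accepted <- TRUE
        break
      }
    }
    if (accepted) next
    # offsetting slips: correct two adjacent boundaries jointly
    paired <- FALSE
    if (length(picks) >= 2L && nrow(found) + 2L <= max_events) {
      for (k1 in seq_len(length(picks) - 1L)) {
        p1 <- picks[[k1]]; p2 <- picks[[k1 + 1L]]
        s1 <- if (p1$kind == "missing_in_b") 1L else -1L
        ev <- edit_events(c(p1$kind, p2$kind), c(p1$year, p2$year + s1),
                          year_uncertainty = c(p1$unc, p2$unc))
        ed <- tryCatch(apply_edits(cur, ev), error = function(e) NULL)
        if (is.null(ed)) next
        t2 <- eval_shift_t(ref_bp, ed, max_events)
        if (is.finite(t2) && t2 >= t_cur + 2 * min_gain) {
          ev$delta_t <- rep((t2 - t_cur) / 2, 2L)
          found <- rbind(found, ev)
          class(found) <- c("edit_events", "data.frame")
          cur <- ed
          t_cur <- t2
          paired <- TRUE
          break
        }
      }
    }
    if (!paired) break
  }
  found
}

# Boundary regions of the best-lag profile: spans around every step in the
# lag sequence, plus the leading (trailing) span when the first (last)
# window is already off the lag expected there. At the start of the
# start-anchored alignment the expected lag is 0; at the end it is the
# stated end-year difference. Each boundary carries its flanking lags
# (a before, b after), whose step direction determines the event kind.
lag_boundaries <- function(prof, window, suspect, reference) {
  ok <- which(!is.na(prof$best))
  if (length(ok) == 0L) return(list())
  starts <- prof$starts[ok]; best <- prof$best[ok]
  # despeckle: a short run (one or two windows) whose lag differs from both
  # neighbours is a correlation blip — typically windows straddling a
  # duplicate pair, whose distorted values can prefer an arbitrary lag —
  # not a boundary; absorb it into the nearer-lag neighbour. Runs of three
  # or more windows are kept: with the default window and step they
  # correspond to genuine segments.
  for (pass in 1:3) {
    r <- rle(best)
    if (length(r$lengths) <= 2L) break
    changed <- FALSE
    for (k in seq.int(2L, length(r$lengths) - 1L)) {
      v <- r$values[k]; prev <- r$values[k - 1L]; nxt <- r$values[k + 1L]
      if (r$lengths[k] <= 2L && v != prev && v != nxt) {
        r$values[k] <- if (abs(v - prev) <= abs(v - nxt)) prev else nxt
        changed <- TRUE
      }
    }
    best <- inverse.rle(r)
    if (!changed) break
  }
  end_lag <- reference$last_year - suspect$last_year
  clip <- function(y1, y2)
    seq.int(max(y1, first_year(suspect) + 1L),
            min(y2, suspect$last_year - 1L))
  out <- list()
  if (best[1L] != 0L)
    out <- c(out, list(list(
      years = clip(first_year(suspect), starts[1L] + window - 1L),
      a = 0L, b = best[1L])))
  if (length(best) > 1L) {
    for (i in which(diff(best) != 0L))
      out <- c(out, list(list(
        years = clip(starts[i], starts[i + 1L] + window - 1L),
        a = best[i], b = best[i + 1L])))
  }
  if (best[length(best)] != end_lag)
    out <- c(out, list(list(
      years = clip(starts[length(starts)], suspect$last_year),
      a = best[length(best)], b = end_lag)))
  out <- out[vapply(out, function(bn) length(bn$years) > 0L, logical(1))]
  # fixed scoring span per boundary: region widened by one window but never
  # reaching into a neighbouring boundary region, so every candidate
  # position of a boundary is judged on the same set of intervals
  for (i in seq_along(out)) {
    lo <- min(out[[i]]$years) - window
    hi <- max(out[[i]]$years) + window
    if (i > 1L) lo <- max(lo, max(out[[i - 1L]]$years) + 1L)
    if (i < length(out)) hi <- min(hi, min(out[[i + 1L]]$years) - 1L)
    lo <- min(lo, min(out[[i]]$years))   # a span always contains its region
    hi <- max(hi, max(out[[i]]$years))
    out[[i]]$span <- c(max(lo, first_year(suspect)),
                       min(hi, suspect$last_year))
  }
  out
}

# Posterior position pick for one boundary region. The suspect's raw ring
# widths are matched to the reference under the split alignment (head rings
# at the boundary's incoming lag, tail rings at the outgoing lag; for a
# doubled-ring hypothesis the two duplicate measurements are replaced by
# their sum matched to the one reference ring). Raw widths are used because
# the measurement noise is additive in mm, making the residual sum of
# squares the Gaussian likelihood statistic; the noise variance is
# estimated from the best-fitting candidate. The reported position
# maximizes the posterior mass of its +/-1-ring neighbourhood — the
# quantity the recovery of a slip to "year (or year +/- 1)" actually needs
# — and the ambiguity flag is raised when the central candidate carries
# less than three quarters of that mass.
pick_position <- function(suspect, reference, bn, kind) {
  ws <- suspect$widths; wr <- reference$widths
  ys <- ring_years(suspect); yr <- ring_years(reference)
  b_shift <- if (kind == "missing_in_b") 1L else -1L
  in_span <- ys >= bn$span[1L] & ys <= bn$span[2L]
  stat <- vapply(bn$years, function(Y) {
    keep <- in_span
    if (kind == "doubled_in_b") keep <- keep & ys != Y & ys != Y + 1L
    target <- ifelse(ys < Y, ys + bn$a, ys + bn$a + b_shift)
    keep <- keep & target %in% yr
    res <- ws[keep] - wr[match(target[keep], yr)]
    if (kind == "doubled_in_b" && (Y + bn$a) %in% yr &&
        Y %in% ys && (Y + 1L) %in% ys)
      res <- c(res, ws[match(Y, ys)] + ws[match(Y + 1L, ys)] -
                 wr[match(Y + bn$a, yr)])
    c(sum(res^2), length(res))
  }, numeric(2))
  rss <- stat[1L, ]; m <- stat[2L, ]
  ok <- is.finite(rss) & m >= 8L
  if (!any(ok)) return(NULL)
  rss[!ok] <- Inf
  s2 <- max(min(rss[ok] / m[ok]), 1e-12)
  ll <- -rss / (2 * s2)
  p <- exp(ll - max(ll[ok]))
  p[!ok] <- 0
  p <- p / sum(p)
  win <- vapply(seq_along(p), function(j)
    sum(p[max(1L, j - 1L):min(length(p), j + 1L)]), numeric(1))
  j <- order(-win, -p)[1L]   # tie on window mass: prefer the central peak
  list(kind = kind, year = bn$years[j],
       unc = as.integer(p[j] / win[j] < 0.75))
}

# A contiguous run of profile windows whose best correlation drops well
# below the series' typical level, with equal lags on both sides, marks a
# zone holding two offsetting single-ring slips.
find_valley <- function(prof, window, suspect) {
  ok <- which(!is.na(prof$best))
  if (length(ok) < 5L) return(NULL)
  co <- prof$corr[ok]; starts <- prof$starts[ok]; best <- prof$best[ok]
  # absolute depth floor: windows inside a genuine two-slip valley are near
  # zero alignment, far below any noise wobble of a clean pair
  cut <- stats::median(co) - max(3 * stats::mad(co), 0.15)
  low <- co < cut
  if (!any(low)) return(NULL)
  r <- rle(low)
  ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
  li <- which(r$values)
  li <- li[which.max(r$lengths[li])]
  b <- begs[li]; e <- ends[li]
  a_lag <- if (b > 1L) best[b - 1L] else 0L
  b_lag <- if (e < length(best)) best[e + 1L] else a_lag
  if (a_lag != b_lag) return(NULL)
  years <- seq.int(starts[b] - window %/% 2L,
                   starts[e] + window + window %/% 2L)
  years <- years[years > first_year(suspect) & years < suspect$last_year]
  if (length(years) < 4L) return(NULL)
  list(years = years, a = a_lag,
       span = c(max(min(years) - window, first_year(suspect)),
                min(max(years) + window, suspect$last_year)))
}

# Joint maximum-likelihood search for one missing plus one doubled ring
# inside a valley region, in either order, by the same raw-width residual
# criterion as pick_position. Returns the two events ready for sequential
# application (the second position already carries the calendar shift the
# first correction introduces), or NULL.
joint_pair_pick <- function(suspect, reference, vr) {
  ws <- suspect$widths; wr <- reference$widths
  ys <- ring_years(suspect); yr <- ring_years(reference)
  in_span <- ys >= vr$span[1L] & ys <= vr$span[2L]
  a <- vr$a
  best <- NULL
  for (ord in c("MD", "DM")) {
    for (Y1 in vr$years) {
      y2s <- vr$years[vr$years >= Y1 + 2L]
      for (Y2 in y2s) {
        if (ord == "MD") {
          drop <- c(Y2, Y2 + 1L)
          target <- ifelse(ys < Y1, ys + a,
                           ifelse(ys < Y2, ys + a + 1L, ys + a))
          sum_year <- Y2; sum_target <- Y2 + a + 1L
        } else {
          drop <- c(Y1, Y1 + 1L)
          target <- ifelse(ys < Y1, ys + a,
                           ifelse(ys < Y2, ys + a - 1L, ys + a))
          sum_year <- Y1; sum_target <- Y1 + a
        }
        keep <- in_span & !(ys %in% drop) & target %in% yr
        res <- ws[keep] - wr[match(target[keep], yr)]
        if (all(c(sum_year, sum_year + 1L) %in% ys) && sum_target %in% yr)
          res <- c(res, ws[match(sum_year, ys)] + ws[match(sum_year + 1L, ys)] -
                     wr[match(sum_target, yr)])
        if (length(res) < 8L) next
        rss <- mean(res^2)
        if (is.null(best) || rss < best$rss)
          best <- list(rss = rss, ord = ord, Y1 = Y1, Y2 = Y2)
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (best$ord == "MD")
    edit_events(c("missing_in_b", "doubled_in_b"),
                c(best$Y1, best$Y2 + 1L), year_uncertainty = 1L)
  else
    edit_events(c("doubled_in_b", "missing_in_b"),
                c(best$Y1, best$Y2 - 1L), year_uncertainty = 1L)
}
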