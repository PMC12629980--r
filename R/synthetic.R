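#' Define a synthetic ring-width scenario
#'
#' Describes a seeded simulation of the data structure the dating analysis
#' assumes: a multi-century regional master signal with first-order
#' autoregressive (AR(1)) persistence; trees whose log growth mixes that
#' master signal with tree-level AR(1) noise (the mixing weight sets the
#' expected inter-tree correlation); a negative-exponential age trend;
#' boards cut from trees with small additive measurement noise; sapwood
#' counts drawn from a regional statistic; and optional injected single-ring
#' measurement errors. Noise is multiplicative (log-space), so widths stay
#' positive and the Baillie-Pilcher log-ratio transform is the natural
#' analysis scale.
#'
#' Defaults emulate the panel-painting study setting: a 551-year master
#' (1100-1650 CE) and three oak boards — a 210-ring board ending 1606 whose
#' outermost ring is the heartwood/sapwood border, a 231-ring board from the
#' same tree with 8 sapwood rings ending 1614, and a 99-ring board from a
#' second tree ending 1601.
#'
#' @param seed integer seed; the whole scenario is deterministic under it.
#' @param master_span `c(first, last)` calendar years of the master signal.
#' @param ar1_phi AR(1) persistence of master and tree-level signals,
#'   `0 <= phi < 1`.
#' @param master_sd standard deviation of the log-width growth signal
#'   (dimensionless, log scale).
#' @param tree_signal_share fraction of the growth-signal variance carried by
#'   the master; the expected log-width correlation between two trees equals
#'   this share, and between a tree and the master its square root.
#' @param trend `c(initial, decay, asymptote)`: age-trend width in mm starts
#'   at `initial` and decays exponentially at rate `decay` per year towards
#'   `asymptote`.
#' @param measurement_sd standard deviation (mm) of the additive measurement
#'   noise added independently to each board.
#' @param boards a `data.frame` with columns `tree`, `length`, `end_year`,
#'   `n_sapwood` (`NA` to draw uniformly from the sapwood statistic) and
#'   optionally `hw_sw_border` (logical); `NULL` gives the study-like
#'   default trio described above.
#' @param sapwood_stats a [sapwood_stats()] used for sapwood draws.
#' @param injected_events `NULL` or a `data.frame` with columns `board`
#'   (index), `kind` (`"missing"`/`"doubled"`), `year` — passed to
#'   [inject_errors()] per board.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L, master_span = c(1100L, 1650L),
                               ar1_phi = 0.3, master_sd = 0.25,
                               tree_signal_share = 0.45,
                               trend = c(initial = 2.5, decay = 0.02,
                                         asymptote = 1.0),
                               measurement_sd = 0.05,
                               boards = NULL,
                               sapwood_stats = dendrodate::sapwood_stats(),
                               injected_events = NULL) {
  master_span <- as.integer(master_span)
  if (length(master_span) != 2L || diff(master_span) + 1L < 100L)
    stop("master_span must cover at least 100 years", call. = FALSE)
  if (!(ar1_phi >= 0 && ar1_phi < 1))
    stop("ar1_phi must lie in [0, 1)", call. = FALSE)
  if (!(tree_signal_share >= 0 && tree_signal_share <= 1))
    stop("tree_signal_share must lie in [0, 1]", call. = FALSE)
  boards_supplied <- !is.null(boards)
  if (is.null(boards))
    boards <- data.frame(
      tree = c(1L, 1L, 2L),
      length = c(210L, 231L, 99L),
      end_year = c(1606L, 1614L, 1601L),
      n_sapwood = c(0L, 8L, 0L),
      hw_sw_border = c(TRUE, FALSE, FALSE))
  if (!all(c("tree", "length", "end_year") %in% names(boards)))
    stop("boards needs columns tree, length, end_year", call. = FALSE)
  if (is.null(boards$n_sapwood)) boards$n_sapwood <- NA_integer_
  if (is.null(boards$hw_sw_border)) boards$hw_sw_border <- FALSE
  if (boards_supplied && !boards_fit(boards, master_span))
    stop("board spans must lie inside the master span", call. = FALSE)
  structure(list(seed = as.integer(seed), master_span = master_span,
                 ar1_phi = ar1_phi, master_sd = master_sd,
                 tree_signal_share = tree_signal_share,
                 trend = trend, measurement_sd = measurement_sd,
                 boards = boards, sapwood_stats = sapwood_stats,
                 injected_events = injected_events),
            class = "synthetic_scenario")
}

boards_fit <- function(boards, master_span) {
  all(boards$end_year <= master_span[2L]) &&
    all(boards$end_year - boards$length + 1L >= master_span[1L])
}

# Standardized AR(1) sequence: marginal variance 1, lag-1 autocorrelation phi.
ar1_standardized <- function(n, phi) {
  if (phi == 0) return(stats::rnorm(n))
  e <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L)
  for (t in seq.int(2L, n)) x[t] <- phi * x[t - 1L] + e[t]
  x
}

#' Generate the synthetic master chronology
#'
#' The master is a standardized AR(1) signal over the scenario's span,
#' expressed as a positive mean ring-width chronology
#' `1.2 * exp(master_sd * z)` mm. Deterministic under the scenario seed (the
#' same master underlies [generate_boards()] for the same scenario).
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [chronology] spanning `master_span`.
#' @export
generate_master <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  n <- scenario$master_span[2L] - scenario$master_span[1L] + 1L
  z <- ar1_standardized(n, scenario$ar1_phi)
  chronology(1.2 * exp(scenario$master_sd * z),
             last_year = scenario$master_span[2L],
             series_id = "SYNMASTR", region = "synthetic")
}

#' Generate synthetic boards with a truth record
#'
#' Draws, deterministically under the scenario seed: the master signal; one
#' tree-level AR(1) noise series per tree, mixed with the master as
#' `sqrt(share) * master + sqrt(1 - share) * tree`; tree ring widths as
#' `trend(age) * exp(master_sd * signal)`; and per board the tree widths over
#' the board's span plus independent additive measurement noise (negative
#' draws are resampled; boards of one tree are identical when
#' `measurement_sd = 0`). Sapwood counts stated as `NA` in the board table
#' are drawn uniformly from the sapwood statistic's `[sw_min, sw_max]`
#' range. Injected errors, if any, are applied last via [inject_errors()].
#'
#' @param scenario a [synthetic_scenario()].
#' @return a list with `boards` (list of [ring_series]), `truth` (a
#'   `data.frame`: board id, tree, true first/end year, sapwood count,
#'   heartwood/sapwood border year or `NA`) and `injected` (the injected
#'   event table, possibly `NULL`).
#' @export
generate_boards <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!boards_fit(scenario$boards, scenario$master_span))
    stop("board spans must lie inside the master span", call. = FALSE)
  set.seed(scenario$seed)
  span <- scenario$master_span
  n <- span[2L] - span[1L] + 1L
  z <- ar1_standardized(n, scenario$ar1_phi)      # same draw as the master
  share <- scenario$tree_signal_share
  trees <- sort(unique(scenario$boards$tree))
  tree_w <- list()
  age <- seq_len(n)
  tr <- scenario$trend
  trend_mm <- tr[[3L]] + (tr[[1L]] - tr[[3L]]) * exp(-tr[[2L]] * age)
  for (tid in trees) {
    e <- ar1_standardized(n, scenario$ar1_phi)
    g <- sqrt(share) * z + sqrt(1 - share) * e
    tree_w[[as.character(tid)]] <- trend_mm * exp(scenario$master_sd * g)
  }
  sw <- scenario$sapwood_stats
  boards <- vector("list", nrow(scenario$boards))
  truth <- scenario$boards
  truth$board_id <- sprintf("SYNB%03d", seq_len(nrow(truth)))
  truth$first_year <- truth$end_year - truth$length + 1L
  for (i in seq_len(nrow(truth))) {
    yrs <- seq.int(truth$first_year[i], truth$end_year[i])
    w <- tree_w[[as.character(truth$tree[i])]][yrs - span[1L] + 1L]
    if (scenario$measurement_sd > 0) {
      noise <- stats::rnorm(length(w), 0, scenario$measurement_sd)
      bad <- which(w + noise <= 0)
      tries <- 0L
      while (length(bad) > 0L && tries < 1000L) {
        noise[bad] <- stats::rnorm(length(bad), 0, scenario$measurement_sd)
        bad <- which(w + noise <= 0)
        tries <- tries + 1L
      }
      if (length(bad) > 0L)
        stop("could not keep widths positive under measurement noise",
             call. = FALSE)
      w <- w + noise
    }
    nsw <- truth$n_sapwood[i]
    if (is.na(nsw))
      nsw <- sample(seq.int(sw$sw_min, sw$sw_max), 1L)
    truth$n_sapwood[i] <- nsw
    boards[[i]] <- ring_series(
      w, last_year = truth$end_year[i], series_id = truth$board_id[i],
      n_sapwood = nsw,
      hw_sw_border_is_last_ring = isTRUE(truth$hw_sw_border[i]))
  }
  truth$hw_sw_border_year <- ifelse(
    truth$hw_sw_border, truth$end_year,
    ifelse(truth$n_sapwood > 0L, truth$end_year - truth$n_sapwood,
           NA_integer_))
  injected <- scenario$injected_events
  if (!is.null(injected)) {
    for (b in unique(injected$board)) {
      ev <- injected[injected$board == b, c("kind", "year")]
      boards[[b]] <- inject_errors(boards[[b]], ev)
    }
  }
  list(boards = boards,
       truth = truth[, c("board_id", "tree", "first_year", "end_year",
                         "length", "n_sapwood", "hw_sw_border_year")],
       injected = injected)
}

#' Inject single-ring measurement errors into a series
#'
#' Emulates the two classic slip errors of manual ring measurement, under the
#' start-anchored calendar convention (the first ring's year stays fixed):
#' a `"missing"` event removes the ring of the stated year, shifting the
#' calendar mapping of all later rings back by one (end year decreases by 1);
#' a `"doubled"` event splits the stated ring into two rings of half its
#' width (end year increases by 1; total width is conserved, which makes the
#' summation merge of [apply_edits()] its exact inverse).
#'
#' @param series a [ring_series].
#' @param events a `data.frame` with columns `kind` (`"missing"` or
#'   `"doubled"`) and `year` (calendar year in the clean series); event years
#'   must be distinct and inside the span.
#' @return the corrupted [ring_series].
#' @export
inject_errors <- function(series, events) {
  stopifnot(inherits(series, "ring_series"), is.data.frame(events))
  if (nrow(events) == 0L) return(series)
  if (!all(events$kind %in% c("missing", "doubled")))
    stop("event kind must be 'missing' or 'doubled'", call. = FALSE)
  if (anyDuplicated(events$year))
    stop("overlapping events: years must be distinct", call. = FALSE)
  fy <- first_year(series)
  if (any(events$year < fy | events$year > series$last_year))
    stop("event year outside the series span", call. = FALSE)
  w <- series$widths
  last <- series$last_year
  # apply in descending year order so earlier indices stay valid
  events <- events[order(-events$year), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    j <- events$year[i] - fy + 1L
    if (events$kind[i] == "missing") {
      w <- w[-j]
      last <- last - 1L
    } else {
      w <- append(w[-j], rep(w[j] / 2, 2L), after = j - 1L)
      last <- last + 1L
    }
  }
  ring_series(w, last_year = last, series_id = series$series_id,
              n_sapwood = series$n_sapwood,
              pith_present = series$pith_present,
              hw_sw_border_is_last_ring = series$hw_sw_border_is_last_ring,
              units_raw = series$units_raw)
}
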