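#' Assemble a dendrochronological dating report
#'
#' A dating report bundles everything a reader needs to assess how a date was
#' obtained: the sample's metadata, the reference chronologies consulted
#' (with identifiers), the crossdating statistics table, and the felling and
#' production estimates with the sapwood statistics behind them. A bare date
#' without its supporting statistics is not representable: a crossdating
#' table requires a felling estimate and vice versa, enforced at
#' construction.
#'
#' @param sample a [ring_series] (its metadata is embedded) or a list of
#'   fields `series_id`, `n_rings`, `first_year`, `last_year`, `n_sapwood`.
#' @param references character vector of reference chronology identifiers.
#' @param crossdating a [crossdate] object, an [assess_same_tree()] /
#'   [scan_offsets()] data frame, or `NULL`.
#' @param felling a [estimate_felling()] result, or `NULL`.
#' @param production a [estimate_production()] result, or `NULL`.
#' @param seed optional integer echoed into the report for reproducibility.
#' @param config optional named list of settings echoed into the report.
#' @return an object of class `dating_report`.
#' @export
dating_report <- function(sample, references = character(0),
                          crossdating = NULL, felling = NULL,
                          production = NULL, seed = NULL, config = NULL) {
  if (inherits(sample, "ring_series"))
    sample <- list(series_id = sample$series_id, n_rings = n_rings(sample),
                   first_year = first_year(sample),
                   last_year = sample$last_year,
                   n_sapwood = sample$n_sapwood)
  if (inherits(crossdating, "crossdate")) crossdating <- crossdating$results
  has_table <- is.data.frame(crossdating) && nrow(crossdating) > 0L
  if (has_table && is.null(felling))
    stop("a crossdating table without a felling estimate states a date ",
         "without its interpretation; supply `felling`", call. = FALSE)
  if (!is.null(felling) && !has_table)
    stop("a felling estimate requires the crossdating statistics that ",
         "support the date; supply a non-empty `crossdating` table",
         call. = FALSE)
  if (!is.null(production) && is.null(felling))
    stop("a production estimate requires its felling estimate",
         call. = FALSE)
  structure(list(schema = "dendrodate-report/1",
                 software = paste0("dendrodate ",
                                   as.character(utils::packageVersion("dendrodate"))),
                 sample = sample, references = as.character(references),
                 crossdating = crossdating, felling = felling,
                 production = production, seed = seed, config = config),
            class = "dating_report")
}

#' Render a dating report
#'
#' @param report a [dating_report()].
#' @param format `"markdown"` (a human-readable report whose statistics
#'   table carries the columns end year, Ol, r, TBP, %PV and significance
#'   marks) or `"json"` (a lossless machine-readable document; see
#'   [report_from_json()]).
#' @return a character scalar holding the rendered document.
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "dating_report"))
  if (format == "json") return(report_to_json(report))
  s <- report$sample
  lines <- c(
    sprintf("# Dendrochronological dating report: %s", s$series_id),
    "",
    sprintf("- Software: %s", report$software),
    sprintf("- Rings measured: %d (%d-%d CE)", s$n_rings, s$first_year,
            s$last_year),
    sprintf("- Sapwood rings: %d", s$n_sapwood))
  if (!is.null(report$seed))
    lines <- c(lines, sprintf("- Seed: %d", as.integer(report$seed)))
  if (!is.null(report$config) && length(report$config))
    lines <- c(lines, paste0("- Config: ",
                             paste(names(report$config), unlist(report$config),
                                   sep = "=", collapse = ", ")))
  if (length(report$references)) {
    lines <- c(lines, "", "## Reference chronologies", "",
               paste0("- ", report$references))
  }
  if (is.data.frame(report$crossdating) && nrow(report$crossdating) > 0L) {
    cd <- report$crossdating
    lines <- c(lines, "", "## Crossdating statistics", "",
               "| end year | Ol | r | TBP | %PV | sig |",
               "|---:|---:|---:|---:|---:|:---|",
               sprintf("| %d | %d | %.3f | %.2f | %.1f | %s |",
                       cd$end_year, cd$overlap, cd$r, cd$t_bp, cd$glk,
                       unname(glk_marks[cd$significance_class])))
  }
  if (!is.null(report$felling)) {
    f <- report$felling
    lines <- c(lines, "", "## Felling estimate", "",
               utils::capture.output(print(f)))
  }
  if (!is.null(report$production)) {
    lines <- c(lines, "", "## Production estimate", "",
               utils::capture.output(print(report$production)))
  }
  paste(lines, collapse = "\n")
}

report_to_json <- function(report) {
  x <- unclass(report)
  if (!is.null(x$felling)) {
    x$felling <- unclass(x$felling)
    x$felling$basis <- unclass(x$felling$basis)
  }
  if (!is.null(x$production)) {
    x$production <- unclass(x$production)
    x$production$felling <- NULL     # held at top level; avoid duplication
    x$production$seasoning <- unclass(x$production$seasoning)
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "columns")
}

#' Parse a JSON dating report back into a `dating_report`
#'
#' Inverse of `render_report(report, "json")`: the round trip preserves the
#' sample metadata, references, crossdating table and both estimates.
#'
#' @param json a JSON string produced by [render_report()].
#' @return a [dating_report()] object.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (!identical(x$schema, "dendrodate-report/1"))
    stop("unrecognised report schema: ", x$schema, call. = FALSE)
  felling <- NULL
  if (!is.null(x$felling)) {
    basis <- do.call(sapwood_stats,
                     x$felling$basis[c("region", "sw_min", "sw_median",
                                       "sw_max", "confidence")])
    felling <- estimate_felling(x$felling$last_ring_year, x$felling$context,
                                stats = basis,
                                n_sapwood = if (x$felling$context ==
                                                "partial_sapwood")
                                  x$felling$last_ring_year -
                                    (x$felling$upper - basis$sw_max)
                                else 0L)
  }
  production <- NULL
  if (!is.null(x$production) && !is.null(felling))
    production <- estimate_production(
      felling, seasoning_policy(x$production$seasoning$s_min,
                                x$production$seasoning$s_max))
  cd <- x$crossdating
  if (!is.null(cd)) cd <- as.data.frame(cd, stringsAsFactors = FALSE)
  dating_report(sample = x$sample, references = x$references,
                crossdating = cd, felling = felling,
                production = production, seed = x$seed, config = x$config)
}

#' @export
print.dating_report <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}
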