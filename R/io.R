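#' Read ring-width series from a dendro data file
#'
#' Supports the three formats in which ring-width series circulate in public
#' tree-ring archives:
#' \describe{
#'   \item{Tucson RWL (`"rwl"`)}{decade rows: an 8-character series ID, the
#'     calendar year of the row's first value, then up to ten integer widths.
#'     The end-of-series sentinel is `999` for files stored in 0.01 mm and
#'     `-9999` for files stored in 0.001 mm; the unit is inferred from the
#'     sentinel unless `unit` is given explicitly.}
#'   \item{Heidelberg FH (`"heidelberg"`)}{`HEADER:` keyword block
#'     (`KeyCode`, `DateEnd`, `Length`, `Unit`, optionally `DateBegin`,
#'     `SapWoodRings`, `Pith`) followed by a `DATA:` block of integer widths.}
#'   \item{CSV (`"csv"`)}{two columns `year,width_mm`, one series per file,
#'     years strictly consecutive.}
#' }
#'
#' @param path path to an existing file.
#' @param format one of `"auto"`, `"rwl"`, `"heidelberg"`, `"csv"`. With
#'   `"auto"` the format is taken from the file extension (`.rwl`/`.tuc`,
#'   `.fh`, `.csv`) or, failing that, sniffed from the content.
#' @param unit optional explicit storage unit (`"0.01 mm"` or `"0.001 mm"`)
#'   overriding sentinel/keyword inference. Required for a Tucson file whose
#'   series carry no recognisable sentinel.
#' @return a list of [ring_series] objects (possibly empty).
#' @seealso [write_series()]
#' @export
read_series <- function(path, format = c("auto", "rwl", "heidelberg", "csv"),
                        unit = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- detect_format(path)
  switch(format,
         rwl = read_rwl(path, unit = unit),
         heidelberg = read_heidelberg(path, unit = unit),
         csv = read_csv_series(path))
}

#' Write ring-width series to a dendro data file
#'
#' Widths are rounded to the storage precision of each series' `units_raw`
#' field (overridable via `unit`), so that a write/read round trip reproduces
#' widths exactly at source precision.
#'
#' @param series a single [ring_series] or a list of them (an empty list
#'   writes a valid empty file).
#' @param path output file path.
#' @param format `"auto"` (from the extension), `"rwl"`, `"heidelberg"` or
#'   `"csv"`. CSV accepts only a single series per file.
#' @param unit optional storage unit forced for all series.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path,
                         format = c("auto", "rwl", "heidelberg", "csv"),
                         unit = NULL) {
  format <- match.arg(format)
  if (inherits(series, "ring_series")) series <- list(series)
  if (!is.list(series) || !all(vapply(series, inherits, TRUE, "ring_series")))
    stop("series must be a ring_series or a list of them", call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     rwl = , tuc = "rwl", fh = "heidelberg", csv = "csv",
                     stop("cannot infer output format from extension of ",
                          path, call. = FALSE))
  }
  switch(format,
         rwl = write_rwl(series, path, unit = unit),
         heidelberg = write_heidelberg(series, path, unit = unit),
         csv = write_csv_series(series, path))
  invisible(path)
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("rwl", "tuc")) return("rwl")
  if (ext == "fh") return("heidelberg")
  if (ext == "csv") return("csv")
  head_lines <- readLines(path, n = 5L, warn = FALSE)
  if (any(grepl("^HEADER:", head_lines))) return("heidelberg")
  if (any(grepl("^\\s*year\\s*,", head_lines, ignore.case = TRUE)))
    return("csv")
  "rwl"
}

# storage divisor: mm = raw / divisor; division (not multiplication by the
# inexact 0.01/0.001) keeps parsed decimals and integer storage bit-identical
unit_divisor <- function(unit) switch(unit, "0.01 mm" = 100,
                                      "0.001 mm" = 1000,
                                      stop("unknown unit: ", unit))

check_unit_arg <- function(unit) {
  if (is.null(unit)) return(NULL)
  match.arg(unit, c("0.01 mm", "0.001 mm"))
}

## ---- Tucson RWL ----------------------------------------------------------

read_rwl <- function(path, unit = NULL) {
  unit <- check_unit_arg(unit)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  ids <- character(0)
  tokens <- list()   # per id: integer vector of raw values
  next_year <- list() # per id: expected year of the next row
  for (i in keep) {
    line <- lines[i]
    id <- trimws(substr(line, 1L, 8L))
    rest <- substring(line, 9L)
    toks <- tryCatch(scan(text = rest, what = character(), quiet = TRUE),
                     error = function(e) NULL)
    vals <- suppressWarnings(as.integer(toks))
    if (id == "" || length(vals) < 2L || anyNA(vals))
      stop("malformed Tucson decade row at line ", i, " of ", path,
           call. = FALSE)
    year <- vals[1L]
    vals <- vals[-1L]
    if (length(vals) > 10L)
      stop("malformed Tucson decade row at line ", i, " of ", path,
           ": more than 10 values", call. = FALSE)
    if (!id %in% ids) {
      ids <- c(ids, id)
      tokens[[id]] <- integer(0)
      next_year[[id]] <- year
    }
    if (year != next_year[[id]])
      stop("Tucson decade row at line ", i, " of ", path,
           " states year ", year, " but ", next_year[[id]],
           " was expected for series '", id, "'", call. = FALSE)
    tokens[[id]] <- c(tokens[[id]], vals)
    next_year[[id]] <- year + length(vals)
  }
  lapply(ids, function(id) {
    vals <- tokens[[id]]
    last <- vals[length(vals)]
    if (!is.null(unit)) {
      sentinel <- if (unit == "0.001 mm") -9999L else 999L
      if (last == sentinel) vals <- vals[-length(vals)]
    } else if (last == -9999L) {
      unit <- "0.001 mm"
      vals <- vals[-length(vals)]
    } else if (last == 999L) {
      unit <- "0.01 mm"
      vals <- vals[-length(vals)]
    } else {
      stop("series '", id, "' in ", path, " ends without a recognised ",
           "sentinel (999 or -9999); pass unit = \"0.01 mm\" or ",
           "\"0.001 mm\" explicitly", call. = FALSE)
    }
    if (length(vals) == 0L)
      stop("series '", id, "' in ", path, " has no ring values",
           call. = FALSE)
    if (any(vals <= 0L))
      stop("series '", id, "' in ", path, " contains non-positive widths; ",
           "width 0 (missing ring placeholder) is rejected", call. = FALSE)
    start <- next_year[[id]] - length(tokens[[id]])
    ring_series(vals / unit_divisor(unit),
                last_year = start + length(vals) - 1L,
                series_id = id, units_raw = unit)
  })
}

write_rwl <- function(series, path, unit = NULL) {
  unit <- check_unit_arg(unit)
  out <- character(0)
  for (s in series) {
    u <- if (is.null(unit)) s$units_raw else unit
    sentinel <- if (u == "0.001 mm") -9999L else 999L
    vals <- as.integer(round(s$widths * unit_divisor(u)))
    if (any(vals <= 0L))
      stop("series '", s$series_id, "': width below storage precision ",
           u, call. = FALSE)
    if (any(vals >= 99999L))
      stop("series '", s$series_id, "': width too large for the Tucson ",
           "6-character field at ", u, call. = FALSE)
    fy <- first_year(s)
    if (fy < 1L || s$last_year > 9999L)
      stop("series '", s$series_id, "': years outside the Tucson format's ",
           "year-field capacity (1..9999 CE)", call. = FALSE)
    vals <- c(vals, sentinel)
    yrs <- seq.int(fy, fy + length(vals) - 1L)
    row_of <- yrs %/% 10L
    for (d in unique(row_of)) {
      sel <- which(row_of == d)
      out <- c(out, sprintf("%-8s%4d%s", substr(s$series_id, 1L, 8L),
                            yrs[sel[1L]],
                            paste0(sprintf("%6d", vals[sel]),
                                   collapse = "")))
    }
  }
  writeLines(out, path)
}

## ---- Heidelberg FH -------------------------------------------------------

read_heidelberg <- function(path, unit = NULL) {
  unit <- check_unit_arg(unit)
  lines <- readLines(path, warn = FALSE)
  hdr_at <- grep("^HEADER:", lines)
  if (length(hdr_at) == 0L && any(nzchar(trimws(lines))))
    stop("no HEADER: block found in ", path, call. = FALSE)
  bounds <- c(hdr_at, length(lines) + 1L)
  out <- vector("list", length(hdr_at))
  for (b in seq_along(hdr_at)) {
    block <- lines[seq.int(hdr_at[b], bounds[b + 1L] - 1L)]
    data_at <- grep("^DATA", block)
    if (length(data_at) != 1L)
      stop("HEADER block ", b, " in ", path, " lacks a DATA line",
           call. = FALSE)
    kv <- block[seq.int(2L, data_at - 1L)]
    kv <- kv[grepl("=", kv, fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- trimws(keys)
    get_key <- function(k) if (k %in% names(vals)) trimws(vals[[k]]) else NA
    len <- as.integer(get_key("Length"))
    date_end <- as.integer(get_key("DateEnd"))
    if (is.na(len) || is.na(date_end))
      stop("HEADER block ", b, " in ", path,
           " must state Length and DateEnd", call. = FALSE)
    u <- unit
    if (is.null(u)) {
      ukey <- get_key("Unit")
      u <- if (is.na(ukey)) "0.01 mm"
           else switch(ukey, "1/100 mm" = "0.01 mm",
                       "1/1000 mm" = "0.001 mm",
                       stop("unsupported Unit '", ukey, "' in ", path,
                            "; pass unit explicitly", call. = FALSE))
    }
    raw <- suppressWarnings(as.integer(scan(
      text = paste(block[seq.int(data_at + 1L, length(block))],
                   collapse = " "),
      what = character(), quiet = TRUE)))
    if (anyNA(raw))
      stop("non-numeric value in DATA block ", b, " of ", path,
           call. = FALSE)
    if (length(raw) < len)
      stop("DATA block ", b, " of ", path, " holds ", length(raw),
           " values but Length=", len, call. = FALSE)
    raw <- raw[seq_len(len)]  # FH files pad the final line with zeros
    if (any(raw <= 0L))
      stop("series '", get_key("KeyCode"), "' in ", path,
           " contains non-positive widths", call. = FALSE)
    db <- as.integer(get_key("DateBegin"))
    if (!is.na(db) && db != date_end - len + 1L)
      stop("DateBegin/DateEnd/Length inconsistent in block ", b, " of ",
           path, call. = FALSE)
    nsw <- as.integer(get_key("SapWoodRings"))
    out[[b]] <- ring_series(
      raw / unit_divisor(u), last_year = date_end,
      series_id = if (is.na(get_key("KeyCode"))) paste0("FH", b)
                  else get_key("KeyCode"),
      n_sapwood = if (is.na(nsw)) 0L else nsw,
      pith_present = identical(get_key("Pith"), "P"),
      units_raw = u)
  }
  out
}

write_heidelberg <- function(series, path, unit = NULL) {
  unit <- check_unit_arg(unit)
  out <- character(0)
  for (s in series) {
    u <- if (is.null(unit)) s$units_raw else unit
    vals <- as.integer(round(s$widths * unit_divisor(u)))
    if (any(vals <= 0L))
      stop("series '", s$series_id, "': width below storage precision ",
           u, call. = FALSE)
    out <- c(out,
             "HEADER:",
             paste0("KeyCode=", s$series_id),
             "DataFormat=Tree",
             paste0("DateBegin=", first_year(s)),
             paste0("DateEnd=", s$last_year),
             paste0("Length=", length(vals)),
             paste0("Unit=", if (u == "0.01 mm") "1/100 mm" else "1/1000 mm"),
             paste0("SapWoodRings=", s$n_sapwood),
             if (s$pith_present) "Pith=P",
             "DATA:Single")
    rows <- split(vals, (seq_along(vals) - 1L) %/% 10L)
    out <- c(out, vapply(rows, function(v)
      paste0(sprintf("%6d", v), collapse = ""), character(1)))
  }
  writeLines(out, path)
}

## ---- CSV -----------------------------------------------------------------

read_csv_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(list())
  names(df) <- tolower(trimws(names(df)))
  if (!all(c("year", "width_mm") %in% names(df)))
    stop("CSV must have columns 'year' and 'width_mm': ", path,
         call. = FALSE)
  yr <- as.integer(df$year)
  if (anyNA(yr) || any(diff(yr) != 1L))
    stop("CSV years must be strictly consecutive integers: ", path,
         call. = FALSE)
  w <- as.numeric(df$width_mm)
  precise <- all(abs(w * 100 - round(w * 100)) < 1e-9)
  list(ring_series(w, last_year = yr[length(yr)],
                   series_id = tools::file_path_sans_ext(basename(path)),
                   units_raw = if (precise) "0.01 mm" else "0.001 mm"))
}

write_csv_series <- function(series, path) {
  if (length(series) > 1L)
    stop("the CSV dialect holds a single series per file", call. = FALSE)
  if (length(series) == 0L) {
    writeLines("year,width_mm", path)
    return(invisible(path))
  }
  utils::write.csv(as.data.frame(series[[1L]]), path, row.names = FALSE,
                   quote = FALSE)
}
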