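#' Read a titration table from CSV
#'
#' The on-disk dialect is a plain comma-separated table with a header row
#' `aliquot,branch,pH` followed by one column per probe; decimal point `.`,
#' UTF-8, no quoting. Empty shift cells denote probes not observed at that
#' point. pH is stored exactly as read from the meter (no deuterium-isotope
#' correction) and shifts are stored as given (no re-referencing).
#'
#' @param path Path to an existing CSV file.
#' @param compound,temperature Metadata attached to the returned series (the
#'   table itself carries none).
#' @return A validated [titration_series()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("aliquot,branch,pH,H6,H9",
#'              "0,initial,6.10,6.90,4.80",
#'              "1,base,8.00,6.75,4.68",
#'              "2,base,9.90,6.61,"), f)
#' read_titration_csv(f)
#' @export
read_titration_csv <- function(path, compound = "", temperature = 296.15) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  mandatory <- c("aliquot", "branch", "pH")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # file line = data row + 1 (header)
  parse_num <- function(txt, column, allow_empty) {
    txt <- trimws(txt)
    empty <- !nzchar(txt)
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) & !empty)
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                   txt[bad[1]], column, bad[1] + 1L), call. = FALSE)
    }
    if (!allow_empty && any(empty)) {
      stop(sprintf("empty value in column '%s' at row %d", column,
                   which(empty)[1] + 1L), call. = FALSE)
    }
    out
  }
  pts <- data.frame(
    aliquot = parse_num(raw$aliquot, "aliquot", allow_empty = FALSE),
    branch = trimws(raw$branch),
    pH = parse_num(raw$pH, "pH", allow_empty = FALSE),
    stringsAsFactors = FALSE
  )
  for (p in setdiff(names(raw), mandatory)) {
    pts[[p]] <- parse_num(raw[[p]], p, allow_empty = TRUE)
  }
  titration_series(pts, compound = compound, temperature = temperature)
}

#' Write a titration table to CSV
#'
#' Emits the dialect read by [read_titration_csv()], preserving shifts and pH
#' to full double precision (up to 15 significant digits), so that a
#' read/write cycle is the identity and a second cycle is byte-identical.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  validate_titration_series(series)
  fmt <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) "" else trimws(formatC(v, digits = 15, format = "g"))
    }, character(1))
  }
  pts <- series$points
  cols <- c(list(aliquot = as.character(pts$aliquot), branch = pts$branch,
                 pH = fmt(pts$pH)),
            stats::setNames(lapply(series$probes, function(p) fmt(pts[[p]])),
                            series$probes))
  header <- paste(names(cols), collapse = ",")
  body <- if (nrow(pts) == 0) character(0) else {
    do.call(paste, c(unname(cols), sep = ","))
  }
  ok <- try(writeLines(c(header, body), path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write titration table to '", path, "'", call. = FALSE)
  }
  invisible(path)
}

#' Restrict a titration series to selected titrant branches
#'
#' Titrations may carry points from both an acid and a base titrant branch;
#' pKa fits conventionally use a single branch (plus the initial spectrum).
#' Acid-branch points remain stored but are excluded from fits by default in
#' [run_pipeline()], because acid titrants can hydrolyse the imine and leave
#' only a handful of usable spectra.
#'
#' @param series A [titration_series()].
#' @param branches Character vector of branch tags to keep (subset of
#'   `"initial"`, `"base"`, `"acid"`).
#' @return The sub-series, ordering and metadata unchanged. If fewer than two
#'   points remain, a `degenerate` attribute is set and a warning raised
#'   (downstream fits will refuse such a series).
#' @export
select_branch <- function(series, branches) {
  validate_titration_series(series)
  if (length(branches) == 0) {
    stop("`branches` must not be empty", call. = FALSE)
  }
  keep <- series$points$branch %in% branches
  out <- titration_series(series$points[keep, , drop = FALSE],
                          compound = series$compound,
                          temperature = series$temperature)
  # preserve full probe set even if a probe is unobserved in the sub-series
  if (nrow(out$points) < 2) {
    attr(out, "degenerate") <- TRUE
    warning("branch selection left fewer than 2 points; ",
            "downstream fits will refuse this series", call. = FALSE)
  }
  out
}
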