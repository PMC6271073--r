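#' Construct a titration series
#'
#' The central container of the package: an ordered table of titration
#' points, each carrying an aliquot index, a titrant branch tag, a pH-meter
#' reading and the observed \eqn{^1}H chemical shifts (ppm) of one or more
#' reporter nuclei ("probes"). Shifts may be missing at individual points
#' (e.g. a resonance lost under overlap); missing entries are `NA`.
#'
#' @param points A data frame with mandatory columns `aliquot` (non-negative
#'   integer, strictly increasing), `branch` (one of `"initial"`, `"base"`,
#'   `"acid"`) and `pH` (finite numeric), followed by one numeric column per
#'   probe (ppm, `NA` where unobserved).
#' @param compound Free-text metadata describing the compound.
#' @param temperature Temperature of the experiment in kelvin.
#' @return An object of class `titration_series` with fields `compound`,
#'   `temperature`, `points` and `probes`.
#' @examples
#' pts <- data.frame(aliquot = 0:2, branch = c("initial", "base", "base"),
#'                   pH = c(6.1, 7.9, 9.8), H6 = c(6.90, 6.75, 6.61),
#'                   H9 = c(4.80, 4.68, 4.56))
#' titration_series(pts, compound = "example")
#' @seealso [read_titration_csv()], [select_branch()]
#' @export
titration_series <- function(points, compound = "", temperature = 296.15) {
  if (!is.data.frame(points)) {
    stop("`points` must be a data frame", call. = FALSE)
  }
  mandatory <- c("aliquot", "branch", "pH")
  miss <- setdiff(mandatory, names(points))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  points$aliquot <- as.integer(points$aliquot)
  points$branch <- as.character(points$branch)
  points$pH <- as.numeric(points$pH)
  probes <- setdiff(names(points), mandatory)
  for (p in probes) points[[p]] <- as.numeric(points[[p]])
  rownames(points) <- NULL
  obj <- structure(
    list(compound = as.character(compound)[1],
         temperature = as.numeric(temperature)[1],
         points = points,
         probes = probes),
    class = "titration_series"
  )
  validate_titration_series(obj)
}

#' Validate a titration series
#'
#' Checks the structural invariants of a [titration_series()]: branch tags
#' are known, pH and shift values are finite where present, aliquot indices
#' are strictly increasing, and at most one point is tagged `initial` (in
#' which case it must come first).
#'
#' @param x A `titration_series` object.
#' @return `x`, invisibly recloned, if valid; otherwise an error is thrown.
#' @export
validate_titration_series <- function(x) {
  if (!inherits(x, "titration_series")) {
    stop("not a titration_series", call. = FALSE)
  }
  pts <- x$points
  if (x$temperature <= 0 || !is.finite(x$temperature)) {
    stop("temperature must be a positive, finite kelvin value", call. = FALSE)
  }
  n <- nrow(pts)
  if (n == 0) return(x)
  bad_branch <- !pts$branch %in% c("initial", "base", "acid")
  if (any(bad_branch)) {
    stop("unknown branch tag(s): ",
         paste(unique(pts$branch[bad_branch]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(pts$pH))) {
    stop("non-finite pH at point(s) ",
         paste(which(!is.finite(pts$pH)), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(pts$aliquot)) || any(pts$aliquot < 0)) {
    stop("aliquot indices must be non-negative integers", call. = FALSE)
  }
  if (n > 1 && any(diff(pts$aliquot) <= 0)) {
    stop("aliquot indices must be strictly increasing (duplicate or ",
         "out-of-order index)", call. = FALSE)
  }
  for (p in x$probes) {
    v <- pts[[p]]
    if (any(!is.na(v) & !is.finite(v))) {
      stop("non-finite shift for probe ", p, call. = FALSE)
    }
  }
  ini <- which(pts$branch == "initial")
  if (length(ini) > 1) {
    stop("at most one point may be tagged 'initial'", call. = FALSE)
  }
  if (length(ini) == 1 && ini != 1) {
    stop("the 'initial' point must be the first point", call. = FALSE)
  }
  x
}

#' Number of points in a titration series
#' @param x A `titration_series`.
#' @return Integer point count.
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "titration_series"))
  nrow(x$points)
}

# observed (non-NA) shifts for one probe, in point order
probe_observations <- function(series, probe) {
  if (!probe %in% series$probes) {
    stop("probe '", probe, "' not present in series (has: ",
         paste(series$probes, collapse = ", "), ")", call. = FALSE)
  }
  pts <- series$points
  keep <- !is.na(pts[[probe]])
  data.frame(index = which(keep), aliquot = pts$aliquot[keep],
             branch = pts$branch[keep], pH = pts$pH[keep],
             shift = pts[[probe]][keep])
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series>", if (nzchar(x$compound)) x$compound else "(unnamed)",
      "\n")
  cat(sprintf("  %d points, %.2f K, probes: %s\n", nrow(x$points),
              x$temperature, paste(x$probes, collapse = ", ")))
  if (nrow(x$points) > 0) {
    tab <- table(x$points$branch)
    cat("  branches:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
    cat(sprintf("  pH range: %.2f .. %.2f\n", min(x$points$pH),
                max(x$points$pH)))
  }
  invisible(x)
}
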