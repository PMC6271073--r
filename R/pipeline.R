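#' Pipeline configuration
#'
#' @param temperature_K Temperature (K) for the thermodynamic layer.
#' @param gas_constant Gas constant, J mol^-1 K^-1.
#' @param probe_x,probe_y Probes paired in the delta-diagram (x
#'   conventionally reports the O--H site, y the N--H site).
#' @param probe_hh Probe used for the Henderson-Hasselbalch stage; defaults
#'   to `probe_y`.
#' @param method `"auto"` selects Perrin for a linear (0-breakpoint)
#'   diagram and Polster-Lachmann otherwise; or force one of the two.
#' @param plateau_points Points averaged per plateau end for limiting
#'   shifts.
#' @param branches Branch tags used in fits; acid-branch points are
#'   excluded by default.
#' @param tol_model,resolution Passed to [linearity_check()].
#' @param tol_unity Near-unity band half-width for flags/classification.
#' @param max_breaks Maximum breakpoints considered.
#' @param anchor_start,anchor_end Optional delta-diagram anchor overrides
#'   (length-2 `(x, y)` in ppm) for truncated titrations.
#' @param seed Seed recorded in reports for provenance of synthetic inputs.
#' @return An object of class `pipeline_config`.
#' @seealso [read_config()] to load a YAML or JSON configuration file.
#' @export
pipeline_config <- function(temperature_K = 296.15, gas_constant = 8.314,
                            probe_x = "H6", probe_y = "H9", probe_hh = NULL,
                            method = c("auto", "perrin", "polster-lachmann"),
                            plateau_points = 3,
                            branches = c("initial", "base"),
                            tol_model = 0.05, resolution = 0.002,
                            tol_unity = 0.005, max_breaks = 2,
                            anchor_start = NULL, anchor_end = NULL,
                            seed = NULL) {
  method <- match.arg(method)
  structure(list(
    temperature_K = temperature_K, gas_constant = gas_constant,
    probe_x = probe_x, probe_y = probe_y,
    probe_hh = probe_hh %||% probe_y,
    method = method, plateau_points = as.integer(plateau_points),
    branches = branches, tol_model = tol_model, resolution = resolution,
    tol_unity = tol_unity, max_breaks = as.integer(max_breaks),
    anchor_start = anchor_start, anchor_end = anchor_end,
    seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized keys match the arguments of [pipeline_config()]; unknown keys
#' are an error (typo protection). JSON is a subset of YAML, so both
#' formats are read by the same parser.
#'
#' @param path Path to a YAML or JSON file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("anchor_start", "anchor_end")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as.numeric(unlist(raw[[k]]))
  }
  if (!is.null(raw$branches)) raw$branches <- as.character(unlist(raw$branches))
  do.call(pipeline_config, raw)
}

#' Run the full titration analysis pipeline
#'
#' Executes branch selection, the Henderson-Hasselbalch pKa stage (split
#' into pH windows around each detected transition when the delta-diagram
#' shows more than one), delta-diagram construction with linearity
#' classification, quotient estimation by the method selected (Perrin for
#' linear diagrams, Polster-Lachmann for kinked ones under `"auto"`), and
#' the thermodynamic layer. Any stage failure is recorded under the stage
#' name and downstream results are reported as explicit nulls; the report
#' is deterministic given the input series and configuration.
#'
#' @param series A [titration_series()].
#' @param config A [pipeline_config()].
#' @return An object of class `titration_report` (a nested list ready for
#'   [write_report()]).
#' @export
run_pipeline <- function(series, config = pipeline_config()) {
  stopifnot(inherits(series, "titration_series"),
            inherits(config, "pipeline_config"))
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  selected <- run_stage("branch_selection", {
    suppressWarnings(select_branch(series, config$branches))
  })

  diagram <- if (!is.null(selected)) run_stage("delta_diagram", {
    build_diagram(selected, config$probe_x, config$probe_y,
                  start_anchor = config$anchor_start,
                  end_anchor = config$anchor_end)
  })

  linearity <- if (!is.null(diagram)) run_stage("linearity", {
    linearity_check(diagram, max_breaks = config$max_breaks,
                    tol_model = config$tol_model,
                    resolution = config$resolution)
  })

  method <- config$method
  if (identical(method, "auto")) {
    method <- if (!is.null(linearity) && linearity$n_breaks == 0) "perrin"
    else "polster-lachmann"
  }

  quotient <- if (!is.null(diagram)) run_stage("delta_K", {
    if (identical(method, "perrin")) {
      perrin_fit(diagram, tol_unity = config$tol_unity)
    } else {
      if (is.null(linearity)) stop("linearity stage failed", call. = FALSE)
      polster_lachmann(diagram, linearity)
    }
  })

  hh_fits <- if (!is.null(selected)) run_stage("hh", {
    windows <- hh_windows(selected, linearity, config, quotient)
    lapply(windows, function(w) {
      fit <- fit_hh(w$series, config$probe_hh,
                    n_plateau = config$plateau_points, limits = w$limits)
      fit$window <- w$label
      fit
    })
  })

  thermo <- if (!is.null(quotient)) run_stage("thermodynamics", {
    tautomer_result(
      quotient$delta_K,
      stderr = if (identical(quotient$method, "perrin"))
        quotient$slope_stderr else NULL,
      method = quotient$method,
      constants = thermo_constants(config$temperature_K, config$gas_constant),
      tol_unity = config$tol_unity
    )
  })

  structure(list(
    compound = series$compound,
    config = unclass(config),
    n_points = n_points(series),
    hh = if (is.null(hh_fits)) NULL else lapply(hh_fits, report_entry),
    linearity = report_entry(linearity),
    delta_fit = report_entry(quotient),
    tautomer = report_entry(thermo),
    errors = errors
  ), class = "titration_report")
}

# Split a series into pH windows around each detected transition; with
# k >= 1 diagram breakpoints the k+1 windows are bounded by the breakpoint
# pH values, so each window isolates one deprotonation step. Near a
# breakpoint the titration curve has no true plateau: the intermediate is
# never fully populated, so a plateau mean there is biased. When the
# Gibbs-triangle fit located the pure-intermediate vertex B, its coordinate
# for the fitted probe is used as the window's inner limiting shift instead
# (one transition only; with more the plateau fallback applies).
hh_windows <- function(series, linearity, config = NULL, quotient = NULL) {
  if (is.null(linearity) || linearity$n_breaks == 0) {
    return(list(list(series = series, label = "full", limits = NULL)))
  }
  cuts <- sort(linearity$vertices$pH)
  inner_shift <- NULL
  if (!is.null(config) && !is.null(quotient) &&
      identical(quotient$method, "polster-lachmann") &&
      linearity$n_breaks == 1) {
    if (identical(config$probe_hh, config$probe_x)) {
      inner_shift <- quotient$triangle$B[1]
    } else if (identical(config$probe_hh, config$probe_y)) {
      inner_shift <- quotient$triangle$B[2]
    }
  }
  bounds <- c(-Inf, cuts, Inf)
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    keep <- series$points$pH >= bounds[k] & series$points$pH <= bounds[k + 1L]
    sub <- titration_series(series$points[keep, , drop = FALSE],
                            compound = series$compound,
                            temperature = series$temperature)
    limits <- NULL
    if (!is.null(inner_shift) && !is.null(config)) {
      obs <- sub$points[[config$probe_hh]]
      obs <- obs[!is.na(obs)]
      np <- min(config$plateau_points, max(1L, length(obs) %/% 2L))
      outer_shift <- if (k == 1L) mean(utils::head(obs, np))
      else mean(utils::tail(obs, np))
      limits <- structure(list(delta_min = min(inner_shift, outer_shift),
                               delta_max = max(inner_shift, outer_shift),
                               probe = config$probe_hh,
                               n_plateau = np,
                               spread_start = NA_real_,
                               spread_end = NA_real_, flagged = FALSE),
                          class = "limiting_shifts")
    }
    out[[k]] <- list(series = sub,
                     label = sprintf("pH %s..%s",
                                     format(bounds[k], digits = 4),
                                     format(bounds[k + 1L], digits = 4)),
                     limits = limits)
  }
  out
}

# flatten an S3 result into plain lists for JSON emission
report_entry <- function(x) {
  if (is.null(x)) return(NULL)
  out <- unclass(x)
  lapply(out, function(v) {
    if (inherits(v, "limiting_shifts") || is.list(v)) unclass(v) else v
  })
}

#' Write a pipeline report as JSON
#'
#' Numbers are written at full precision and refused stages appear as
#' explicit nulls, so identical input and configuration produce
#' byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "titration_report"))
  body <- unclass(report)
  # refused stages: explicit nulls
  for (k in c("hh", "linearity", "delta_fit", "tautomer")) {
    if (is.null(body[[k]])) body[[k]] <- NA
  }
  if (length(body$errors) == 0) body$errors <- NULL
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.titration_report <- function(x, ...) {
  cat("<titration_report>", if (nzchar(x$compound)) x$compound else "(unnamed)",
      "\n")
  if (!is.null(x$linearity)) {
    cat(sprintf("  linearity: %d breakpoint(s)\n", x$linearity$n_breaks))
  }
  if (!is.null(x$hh)) {
    for (h in x$hh) {
      cat(sprintf("  pKa [%s] = %.3f\n", h$window %||% "full", h$pKa))
    }
  }
  if (!is.null(x$tautomer)) {
    cat(sprintf("  delta_K = %.4f (%s) -> %s, ddG = %.3f kJ/mol\n",
                x$tautomer$delta_K, x$tautomer$method,
                x$tautomer$classification, x$tautomer$delta_delta_G))
  }
  if (length(x$errors) > 0) {
    for (nm in names(x$errors)) cat("  stage error [", nm, "]: ",
                                    x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}
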