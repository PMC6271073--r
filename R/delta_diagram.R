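#' Build a delta-diagram from a titration series
#'
#' A delta-diagram is the parametric trajectory of one probe's chemical
#' shift against another's over the course of a titration. A single
#' deprotonation step traces a straight chord between the two state points;
#' multi-step or tautomerically coupled systems trace kinked or curved
#' paths. Only points where both probes are observed enter the diagram.
#'
#' @param series A [titration_series()].
#' @param probe_x,probe_y Names of the probes plotted on x and y.
#' @param start_anchor,end_anchor Optional length-2 numeric overrides
#'   `(delta_x, delta_y)` for the start/end anchor points, e.g. for a
#'   truncated titration whose final plateau was not reached. By default the
#'   anchors are the first and last included points.
#' @return An object of class `delta_diagram`: ordered points
#'   (`aliquot`, `pH`, `x`, `y`), anchors and probe names.
#' @export
build_diagram <- function(series, probe_x, probe_y,
                          start_anchor = NULL, end_anchor = NULL) {
  ox <- probe_observations(series, probe_x)
  oy <- probe_observations(series, probe_y)
  common <- intersect(ox$index, oy$index)
  if (length(common) < 3) {
    stop("degenerate diagram: fewer than 3 points carry both probes",
         call. = FALSE)
  }
  pts <- data.frame(
    aliquot = series$points$aliquot[common],
    pH = series$points$pH[common],
    x = series$points[[probe_x]][common],
    y = series$points[[probe_y]][common]
  )
  as_anchor <- function(a, default) {
    if (is.null(a)) return(default)
    stopifnot(is.numeric(a), length(a) == 2, all(is.finite(a)))
    unname(a)
  }
  structure(list(
    points = pts,
    start_anchor = as_anchor(start_anchor, c(pts$x[1], pts$y[1])),
    end_anchor = as_anchor(end_anchor,
                           c(pts$x[nrow(pts)], pts$y[nrow(pts)])),
    probe_x = probe_x, probe_y = probe_y
  ), class = "delta_diagram")
}

#' @export
print.delta_diagram <- function(x, ...) {
  cat(sprintf("<delta_diagram> %s vs %s, %d points\n", x$probe_y, x$probe_x,
              nrow(x$points)))
  cat(sprintf("  start (%.4f, %.4f)  end (%.4f, %.4f)\n",
              x$start_anchor[1], x$start_anchor[2],
              x$end_anchor[1], x$end_anchor[2]))
  invisible(x)
}

# ---- planar total-least-squares segments ------------------------------------

# principal-axis line through a point cloud: centroid + unit direction
tls_line <- function(P) {
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  list(ctr = ctr, dir = sv$v[, 1])
}

# sum of squared orthogonal distances to a tls line
tls_rss <- function(P, line) {
  Pc <- sweep(P, 2, line$ctr)
  sum((Pc[, 1] * (-line$dir[2]) + Pc[, 2] * line$dir[1])^2)
}

# piecewise-TLS fit with interior vertices at the given data indices;
# adjacent runs share the vertex point
piecewise_tls <- function(P, breaks) {
  idx <- c(1L, breaks, nrow(P))
  segs <- vector("list", length(idx) - 1L)
  rss <- 0
  for (k in seq_along(segs)) {
    run <- idx[k]:idx[k + 1L]
    ln <- tls_line(P[run, , drop = FALSE])
    rss <- rss + tls_rss(P[run, , drop = FALSE], ln)
    ln$from <- idx[k]; ln$to <- idx[k + 1L]
    segs[[k]] <- ln
  }
  list(rss = rss, segments = segs, breaks = breaks)
}

# exhaustive search over vertex positions for a given break count
best_piecewise <- function(P, n_breaks, min_seg) {
  n <- nrow(P)
  if (n_breaks == 0) return(piecewise_tls(P, integer(0)))
  best <- NULL
  if (n_breaks == 1) {
    for (i in (1L + min_seg - 1L):(n - min_seg + 1L)) {
      if (i <= 1L || i >= n) next
      fit <- piecewise_tls(P, i)
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
  } else if (n_breaks == 2) {
    for (i in 2:(n - 1L)) {
      if (i - 1L < min_seg - 1L) next
      for (j in (i + min_seg - 1L):(n - 1L)) {
        if (j <= i || j >= n || n - j < min_seg - 1L) next
        fit <- piecewise_tls(P, c(i, j))
        if (is.null(best) || fit$rss < best$rss) best <- fit
      }
    }
  } else {
    stop("at most 2 interior breakpoints are supported", call. = FALSE)
  }
  if (is.null(best)) {
    stop("too few points for ", n_breaks, " breakpoint(s)", call. = FALSE)
  }
  best
}

#' Classify the linearity of a delta-diagram
#'
#' Fits continuous piecewise-linear models (total least squares on the
#' planar trajectory, vertices restricted to data points, exhaustive vertex
#' search) with 0 to `max_breaks` interior breakpoints, and selects the
#' smallest breakpoint count whose residual sum is within a factor
#' `(1 + tol_model)` of the best model, plus an absolute resolution floor of
#' `2 * n * resolution^2` below which residual differences are considered
#' sub-digitizer and not meaningful.
#'
#' A count of 0 marks a single deprotonation step (Perrin territory), 1 a
#' two-step system with a sharp neutralization vertex, 2 a broad multi-state
#' trajectory (Polster-Lachmann territory in both latter cases).
#'
#' @param diagram A [build_diagram()] result.
#' @param max_breaks Maximum interior breakpoints considered (0..2). At
#'   least 4 points are required for 1 breakpoint and 6 for 2.
#' @param tol_model Relative residual slack for preferring fewer breakpoints
#'   (default 0.05).
#' @param resolution Shift digitization scale in ppm (default 0.002) setting
#'   the absolute residual floor.
#' @return An object of class `linearity_fit`: `n_breaks`, `breaks` (data
#'   indices), `vertices` (their coordinates and pH), `segments` of the
#'   selected model, and the residual sums `rss` of all candidate counts.
#' @export
linearity_check <- function(diagram, max_breaks = 2, tol_model = 0.05,
                            resolution = 0.002) {
  stopifnot(inherits(diagram, "delta_diagram"),
            max_breaks %in% 0:2, tol_model >= 0, resolution >= 0)
  P <- as.matrix(diagram$points[, c("x", "y")])
  n <- nrow(P)
  needed <- c(2, 4, 6)[max_breaks + 1L]
  if (n < needed) {
    stop("too few points (", n, ") for ", max_breaks, " breakpoint(s); need ",
         needed, call. = FALSE)
  }
  # prefer 3-point minimum segments when the data afford them
  fits <- vector("list", max_breaks + 1L)
  for (k in 0:max_breaks) {
    min_seg <- if (n >= 3 * (k + 1)) 3L else 2L
    fits[[k + 1L]] <- best_piecewise(P, k, min_seg)
  }
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  floor_abs <- 2 * n * resolution^2
  sel <- which(rss <= (1 + tol_model) * min(rss) + floor_abs)[1] - 1L
  chosen <- fits[[sel + 1L]]
  verts <- diagram$points[chosen$breaks, , drop = FALSE]
  structure(list(
    n_breaks = sel,
    breaks = chosen$breaks,
    vertices = verts,
    segments = chosen$segments,
    rss = stats::setNames(rss, paste0("breaks", 0:max_breaks)),
    tol_model = tol_model, resolution = resolution, n = n
  ), class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf("<linearity_fit> %d breakpoint(s) selected from rss [%s]\n",
              x$n_breaks, paste(sprintf("%.3g", x$rss), collapse = ", ")))
  if (x$n_breaks > 0) {
    cat("  vertices at pH:", paste(sprintf("%.3f", x$vertices$pH),
                                   collapse = ", "), "\n")
  }
  invisible(x)
}
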