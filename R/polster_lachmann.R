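#' Polster-Lachmann Gibbs-triangle analysis of a delta-diagram
#'
#' @description
#' For a two-step acid-base system the delta-diagram is a curve inside the
#' Gibbs triangle spanned by the three state points: A (initial state),
#' B (the neutralization vertex, i.e. the pure intermediate) and C (final
#' state). Writing a trajectory point in barycentric coordinates
#' \eqn{(b_0, b_1, b_2)} with respect to that triangle, the coordinates are
#' the species fractions, so the stepwise-constant quotient
#' \deqn{\Delta K = K_1 / K_2 = b_1^2 / (b_0 b_2)}
#' is the same at every trajectory point — a ratio of distances read from
#' the triangle, independent of the pH readings. Equivalently, the cevian
#' from A through a trajectory point BC cuts the side B--C at X with
#' \eqn{|BX|/|XC| = b_2/b_1}, and the cevian from C cuts A--B at Y with
#' \eqn{|AY|/|YB| = b_1/b_0}; the product of the two distance ratios
#' \eqn{(b_1/b_2)(b_1/b_0)} is \eqn{\Delta K}.
#'
#' A and C are the diagram anchors. B is not observed directly: the
#' trajectory with a constant quotient is exactly a conic tangent to side
#' A--B at A and to side C--B at C, so B is the intersection of the
#' trajectory's end tangents. It is estimated here by a geometric
#' least-squares fit of that constant-quotient conic, parametrized directly
#' by (B, \eqn{\Delta K}) and initialized from the piecewise-linear
#' segments of [linearity_check()] (whose first/last segment lines
#' approximate the tangents). At zero noise the fit reproduces the tangent
#' construction exactly.
#'
#' The analysis requires a usable triangle: a collinear diagram (0
#' breakpoints) is refused.
#'
#' @param diagram A [build_diagram()] result.
#' @param linearity A [linearity_check()] result for the same diagram with
#'   at least one breakpoint; computed on the fly if `NULL`.
#' @param ... Passed to [linearity_check()] when `linearity` is `NULL`.
#' @return An object of class `pl_result`: `delta_K`, the `triangle`
#'   (A, B, C and the experimental point BC nearest the detected vertex),
#'   `distance_ratio` (`|BX|/|XC|` of the A-cevian at BC), `n_used`,
#'   `rss` of the conic fit and `method`.
#' @examples
#' spec <- diprotic_system(8, 9, c(H6 = 6.90, H9 = 4.80),
#'                         c(H6 = 6.72, H9 = 4.86), c(H6 = 6.58, H9 = 4.60))
#' s <- simulate_diprotic(spec, ph_grid(8, 9), noise_spec(0, 0))
#' polster_lachmann(build_diagram(s, "H6", "H9"))  # delta_K ~ 10
#' @export
polster_lachmann <- function(diagram, linearity = NULL, ...) {
  stopifnot(inherits(diagram, "delta_diagram"))
  if (is.null(linearity)) linearity <- linearity_check(diagram, ...)
  stopifnot(inherits(linearity, "linearity_fit"))
  if (linearity$n_breaks < 1) {
    stop("degenerate triangle: the delta-diagram is collinear ",
         "(no breakpoint); use perrin_fit for single-step systems",
         call. = FALSE)
  }
  P <- as.matrix(diagram$points[, c("x", "y")])
  n <- nrow(P)
  A <- diagram$start_anchor
  C <- diagram$end_anchor
  scale <- max(diff(range(P[, 1])), diff(range(P[, 2])))

  # initial vertex: intersection of the first and last segment lines
  segs <- linearity$segments
  B0 <- line_intersection(segs[[1]], segs[[length(segs)]])
  if (is.null(B0)) B0 <- apex_heuristic(P, A, C)
  if (is.null(B0) || triangle_area(A, B0, C) < 1e-10 * scale^2) {
    stop("degenerate triangle: cannot locate the neutralization vertex ",
         "(parallel end segments)", call. = FALSE)
  }

  # dominant experimental vertex: breakpoint farthest from the chord A-C
  verts <- linearity$breaks
  chord_d <- abs(point_line_distance(P[verts, , drop = FALSE], A, C))
  bc_idx <- verts[which.max(chord_d)]
  if (bc_idx <= 1L || bc_idx >= n) {
    stop("experimental point BC coincides with an anchor", call. = FALSE)
  }
  BC <- P[bc_idx, ]
  if (sum((BC - A)^2) < (1e-9 * scale)^2 ||
      sum((BC - C)^2) < (1e-9 * scale)^2) {
    stop("experimental point BC coincides with an anchor", call. = FALSE)
  }

  dK0 <- initial_quotient(P, A, B0, C, bc_idx)
  fit <- fit_quotient_conic(P, A, C, B0, dK0)
  B <- fit$B
  if (!all(is.finite(B)) || !is.finite(fit$delta_K) || fit$delta_K <= 0 ||
      triangle_area(A, B, C) < 1e-10 * scale^2) {
    stop("degenerate triangle: conic fit did not converge to a valid ",
         "vertex", call. = FALSE)
  }

  # cevian from A through BC meets side B-C at X; |BX|/|XC| = b2/b1
  X <- ray_side_intersection(A, BC, B, C)
  distance_ratio <- if (is.null(X)) NA_real_ else {
    sqrt(sum((B - X)^2) / sum((X - C)^2))
  }

  structure(list(
    delta_K = fit$delta_K,
    triangle = list(A = A, B = B, C = C, BC = BC),
    distance_ratio = distance_ratio,
    n_used = n - 2L,
    rss = fit$rss,
    n_breaks = linearity$n_breaks,
    method = "polster-lachmann"
  ), class = "pl_result")
}

#' @export
print.pl_result <- function(x, ...) {
  cat("<pl_result>\n")
  cat(sprintf("  delta_K = %.4f   distance ratio |BX|/|XC| = %.4f   n = %d\n",
              x$delta_K, x$distance_ratio, x$n_used))
  cat(sprintf("  triangle A (%.4f, %.4f)  B (%.4f, %.4f)  C (%.4f, %.4f)\n",
              x$triangle$A[1], x$triangle$A[2], x$triangle$B[1],
              x$triangle$B[2], x$triangle$C[1], x$triangle$C[2]))
  invisible(x)
}

# ---- internal geometry ------------------------------------------------------

triangle_area <- function(A, B, C) {
  abs((B[1] - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (B[2] - A[2])) / 2
}

# signed distances of points (rows) from the line through a and b
point_line_distance <- function(P, a, b) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) return(rep(0, nrow(P)))
  ((P[, 1] - a[1]) * (-d[2]) + (P[, 2] - a[2]) * d[1]) / len
}

# intersection of two centroid+direction lines; NULL when near-parallel
line_intersection <- function(l1, l2) {
  M <- cbind(l1$dir, -l2$dir)
  if (abs(det(M)) < 1e-9) return(NULL)
  t <- solve(M, l2$ctr - l1$ctr)
  unname(l1$ctr + t[1] * l1$dir)
}

# fallback vertex start: push the point farthest from the chord outward
apex_heuristic <- function(P, A, C) {
  d <- point_line_distance(P, A, C)
  i <- which.max(abs(d))
  if (abs(d[i]) == 0) return(NULL)
  mid <- (A + C) / 2
  unname(P[i, ] + (P[i, ] - mid) * 0.6)
}

# barycentric coordinates of rows of P wrt triangle (A, B, C)
barycentric <- function(P, A, B, C) {
  M <- cbind(B - A, C - A)
  if (abs(det(M)) < .Machine$double.eps) return(NULL)
  Mi <- solve(M)
  Pc <- sweep(P, 2, A)
  b12 <- Pc %*% t(Mi)
  cbind(1 - rowSums(b12), b12)
}

initial_quotient <- function(P, A, B, C, idx) {
  b <- barycentric(P[idx, , drop = FALSE], A, B, C)
  if (is.null(b) || any(b <= 0)) return(1)
  min(max(b[2]^2 / (b[1] * b[3]), 1e-3), 1e3)
}

# intersection of the ray from `from` through `through` with line (s1, s2)
ray_side_intersection <- function(from, through, s1, s2) {
  M <- cbind(through - from, -(s2 - s1))
  if (abs(det(M)) < 1e-12) return(NULL)
  t <- solve(M, s1 - from)
  unname(s1 + t[2] * (s2 - s1))
}

# Geometric least squares of the constant-quotient conic b1^2 = dK * b0 * b2,
# parametrized by the free vertex B and log dK. Residuals are the implicit
# values normalized by their gradient magnitude in shift space (first-order
# orthogonal distances).
fit_quotient_conic <- function(P, A, C, B0, dK0) {
  interior <- P[-c(1L, nrow(P)), , drop = FALSE]
  resid <- function(par) {
    B <- par[1:2]
    dK <- exp(par[3])
    b <- barycentric(interior, A, B, C)
    if (is.null(b)) return(rep(1e3, nrow(interior)))
    Mi <- solve(cbind(B - A, C - A))
    g <- b[, 2]^2 - dK * b[, 1] * b[, 3]
    # chain rule: db1/dP = Mi[1,], db2/dP = Mi[2,], db0/dP = -(Mi[1,]+Mi[2,])
    dg0 <- -dK * b[, 3]; dg1 <- 2 * b[, 2]; dg2 <- -dK * b[, 1]
    gx <- dg0 * (-(Mi[1, 1] + Mi[2, 1])) + dg1 * Mi[1, 1] + dg2 * Mi[2, 1]
    gy <- dg0 * (-(Mi[1, 2] + Mi[2, 2])) + dg1 * Mi[1, 2] + dg2 * Mi[2, 2]
    g / pmax(sqrt(gx^2 + gy^2), 1e-12)
  }
  objective <- function(par) {
    r <- resid(par)
    if (any(!is.finite(r))) return(1e6)
    sum(r^2)
  }
  par <- c(B0, log(dK0))
  for (round in 1:2) {
    opt <- stats::optim(par, objective,
                        control = list(maxit = 5000, reltol = 1e-14))
    par <- opt$par
  }
  list(B = par[1:2], delta_K = exp(par[3]), rss = opt$value)
}
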