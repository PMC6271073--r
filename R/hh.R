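#' Convert a dissociation constant to its exponent, and back
#'
#' `ka_to_pka()` returns \eqn{-\log_{10} K_a}; `pka_to_ka()` returns
#' \eqn{10^{-pK_a}}. Both are vectorized and exact inverses of one another.
#'
#' @param Ka Positive dissociation constant(s).
#' @param pKa Finite exponent(s).
#' @return Numeric vector of the converted values.
#' @examples
#' ka_to_pka(15.1e-9)   # 7.82
#' pka_to_ka(7)         # 1e-7
#' @export
ka_to_pka <- function(Ka) {
  if (any(!is.finite(Ka)) || any(Ka <= 0)) {
    stop("Ka must be positive and finite", call. = FALSE)
  }
  -log10(Ka)
}

#' @rdname ka_to_pka
#' @export
pka_to_ka <- function(pKa) {
  if (any(!is.finite(pKa))) stop("pKa must be finite", call. = FALSE)
  10^(-pKa)
}

#' Extract limiting shifts from the titration-curve plateaus
#'
#' The limiting shifts \eqn{\delta_{min}} and \eqn{\delta_{max}} of the
#' semilogarithmic transform are estimated as the means of the first and
#' last `n_plateau` observed shifts of the probe; they are assigned to
#' min/max by value, not by titration direction. When a plateau is not flat
#' (its points spread more than `plateau_tol` of the full shift range, as
#' happens when the titration was truncated before saturation) the result
#' carries `flagged = TRUE`.
#'
#' @param series A [titration_series()].
#' @param probe Probe name.
#' @param n_plateau Points averaged at each end (default 3).
#' @param plateau_tol Relative spread above which a plateau is flagged.
#' @return An object of class `limiting_shifts` with fields `delta_min`,
#'   `delta_max`, `probe`, `n_plateau`, per-end spreads and `flagged`.
#' @export
extract_limits <- function(series, probe, n_plateau = 3, plateau_tol = 0.05) {
  stopifnot(n_plateau >= 1)
  obs <- probe_observations(series, probe)$shift
  if (length(obs) < 2 * n_plateau) {
    stop("degenerate series: need at least ", 2 * n_plateau,
         " observed points for probe ", probe, call. = FALSE)
  }
  first <- utils::head(obs, n_plateau)
  last <- utils::tail(obs, n_plateau)
  lo <- mean(first); hi <- mean(last)
  delta_min <- min(lo, hi); delta_max <- max(lo, hi)
  rng <- delta_max - delta_min
  spread_start <- diff(range(first))
  spread_end <- diff(range(last))
  flagged <- rng > 0 && max(spread_start, spread_end) > plateau_tol * rng
  structure(list(delta_min = delta_min, delta_max = delta_max, probe = probe,
                 n_plateau = as.integer(n_plateau),
                 spread_start = spread_start, spread_end = spread_end,
                 flagged = flagged),
            class = "limiting_shifts")
}

#' Semilogarithmic (Henderson-Hasselbalch) transform
#'
#' Tabulates \eqn{y = \log_{10}[(\delta_{max} - \delta_{obs}) /
#' (\delta_{obs} - \delta_{min})]} against pH. Points where either the
#' numerator or the denominator is not strictly positive (observations at or
#' beyond the limiting shifts, as occurs on the plateaus) are excluded, not
#' errors; the count of exclusions travels with the result.
#'
#' @param series A [titration_series()].
#' @param probe Probe name.
#' @param limits A `limiting_shifts` object (see [extract_limits()]), or any
#'   list with `delta_min` and `delta_max`.
#' @return A data frame of `(pH, y)` pairs with attribute `n_excluded`.
#' @export
hh_transform <- function(series, probe, limits) {
  dmin <- limits$delta_min; dmax <- limits$delta_max
  if (!is.finite(dmin) || !is.finite(dmax) || !(dmin < dmax)) {
    stop("no transition: limiting shifts are degenerate ",
         "(delta_min >= delta_max)", call. = FALSE)
  }
  obs <- probe_observations(series, probe)
  num <- dmax - obs$shift
  den <- obs$shift - dmin
  ok <- num > 0 & den > 0
  out <- data.frame(pH = obs$pH[ok], y = log10(num[ok] / den[ok]))
  if (nrow(out) < 2) {
    stop("degenerate transform: fewer than 2 points inside the limiting ",
         "shifts", call. = FALSE)
  }
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Fit a pKa from the semilogarithmic transform
#'
#' Ordinary least squares of the transformed response on pH. The pKa is the
#' pH at which the fitted line crosses zero, `-intercept/slope`; in the
#' ideal two-state case the line has slope of magnitude exactly 1 (sign set
#' by which endpoint is labelled min). A fit with `|slope| < 0.1` is refused
#' as showing no acid-base transition; `|slope|` outside `[0.8, 1.2]` sets a
#' deviation flag (non-ideal or multi-step response). The pKa standard error
#' is first-order propagation from the slope/intercept covariance.
#'
#' @param transformed A data frame of `(pH, y)` pairs from [hh_transform()].
#' @return An object of class `hh_fit` with fields `pKa`, `slope`,
#'   `intercept`, `r_squared`, `n_used`, `n_excluded`, `pKa_stderr` and
#'   `slope_deviation`.
#' @examples
#' fit_pka(data.frame(pH = c(8, 9, 10), y = c(1, 0, -1)))  # pKa = 9
#' @export
fit_pka <- function(transformed) {
  stopifnot(is.data.frame(transformed), all(c("pH", "y") %in%
                                              names(transformed)))
  n <- nrow(transformed)
  if (n < 2) stop("need at least 2 transformed points", call. = FALSE)
  if (stats::sd(transformed$pH) == 0) {
    stop("singular design: all pH values are equal", call. = FALSE)
  }
  fit <- stats::lm(y ~ pH, data = transformed)
  b <- stats::coef(fit)
  intercept <- unname(b[1]); slope <- unname(b[2])
  if (abs(slope) < 0.1) {
    stop("no transition: fitted semilog slope is ",
         sprintf("%.3g", slope), " (|slope| < 0.1)", call. = FALSE)
  }
  pKa <- -intercept / slope
  r2 <- if (n == 2) 1 else summary(fit)$r.squared
  pKa_se <- NA_real_
  if (n >= 3) {
    V <- stats::vcov(fit)
    g <- c(-1 / slope, intercept / slope^2)  # d(pKa)/d(intercept, slope)
    pKa_se <- sqrt(drop(t(g) %*% V %*% g))
  }
  structure(list(pKa = pKa, slope = slope, intercept = intercept,
                 r_squared = r2, n_used = n,
                 n_excluded = attr(transformed, "n_excluded") %||% 0L,
                 pKa_stderr = pKa_se,
                 slope_deviation = abs(slope) < 0.8 || abs(slope) > 1.2),
            class = "hh_fit")
}

#' One-call Henderson-Hasselbalch pKa fit
#'
#' Convenience wrapper: [extract_limits()], [hh_transform()] and [fit_pka()]
#' in sequence. Pass `limits` to override the plateau-derived limiting
#' shifts (e.g. with known state shifts, or for a truncated titration).
#'
#' @inheritParams extract_limits
#' @param limits Optional `limiting_shifts` override.
#' @return An `hh_fit`, with the limits used attached as field `limits`.
#' @export
fit_hh <- function(series, probe, n_plateau = 3, plateau_tol = 0.05,
                   limits = NULL) {
  if (is.null(limits)) {
    limits <- extract_limits(series, probe, n_plateau, plateau_tol)
  }
  tr <- hh_transform(series, probe, limits)
  fit <- fit_pka(tr)
  fit$limits <- limits
  fit
}

#' @export
print.hh_fit <- function(x, ...) {
  cat("<hh_fit>\n")
  cat(sprintf("  pKa = %.4f%s   slope = %.4f   R^2 = %.4f   n = %d (%d excluded)\n",
              x$pKa,
              if (is.finite(x$pKa_stderr)) sprintf(" (+/- %.4f)", x$pKa_stderr)
              else "",
              x$slope, x$r_squared, x$n_used, x$n_excluded))
  if (isTRUE(x$slope_deviation)) {
    cat("  note: |slope| deviates from 1 beyond [0.8, 1.2] (non-ideal response)\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
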