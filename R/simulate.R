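#' Synthetic titration generators
#'
#' @description
#' Generators for titration series with known ground truth under the
#' fast-exchange averaging model that the downstream analyses assume: each
#' probe resonates at the population-weighted mean of its state shifts, so
#' the observed shift is an affine function of the species fractions along
#' the pH ramp. Three system classes are covered:
#'
#' * [simulate_monoprotic()] — a single deprotonation step;
#' * [simulate_tautomeric()] — two coupled deprotonation paths (O--H and
#'   N--H) of one tautomeric system, each reported by its own probe;
#' * [simulate_diprotic()] — two sequential deprotonations with three
#'   protonation states.
#'
#' Gaussian noise is added to shifts and to the recorded pH reading (the
#' chemistry follows the true pH of the grid; only the reading is noisy).
#' A fixed seed makes the full output stream reproducible.
#'
#' @name simulate
NULL

#' Monoprotic site model
#'
#' @param pKa Acid dissociation exponent of the site; must lie inside (0, 14)
#'   so that practical pH grids can bracket it.
#' @param delta_acid Named numeric vector: probe shifts (ppm) of the fully
#'   protonated form.
#' @param delta_base Named numeric vector over the same probes: shifts of the
#'   deprotonated form.
#' @return An object of class `site_model`.
#' @examples
#' site_model(8.5, c(H6 = 6.90, H9 = 4.80), c(H6 = 6.60, H9 = 4.55))
#' @export
site_model <- function(pKa, delta_acid, delta_base) {
  stopifnot(is.numeric(pKa), length(pKa) == 1, is.finite(pKa))
  if (pKa <= 0 || pKa >= 14) {
    stop("pKa must lie in (0, 14)", call. = FALSE)
  }
  check_shift_map(delta_acid, "delta_acid")
  check_shift_map(delta_base, "delta_base")
  if (!setequal(names(delta_acid), names(delta_base))) {
    stop("delta_acid and delta_base must share the same probe set",
         call. = FALSE)
  }
  structure(list(pKa = pKa, delta_acid = delta_acid,
                 delta_base = delta_base[names(delta_acid)]),
            class = "site_model")
}

#' Coupled two-site tautomeric system
#'
#' Ground truth for a prototropic tautomer with an intramolecular
#' O...H...N hydrogen bond: deprotonation can proceed through the O--H path
#' (site constant \eqn{K_{HO}}, exponent `pKa_HO`) or the N--H path
#' (\eqn{K_{HN}}, `pKa_HN`). Each path is reported by its own probe
#' (`probe_O`, `probe_N`), taken as pure reporters of their sites. The
#' derived tautomeric quotient is
#' \eqn{\Delta K = K_{HN}/K_{HO} = 10^{pKa_{HO} - pKa_{HN}}}.
#'
#' @param pKa_HO,pKa_HN Site dissociation exponents of the O--H and N--H
#'   paths.
#' @param delta_start Named shifts (ppm) at the start of the titration; must
#'   contain `probe_O` and `probe_N`.
#' @param delta_end Named shifts at the end of the titration (same probes).
#' @param probe_O,probe_N Names of the reporter probes of the two sites.
#' @return An object of class `tautomer_system`, with the derived quotient in
#'   field `delta_K`.
#' @export
tautomer_system <- function(pKa_HO, pKa_HN, delta_start, delta_end,
                            probe_O = "H6", probe_N = "H9") {
  stopifnot(is.finite(pKa_HO), is.finite(pKa_HN))
  if (identical(probe_O, probe_N)) {
    stop("probe_O and probe_N must differ", call. = FALSE)
  }
  check_shift_map(delta_start, "delta_start")
  check_shift_map(delta_end, "delta_end")
  for (p in c(probe_O, probe_N)) {
    if (!p %in% names(delta_start) || !p %in% names(delta_end)) {
      stop("probe '", p, "' absent from delta_start/delta_end", call. = FALSE)
    }
  }
  structure(list(pKa_HO = pKa_HO, pKa_HN = pKa_HN,
                 delta_start = delta_start, delta_end = delta_end,
                 probe_O = probe_O, probe_N = probe_N,
                 delta_K = 10^(pKa_HO - pKa_HN)),
            class = "tautomer_system")
}

#' Diprotic (three-state) system
#'
#' @param pKa1,pKa2 First and second dissociation exponents; `pKa1 < pKa2`
#'   is enforced.
#' @param delta_H2A,delta_HA,delta_A Named shift vectors (ppm, same probe
#'   set) of the fully protonated, intermediate and fully deprotonated
#'   states. A probe whose three state shifts are not collinear responses of
#'   a single step acts as a three-state reporter.
#' @return An object of class `diprotic_system`.
#' @export
diprotic_system <- function(pKa1, pKa2, delta_H2A, delta_HA, delta_A) {
  stopifnot(is.finite(pKa1), is.finite(pKa2))
  if (pKa1 >= pKa2) {
    stop("pKa1 must be smaller than pKa2", call. = FALSE)
  }
  check_shift_map(delta_H2A, "delta_H2A")
  check_shift_map(delta_HA, "delta_HA")
  check_shift_map(delta_A, "delta_A")
  if (!setequal(names(delta_H2A), names(delta_HA)) ||
      !setequal(names(delta_H2A), names(delta_A))) {
    stop("the three state-shift maps must share the same probe set",
         call. = FALSE)
  }
  probes <- names(delta_H2A)
  structure(list(pKa1 = pKa1, pKa2 = pKa2, delta_H2A = delta_H2A,
                 delta_HA = delta_HA[probes], delta_A = delta_A[probes]),
            class = "diprotic_system")
}

#' Measurement-noise specification
#'
#' @param sigma_shift Standard deviation (ppm) of Gaussian noise added to
#'   every observed shift. The default, 0.002 ppm, reflects typical digital
#'   resolution of a 500 MHz spectrum.
#' @param sigma_pH Standard deviation of Gaussian noise on the recorded pH
#'   reading (the underlying chemistry follows the true grid pH).
#' @param seed Integer RNG seed fixing the full output stream, or `NULL` to
#'   draw from the current RNG state.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec()            # default measurement noise
#' noise_spec(0, 0)        # noiseless
#' @export
noise_spec <- function(sigma_shift = 0.002, sigma_pH = 0.02, seed = 1L) {
  stopifnot(sigma_shift >= 0, sigma_pH >= 0)
  structure(list(sigma_shift = sigma_shift, sigma_pH = sigma_pH,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_spec")
}

#' Default pH grid around the transitions of interest
#'
#' @param pka_lo,pka_hi Lowest and highest dissociation exponents the grid
#'   must bracket (equal for a single site).
#' @param halfwidth Units of pH extended beyond each exponent (default 2.5).
#' @param n Number of grid points (default 25).
#' @return Increasing numeric pH grid, symmetric about
#'   `(pka_lo + pka_hi) / 2`.
#' @export
ph_grid <- function(pka_lo, pka_hi = pka_lo, halfwidth = 2.5, n = 25) {
  stopifnot(pka_lo <= pka_hi, halfwidth > 0, n >= 2)
  seq(pka_lo - halfwidth, pka_hi + halfwidth, length.out = n)
}

# fraction deprotonated for a single two-state site
deprotonated_fraction <- function(pH, pKa) 1 / (1 + 10^(pKa - pH))

# evaluate code under a local, restored RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_shift_map <- function(x, what) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))) ||
      anyDuplicated(names(x)) || any(!is.finite(x))) {
    stop(what, " must be a finite numeric vector with unique, non-empty ",
         "probe names", call. = FALSE)
  }
  invisible(x)
}

# assemble the output series: first point 'initial', rest 'base'
assemble_series <- function(pH_grid, shifts, noise, compound) {
  n <- length(pH_grid)
  with_seed(noise$seed, {
    pH_obs <- pH_grid +
      if (noise$sigma_pH > 0) stats::rnorm(n, 0, noise$sigma_pH) else 0
    if (noise$sigma_shift > 0) {
      for (p in colnames(shifts)) {
        shifts[, p] <- shifts[, p] + stats::rnorm(n, 0, noise$sigma_shift)
      }
    }
    pts <- data.frame(aliquot = seq_len(n) - 1L,
                      branch = c("initial", rep("base", n - 1L)),
                      pH = pH_obs, stringsAsFactors = FALSE)
    for (p in colnames(shifts)) pts[[p]] <- shifts[, p]
    titration_series(pts, compound = compound)
  })
}

#' Simulate a monoprotic titration
#'
#' At each grid pH the deprotonated fraction is
#' \eqn{f = 1 / (1 + 10^{pKa - pH})} and every probe resonates at
#' `delta_acid + f * (delta_base - delta_acid)` (fast exchange). The first
#' point is tagged `initial`, the rest `base`.
#'
#' @param site A [site_model()].
#' @param pH_grid Increasing pH values (at least 2).
#' @param noise A [noise_spec()].
#' @return A [titration_series()] with one shift column per probe of `site`.
#' @examples
#' s <- simulate_monoprotic(
#'   site_model(8.5, c(H9 = 4.80), c(H9 = 4.55)),
#'   ph_grid(8.5), noise_spec(0, 0))
#' fit_hh(s, "H9")
#' @export
simulate_monoprotic <- function(site, pH_grid, noise = noise_spec()) {
  stopifnot(inherits(site, "site_model"), inherits(noise, "noise_spec"))
  if (length(pH_grid) < 2) {
    stop("pH_grid must contain at least 2 values", call. = FALSE)
  }
  f <- deprotonated_fraction(pH_grid, site$pKa)
  probes <- names(site$delta_acid)
  shifts <- vapply(probes, function(p) {
    site$delta_acid[[p]] + f * (site$delta_base[[p]] - site$delta_acid[[p]])
  }, numeric(length(pH_grid)))
  dim(shifts) <- c(length(pH_grid), length(probes))
  colnames(shifts) <- probes
  assemble_series(pH_grid, shifts, noise,
                  sprintf("synthetic monoprotic pKa=%g", site$pKa))
}

#' Simulate a coupled tautomeric titration
#'
#' Each reporter probe follows two-state averaging governed by its own site
#' exponent: `probe_O` by `pKa_HO`, `probe_N` by `pKa_HN`, between the
#' matching `delta_start` and `delta_end` entries. By construction the
#' noiseless trajectory satisfies the Perrin bilinear identity exactly, with
#' slope equal to the site-constant quotient
#' \eqn{K_{HN}/K_{HO} = 10^{pKa_{HO} - pKa_{HN}}}.
#'
#' @param spec A [tautomer_system()].
#' @param pH_grid Increasing pH values (at least 2); for reliable recovery it
#'   should bracket both site exponents by at least one unit.
#' @param noise A [noise_spec()].
#' @return A [titration_series()] carrying the two reporter probes.
#' @export
simulate_tautomeric <- function(spec, pH_grid, noise = noise_spec()) {
  stopifnot(inherits(spec, "tautomer_system"), inherits(noise, "noise_spec"))
  if (length(pH_grid) < 2) {
    stop("pH_grid must contain at least 2 values", call. = FALSE)
  }
  fO <- deprotonated_fraction(pH_grid, spec$pKa_HO)
  fN <- deprotonated_fraction(pH_grid, spec$pKa_HN)
  pO <- spec$probe_O; pN <- spec$probe_N
  shifts <- cbind(
    spec$delta_start[[pO]] + fO * (spec$delta_end[[pO]] - spec$delta_start[[pO]]),
    spec$delta_start[[pN]] + fN * (spec$delta_end[[pN]] - spec$delta_start[[pN]])
  )
  colnames(shifts) <- c(pO, pN)
  assemble_series(pH_grid, shifts, noise,
                  sprintf("synthetic tautomer pKa_HO=%g pKa_HN=%g",
                          spec$pKa_HO, spec$pKa_HN))
}

#' Simulate a diprotic titration
#'
#' State populations follow the partition
#' \eqn{1 : K_1/[H^+] : K_1 K_2 / [H^+]^2} for H2A, HA and A; each probe
#' resonates at the population-weighted mean of its three state shifts.
#'
#' @param spec A [diprotic_system()].
#' @param pH_grid Increasing pH values spanning both exponents.
#' @param noise A [noise_spec()].
#' @return A [titration_series()].
#' @export
simulate_diprotic <- function(spec, pH_grid, noise = noise_spec()) {
  stopifnot(inherits(spec, "diprotic_system"), inherits(noise, "noise_spec"))
  if (length(pH_grid) < 2) {
    stop("pH_grid must contain at least 2 values", call. = FALSE)
  }
  fr <- diprotic_fractions(pH_grid, spec$pKa1, spec$pKa2)
  probes <- names(spec$delta_H2A)
  shifts <- vapply(probes, function(p) {
    fr[, 1] * spec$delta_H2A[[p]] + fr[, 2] * spec$delta_HA[[p]] +
      fr[, 3] * spec$delta_A[[p]]
  }, numeric(length(pH_grid)))
  dim(shifts) <- c(length(pH_grid), length(probes))
  colnames(shifts) <- probes
  assemble_series(pH_grid, shifts, noise,
                  sprintf("synthetic diprotic pKa1=%g pKa2=%g",
                          spec$pKa1, spec$pKa2))
}

# population fractions (H2A, HA, A) of a diprotic acid
diprotic_fractions <- function(pH, pKa1, pKa2) {
  h <- 10^(-pH)
  w1 <- 10^(-pKa1) / h
  w2 <- 10^(-pKa1 - pKa2) / h^2
  tot <- 1 + w1 + w2
  cbind(1 / tot, w1 / tot, w2 / tot)
}
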