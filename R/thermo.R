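#' Thermodynamic constants
#'
#' @param temperature Temperature in kelvin (default 296.15 K, the
#'   titration temperature of the reference data set).
#' @param gas_constant Gas constant in J mol^-1 K^-1.
#' @return An object of class `thermo_constants`.
#' @export
thermo_constants <- function(temperature = 296.15, gas_constant = 8.314) {
  stopifnot(is.finite(temperature), temperature > 0,
            is.finite(gas_constant), gas_constant > 0)
  structure(list(T = temperature, R = gas_constant),
            class = "thermo_constants")
}

#' Tautomeric quotient to delta-pK
#'
#' \eqn{\Delta pK = -\log_{10} \Delta K}. The sign convention follows the
#' tabulated usage for NHO tautomers: a quotient above 1 (proton
#' predominantly on nitrogen) gives a negative \eqn{\Delta pK}.
#'
#' @param delta_K Positive tautomeric quotient(s).
#' @return Numeric vector.
#' @examples
#' delta_pk(1.031)  # -0.0133
#' @export
delta_pk <- function(delta_K) {
  if (any(!is.finite(delta_K)) || any(delta_K <= 0)) {
    stop("delta_K must be positive and finite", call. = FALSE)
  }
  -log10(delta_K)
}

#' Tautomeric quotient to standard Gibbs free-energy difference
#'
#' \eqn{\Delta\Delta G^\circ = -RT \ln \Delta K}, in kJ mol^-1, the free
#' energy difference between the two tautomers of the intramolecular
#' hydrogen bond.
#'
#' @param delta_K Positive tautomeric quotient(s).
#' @param constants A [thermo_constants()].
#' @return Numeric vector, kJ mol^-1.
#' @examples
#' delta_g(0.841)  # +0.426 kJ/mol at 296.15 K
#' @export
delta_g <- function(delta_K, constants = thermo_constants()) {
  if (any(!is.finite(delta_K)) || any(delta_K <= 0)) {
    stop("delta_K must be positive and finite", call. = FALSE)
  }
  stopifnot(inherits(constants, "thermo_constants"))
  -constants$R * constants$T * log(delta_K) / 1000
}

#' Classify the proton position of an NHO tautomer
#'
#' A quotient above 1 places the labile proton predominantly on the
#' nitrogen atom (zwitterionic \eqn{^{+}}N--H...O\eqn{^{-}} form), below 1
#' on the oxygen atom (neutral N...H--O form), and exactly 1 denotes a
#' shared proton (N...H...O). Quotients within
#' `max(tol_unity, 2 * stderr)` of 1 additionally set the `near_unity`
#' flag: the proton sits near the middle of the bridge and the sign of the
#' displacement is not resolved.
#'
#' @param delta_K Positive quotient.
#' @param stderr Optional standard error of `delta_K`.
#' @param tol_unity Minimum half-width of the near-unity band.
#' @return A list with `classification` (one of `"proton-on-N"`,
#'   `"proton-on-O"`, `"shared"`) and logical `near_unity`.
#' @examples
#' classify_tautomer(1.04)   # proton-on-N
#' classify_tautomer(0.841)  # proton-on-O
#' @export
classify_tautomer <- function(delta_K, stderr = NULL, tol_unity = 0.005) {
  if (!is.finite(delta_K) || delta_K <= 0) {
    stop("delta_K must be positive and finite", call. = FALSE)
  }
  classification <- if (delta_K > 1) "proton-on-N"
  else if (delta_K < 1) "proton-on-O"
  else "shared"
  band <- max(tol_unity,
              if (!is.null(stderr) && is.finite(stderr)) 2 * stderr else 0)
  list(classification = classification,
       near_unity = abs(delta_K - 1) <= band)
}

#' Assemble the thermodynamic result for a tautomeric quotient
#'
#' @param delta_K Positive quotient, from [perrin_fit()] or
#'   [polster_lachmann()].
#' @param stderr Optional standard error of the quotient.
#' @param method Label of the method that produced `delta_K`.
#' @param constants A [thermo_constants()].
#' @param tol_unity Near-unity band half-width.
#' @return An object of class `tautomer_result` with `delta_K`, `stderr`,
#'   `delta_pK`, `delta_delta_G` (kJ mol^-1), `classification`,
#'   `near_unity`, `method` and the sign convention used.
#' @export
tautomer_result <- function(delta_K, stderr = NULL,
                            method = c("perrin", "polster-lachmann"),
                            constants = thermo_constants(),
                            tol_unity = 0.005) {
  method <- match.arg(method)
  cls <- classify_tautomer(delta_K, stderr, tol_unity)
  structure(list(
    delta_K = delta_K,
    stderr = if (is.null(stderr)) NA_real_ else stderr,
    delta_pK = delta_pk(delta_K),
    delta_delta_G = delta_g(delta_K, constants),
    classification = cls$classification,
    near_unity = cls$near_unity,
    method = method,
    temperature = constants$T,
    sign_convention = "delta_pK = -log10(delta_K); delta_delta_G = -RT ln(delta_K)"
  ), class = "tautomer_result")
}

#' @export
print.tautomer_result <- function(x, ...) {
  cat("<tautomer_result>", x$method, "\n")
  cat(sprintf("  delta_K = %.4f%s   delta_pK = %.4f   ddG = %.3f kJ/mol (%.2f K)\n",
              x$delta_K,
              if (is.finite(x$stderr)) sprintf(" (+/- %.4f)", x$stderr) else "",
              x$delta_pK, x$delta_delta_G, x$temperature))
  cat("  proton position:", x$classification,
      if (isTRUE(x$near_unity)) "(near unity: effectively shared)" else "",
      "\n")
  invisible(x)
}
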