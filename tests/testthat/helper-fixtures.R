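# Shared synthetic fixtures. State shifts are typical aromatic (H5/H6) and
# benzylic (H9) proton positions with deprotonation responses of 0.2-0.3 ppm.

no_noise <- function() noise_spec(0, 0)

mono_site <- function(pKa = 8.5) {
  site_model(pKa,
             delta_acid = c(H6 = 6.90, H9 = 4.80),
             delta_base = c(H6 = 6.60, H9 = 4.55))
}

mono_series <- function(pKa = 8.5, halfwidth = 2.5, n = 25,
                        noise = no_noise()) {
  simulate_monoprotic(mono_site(pKa), ph_grid(pKa, halfwidth = halfwidth,
                                              n = n), noise)
}

taut_spec <- function(pKa_HO = 8.0, pKa_HN = 8.3) {
  tautomer_system(pKa_HO, pKa_HN,
                  delta_start = c(H6 = 6.90, H9 = 4.80),
                  delta_end = c(H6 = 6.60, H9 = 4.55))
}

taut_series <- function(pKa_HO = 8.0, pKa_HN = 8.3, n = 25,
                        noise = no_noise()) {
  spec <- taut_spec(pKa_HO, pKa_HN)
  simulate_tautomeric(spec, ph_grid(min(pKa_HO, pKa_HN),
                                    max(pKa_HO, pKa_HN), n = n), noise)
}

# sharp-corner two-step system (H6, H9 both two-state-ish reporters)
dip_spec <- function(pKa1 = 8, pKa2 = 10) {
  diprotic_system(pKa1, pKa2,
                  delta_H2A = c(H6 = 6.90, H9 = 4.80),
                  delta_HA  = c(H6 = 6.72, H9 = 4.72),
                  delta_A   = c(H6 = 6.58, H9 = 4.60))
}

# delta-diagram of a tautomeric series anchored at the species shifts
# (the bilinear transform's endpoint symbols refer to the pure species)
taut_diagram <- function(s, spec, x = "H6", y = "H9") {
  build_diagram(s, x, y,
                start_anchor = unname(spec$delta_start[c(x, y)]),
                end_anchor = unname(spec$delta_end[c(x, y)]))
}

dip_series <- function(pKa1 = 8, pKa2 = 10, n = 25, noise = no_noise()) {
  simulate_diprotic(dip_spec(pKa1, pKa2), ph_grid(pKa1, pKa2, n = n), noise)
}

# close-pKa three-state reporter pair (broad arc in the delta-diagram)
three_state_spec <- function() {
  diprotic_system(9.7, 9.8,
                  delta_H2A = c(H6 = 6.68, H5 = 6.95),
                  delta_HA  = c(H6 = 6.60, H5 = 6.70),
                  delta_A   = c(H6 = 6.40, H5 = 6.62))
}

three_state_series <- function(n = 25, noise = no_noise()) {
  simulate_diprotic(three_state_spec(), ph_grid(9.7, 9.8, n = n), noise)
}

# hand-built series for IO tests
small_series <- function() {
  titration_series(data.frame(
    aliquot = 0:4,
    branch = c("initial", "base", "base", "base", "base"),
    pH = c(6.0, 7.5, 8.5, 9.5, 11.0),
    H6 = c(6.9000, 6.8712, 6.7501, 6.6305, 6.6012),
    H9 = c(4.8001, 4.7761, NA, 4.5754, 4.5512)
  ), compound = "demo")
}
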