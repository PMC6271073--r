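test_that("Ka/pKa conversions match tabulated weak-acid values", {
  # printed dissociation constants of the nitro and bromo derivatives
  expect_equal(round(ka_to_pka(15.1e-9), 1), 7.8)
  expect_equal(round(ka_to_pka(1.44e-9), 1), 8.8)
  expect_equal(ka_to_pka(1e-7), 7.0)
  expect_equal(pka_to_ka(7.0), 1e-7)
  expect_equal(pka_to_ka(0), 1)
  x <- 10^seq(-10, -4)
  expect_equal(pka_to_ka(ka_to_pka(x)), x, tolerance = 1e-12)
  expect_error(ka_to_pka(0), "positive")
  expect_error(ka_to_pka(-1), "positive")
})

test_that("limiting shifts come from the plateau means", {
  s <- mono_series(8.5, halfwidth = 3.5)
  site <- mono_site(8.5)
  lim <- extract_limits(s, "H9", n_plateau = 3)
  rng <- abs(site$delta_base[["H9"]] - site$delta_acid[["H9"]])
  expect_lt(abs(lim$delta_min - site$delta_base[["H9"]]), 1e-3 * rng)
  expect_lt(abs(lim$delta_max - site$delta_acid[["H9"]]), 1e-3 * rng)
  expect_true(lim$delta_min < lim$delta_max)
  expect_false(lim$flagged)
})

test_that("a truncated titration flags the unreached plateau", {
  pKa <- 8.5
  grid <- seq(pKa - 3, pKa + 0.5, length.out = 15)  # basic side truncated
  s <- simulate_monoprotic(mono_site(pKa), grid, no_noise())
  lim <- extract_limits(s, "H9", n_plateau = 3)
  expect_true(lim$flagged)
  # the basic-end limit is biased toward the midpoint
  expect_gt(lim$delta_min, mono_site(pKa)$delta_base[["H9"]] + 0.01)
})

test_that("constant-shift series yields degenerate limits refused downstream", {
  pts <- data.frame(aliquot = 0:6, branch = c("initial", rep("base", 6)),
                    pH = seq(6, 12, 1), H9 = rep(4.7, 7))
  s <- titration_series(pts)
  lim <- extract_limits(s, "H9", n_plateau = 3)
  expect_equal(lim$delta_min, lim$delta_max)
  expect_error(hh_transform(s, "H9", lim), "no transition")
})

test_that("the semilog transform is the exact two-state line", {
  pKa <- 8.5
  s <- mono_series(pKa)
  site <- mono_site(pKa)
  for (p in c("H6", "H9")) {
    lim <- list(delta_min = min(site$delta_acid[[p]], site$delta_base[[p]]),
                delta_max = max(site$delta_acid[[p]], site$delta_base[[p]]))
    tr <- hh_transform(s, p, lim)
    # y = pH - pKa exactly (delta decreases with deprotonation for both
    # probes, so delta_max is the acid-form shift)
    expect_equal(tr$y, tr$pH - pKa, tolerance = 1e-9)
  }
})

test_that("midway observation transforms to zero and endpoints are excluded", {
  pts <- data.frame(aliquot = 0:3, branch = c("initial", rep("base", 3)),
                    pH = c(7, 8.5, 9.5, 10),
                    H9 = c(4.80, 4.675, 4.60, 4.55))
  s <- titration_series(pts)
  lim <- list(delta_min = 4.55, delta_max = 4.80)
  tr <- hh_transform(s, "H9", lim)
  expect_equal(nrow(tr), 2)  # both endpoint observations excluded
  expect_equal(attr(tr, "n_excluded"), 2L)
  expect_equal(tr$y[tr$pH == 8.5], 0)
})

test_that("fit_pka reads the pKa at the zero crossing", {
  fit <- fit_pka(data.frame(pH = c(8, 9, 10), y = c(1, 0, -1)))
  expect_equal(fit$pKa, 9.0)
  expect_equal(fit$slope, -1)
  expect_equal(fit$r_squared, 1)

  # with plateau-derived limits on a symmetric grid the pKa is exact
  s <- mono_series(8.5)
  fit2 <- fit_hh(s, "H9")
  expect_lt(abs(fit2$pKa - 8.5), 1e-6)
  # with the true species shifts as limits the line has unit slope too
  site <- mono_site(8.5)
  lim <- list(delta_min = site$delta_base[["H9"]],
              delta_max = site$delta_acid[["H9"]])
  fit3 <- fit_hh(s, "H9", limits = lim)
  expect_lt(abs(fit3$pKa - 8.5), 1e-6)
  expect_lt(abs(fit3$slope - 1), 1e-6)
  expect_false(fit3$slope_deviation)
})

test_that("fit is invariant under swapping the min/max labels", {
  s <- mono_series(8.5)
  site <- mono_site(8.5)
  fit <- fit_hh(s, "H9")
  # mirroring the response swaps which endpoint is the min: same pKa,
  # flipped slope sign
  mirrored <- s
  for (p in s$probes) {
    mirrored$points[[p]] <- site$delta_acid[[p]] + site$delta_base[[p]] -
      s$points[[p]]
  }
  fit_m <- fit_hh(mirrored, "H9")
  expect_equal(fit_m$pKa, fit$pKa, tolerance = 1e-9)
  expect_equal(fit_m$slope, -fit$slope, tolerance = 1e-9)
})

test_that("degenerate and transitionless fits are refused", {
  expect_error(fit_pka(data.frame(pH = c(8, 8, 8), y = c(1, 0, -1))),
               "singular")
  expect_error(fit_pka(data.frame(pH = c(7, 8, 9), y = c(0.01, 0, -0.01))),
               "no transition")
  expect_error(fit_pka(data.frame(pH = 8, y = 0)), "at least 2")
})

test_that("noisy replicates recover the pKa with small mean absolute error", {
  errs <- vapply(1:200, function(seed) {
    s <- mono_series(8.5, noise = noise_spec(0.002, 0.02, seed = seed))
    fit_hh(s, "H9")$pKa - 8.5
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.05)
})

test_that("no single interior point dominates the noisy fit", {
  s <- mono_series(8.5, noise = noise_spec(0.002, 0.02, seed = 7))
  lim <- extract_limits(s, "H9")
  tr <- hh_transform(s, "H9", lim)
  full <- fit_pka(tr)
  interior <- 2:(nrow(tr) - 1)
  for (i in interior) {
    drop1 <- fit_pka(tr[-i, ])
    expect_lt(abs(drop1$pKa - full$pKa), full$pKa_stderr)
  }
})
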