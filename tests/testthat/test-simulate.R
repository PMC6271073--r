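test_that("monoprotic generator reproduces the two-state averaging law", {
  site <- mono_site(8.5)
  s <- simulate_monoprotic(site, c(3.5, 8.5, 13.5), no_noise())
  rng <- site$delta_base - site$delta_acid
  # pH = pKa: exactly midway
  expect_equal(s$points$H6[2], site$delta_acid[["H6"]] + rng[["H6"]] / 2)
  expect_equal(s$points$H9[2], site$delta_acid[["H9"]] + rng[["H9"]] / 2)
  # pH = pKa - 5: at the acid endpoint within 1e-5 of the step
  expect_lt(abs(s$points$H6[1] - site$delta_acid[["H6"]]),
            1e-5 * abs(rng[["H6"]]))
  expect_lt(abs(s$points$H6[3] - site$delta_base[["H6"]]),
            1e-5 * abs(rng[["H6"]]))
  # branch tags
  expect_equal(s$points$branch, c("initial", "base", "base"))
})

test_that("generator and HH estimator close the loop at zero noise", {
  s <- simulate_monoprotic(mono_site(8.5), seq(6.5, 10.5, by = 0.25),
                           no_noise())
  fit <- fit_hh(s, "H9")
  expect_lt(abs(fit$pKa - 8.5), 1e-6)
})

test_that("tautomeric generator satisfies the bilinear identity point-wise", {
  spec <- taut_spec(8.0, 8.3)
  s <- simulate_tautomeric(spec, ph_grid(8.0, 8.3), no_noise())
  d <- taut_diagram(s, spec)
  a <- d$start_anchor; e <- d$end_anchor
  u <- (d$points$x - a[1]) * (e[2] - d$points$y)
  v <- (d$points$y - a[2]) * (e[1] - d$points$x)
  expect_true(all(abs(v - spec$delta_K * u) < 1e-12))
})

test_that("equal site constants collapse the delta-diagram to a line", {
  s <- taut_series(8.2, 8.2)
  d <- build_diagram(s, "H6", "H9")
  dev <- abs((d$points$x - d$start_anchor[1]) *
               (d$end_anchor[2] - d$start_anchor[2]) -
             (d$points$y - d$start_anchor[2]) *
               (d$end_anchor[1] - d$start_anchor[1]))
  expect_true(all(dev < 1e-10))
})

test_that("diprotic fractions drive the three-state average", {
  spec <- dip_spec(8, 12)  # wide separation
  s <- simulate_diprotic(spec, c(3.0, 10.0, 17.0), no_noise())
  rngs <- abs(spec$delta_A - spec$delta_H2A)
  # 5 units below pKa1: pure H2A
  expect_lt(abs(s$points$H6[1] - spec$delta_H2A[["H6"]]), 1e-5 * rngs[["H6"]])
  # midpoint with separation 4: pure intermediate within 1e-2 of range
  expect_lt(abs(s$points$H6[2] - spec$delta_HA[["H6"]]), 1e-2 * rngs[["H6"]])
  expect_lt(abs(s$points$H9[2] - spec$delta_HA[["H9"]]), 1e-2 * rngs[["H9"]])
  # 5 units above pKa2: pure A
  expect_lt(abs(s$points$H6[3] - spec$delta_A[["H6"]]), 1e-5 * rngs[["H6"]])
})

test_that("generated shifts stay inside the state-shift envelope (zero noise)", {
  for (pKa in c(5.5, 8.5, 11)) {
    s <- mono_series(pKa)
    site <- mono_site(pKa)
    for (p in s$probes) {
      lo <- min(site$delta_acid[[p]], site$delta_base[[p]])
      hi <- max(site$delta_acid[[p]], site$delta_base[[p]])
      expect_true(all(s$points[[p]] >= lo - 1e-12 &
                        s$points[[p]] <= hi + 1e-12))
      # monotone grid + monotone endpoints => monotone shifts
      expect_true(all(diff(s$points[[p]]) <= 1e-12))
    }
  }
  s <- dip_series(8, 10)
  spec <- dip_spec(8, 10)
  for (p in s$probes) {
    lo <- min(spec$delta_H2A[[p]], spec$delta_HA[[p]], spec$delta_A[[p]])
    hi <- max(spec$delta_H2A[[p]], spec$delta_HA[[p]], spec$delta_A[[p]])
    expect_true(all(s$points[[p]] >= lo - 1e-12 &
                      s$points[[p]] <= hi + 1e-12))
  }
})

test_that("a fixed seed makes output reproducible and restores the RNG", {
  n1 <- noise_spec(0.002, 0.02, seed = 42)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  s1 <- simulate_monoprotic(mono_site(), ph_grid(8.5), n1)
  after <- runif(1)
  expect_identical(before, after)  # generator does not consume the stream
  s2 <- simulate_monoprotic(mono_site(), ph_grid(8.5), n1)
  expect_identical(s1$points, s2$points)
  s3 <- simulate_monoprotic(mono_site(), ph_grid(8.5),
                            noise_spec(0.002, 0.02, seed = 43))
  expect_false(identical(s1$points, s3$points))
})

test_that("generator argument errors are raised", {
  expect_error(simulate_monoprotic(mono_site(), c(7), no_noise()),
               "at least 2")
  expect_error(diprotic_system(9, 8, c(H6 = 1), c(H6 = 2), c(H6 = 3)),
               "smaller")
  expect_error(site_model(15, c(H6 = 1), c(H6 = 2)), "0, 14")
  expect_error(tautomer_system(8, 8.3, c(H6 = 1), c(H6 = 2),
                               probe_O = "H6", probe_N = "H9"),
               "absent")
  expect_error(tautomer_system(8, 8.3, c(H6 = 1, H9 = 2),
                               c(H6 = 2, H9 = 3),
                               probe_O = "H6", probe_N = "H6"),
               "differ")
})
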