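test_that("a small CSV parses into a validated series", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("aliquot,branch,pH,H6,H9",
               "0,initial,6.10,6.90,4.80",
               "1,base,8.00,6.75,4.68",
               "2,base,9.90,6.61,"), f)
  s <- read_titration_csv(f, compound = "x")
  expect_s3_class(s, "titration_series")
  expect_equal(n_points(s), 3)
  expect_equal(s$probes, c("H6", "H9"))
  expect_true(is.na(s$points$H9[3]))
  expect_equal(s$points$pH, c(6.10, 8.00, 9.90))
})

test_that("write then read is the identity, and rewriting is byte-stable", {
  s <- small_series()
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(s, f1)
  expect_length(readLines(f1), 6)  # header + 5 points
  # missing H9 (the last column) at point 3 leaves an empty trailing cell
  expect_match(readLines(f1)[4], ",$")
  s2 <- read_titration_csv(f1, compound = s$compound)
  expect_equal(s2$points, s$points)
  expect_equal(s2$probes, s$probes)
  expect_equal(s2$compound, s$compound)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(s2, f2)
  expect_identical(readLines(f2), readLines(f1))
})

test_that("full shift precision survives a round trip", {
  pts <- data.frame(aliquot = 0:1, branch = c("initial", "base"),
                    pH = c(6.123456789012, 9.5),
                    H9 = c(4.801234567891, 4.5512345678912))
  s <- titration_series(pts)
  f <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(s, f)
  s2 <- read_titration_csv(f)
  expect_equal(s2$points$H9, pts$H9, tolerance = 1e-14)
  expect_equal(s2$points$pH, pts$pH, tolerance = 1e-14)
})

test_that("malformed tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("aliquot,branch,H6", "0,initial,6.9"), f)
  expect_error(read_titration_csv(f), "pH")

  writeLines(c("aliquot,branch,pH,H6",
               "0,initial,abc,6.9",
               "1,base,8.0,6.8"), f)
  expect_error(read_titration_csv(f), "row 2")

  writeLines(c("aliquot,branch,pH,H6",
               "0,initial,6.1,6.9",
               "1,base,8.0,6.8",
               "2,base,9.0,6,7"), f)  # extra field makes H6 land wrong
  expect_error(read_titration_csv(f))

  writeLines(c("aliquot,branch,pH,H6",
               "0,initial,6.1,6.9",
               "0,base,8.0,6.8"), f)
  expect_error(read_titration_csv(f), "strictly increasing")

  writeLines(c("aliquot,branch,pH,H6",
               "0,initial,6.1,6.9",
               "1,bose,8.0,6.8"), f)
  expect_error(read_titration_csv(f), "branch")
})

test_that("series invariants are enforced by the constructor", {
  pts <- data.frame(aliquot = 0:1, branch = c("base", "initial"),
                    pH = c(6, 7), H6 = c(6.9, 6.8))
  expect_error(titration_series(pts), "first")
  pts$branch <- c("initial", "initial")
  expect_error(titration_series(pts), "at most one")
  pts$branch <- c("initial", "base"); pts$pH <- c(6, Inf)
  expect_error(titration_series(pts), "pH")
})

test_that("select_branch keeps requested branches in order", {
  pts <- data.frame(
    aliquot = 0:17,
    branch = c("initial", rep("acid", 5), rep("base", 12)),
    pH = c(6.5, seq(6.0, 4.0, length.out = 5), seq(7, 11, length.out = 12)),
    H9 = seq(4.80, 4.55, length.out = 18)
  )
  s <- titration_series(pts)
  base_side <- select_branch(s, c("initial", "base"))
  expect_equal(n_points(base_side), 13)
  expect_equal(base_side$points$branch[1], "initial")
  expect_equal(base_side$points$aliquot,
               pts$aliquot[pts$branch != "acid"])

  all_tags <- select_branch(s, c("initial", "acid", "base"))
  expect_equal(all_tags$points, s$points)
})

test_that("empty branch selection warns and flags a degenerate series", {
  pts <- data.frame(aliquot = 0:2, branch = rep("base", 3),
                    pH = c(7, 8, 9), H9 = c(4.8, 4.7, 4.6))
  s <- titration_series(pts)
  expect_warning(out <- select_branch(s, "acid"), "fewer than 2")
  expect_equal(n_points(out), 0)
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_error(select_branch(s, character(0)), "empty")
})

test_that("select_branch is idempotent and intersects under composition", {
  pts <- data.frame(
    aliquot = 0:9,
    branch = c("initial", rep("acid", 3), rep("base", 6)),
    pH = c(6.5, 6:4, 7:12), H9 = seq(4.8, 4.5, length.out = 10)
  )
  s <- titration_series(pts)
  once <- select_branch(s, c("initial", "base"))
  twice <- select_branch(once, c("initial", "base"))
  expect_equal(twice$points, once$points)
  # composition = intersection of branch sets
  ab <- select_branch(select_branch(s, c("initial", "base", "acid")),
                      c("initial", "base"))
  expect_equal(ab$points, once$points)
})
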