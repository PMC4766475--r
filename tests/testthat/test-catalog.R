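unit_dir <- function(v) v / sqrt(sum(v^2))

test_that("A1 is the zero-mean ramp with accelerating orientation for +", {
  expect_equal(make_a1(5, "+")$direction, unit_dir(c(2, 1, 0, -1, -2)))
  expect_equal(make_a1(5, "-")$direction, -make_a1(5, "+")$direction)
  expect_equal(make_a1(2, "+")$direction, unit_dir(c(1, -1)))
  expect_equal(make_a1(4, "+")$direction, unit_dir(c(3, 1, -1, -3)))
  expect_error(make_a1(1), "N >= 2")
})

test_that("A2 is the sampled full-period sinusoid", {
  a2 <- make_a2(5, "+")
  expect_equal(a2$direction,
               unit_dir(sin(2 * pi * (0:4) / 5)), tolerance = 1e-12)
  expect_lt(abs(sum(a2$direction)), 1e-12)
  expect_equal(make_a2(4, "+")$direction, unit_dir(c(0, 1, 0, -1)),
               tolerance = 1e-12)
  for (N in c(3, 5, 8))
    expect_equal(make_a2(N, "-")$direction, -make_a2(N, "+")$direction)
  # zero-sum holds for any phase over a full period
  expect_lt(abs(sum(make_a2(7, "+", phase = 0.61)$direction)), 1e-12)
  expect_error(make_a2(2), "N >= 3")
})

test_that("B1 is a premature beat followed by a compensatory pause", {
  expect_equal(make_b1(5)$direction, unit_dir(c(0, 0, -1, 1, 0)))
  expect_equal(make_b1(5, position = 1)$direction,
               unit_dir(c(0, -1, 1, 0, 0)))
  expect_equal(make_b1(4, position = 1)$direction, unit_dir(c(0, -1, 1, 0)))
  expect_true(make_b1(5)$terminated)
  expect_error(make_b1(5, position = 3), "position")
  edge <- make_b1(5, variant = "edge")
  expect_equal(edge$direction, unit_dir(c(1, 0, 0, 0, -1)))
  expect_false("B1_edge" %in% names(default_catalog(5)))
})

test_that("B2 family is pause + proportional run + terminating beat", {
  b2 <- make_b2(6)
  expect_equal(b2$direction, unit_dir(c(4, -1, -1, -1, -1, 0)))
  expect_identical(b2$name, "B2")
  expect_equal(b2$family_index, 4L)
  expect_equal(make_b2_family(2)$direction, unit_dir(c(2, -1, -1, 0)))
  for (m in 2:8) {
    ln <- make_b2_family(m)
    expect_lt(abs(sum(ln$direction)), 1e-12)
    expect_identical(ln$direction[m + 2], 0)
  }
  expect_error(make_b2_family(1), "m >= 2")
  fr <- make_b2_fragment(1)
  expect_equal(fr$direction, unit_dir(c(4, -1, -1, -1, -1)))
  expect_false(fr$compensated)
})

test_that("B3 and shadow families are compensated and pairwise non-parallel", {
  expect_equal(make_b3(4, 2)$direction, unit_dir(c(-1, -1, 4, -1, -1, 0)))
  for (m in c(3, 4, 6)) {
    fam <- lapply(1:m, function(i) make_b3(m, i)$direction)
    sh <- lapply(1:m, function(i) make_shadow(m, i)$direction)
    for (v in c(fam, sh)) expect_lt(abs(sum(v)), 1e-12)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        expect_lt(abs(oracle_cos(fam[[i]], fam[[j]])), 1 - 1e-6)
        expect_lt(abs(oracle_cos(sh[[i]], sh[[j]])), 1 - 1e-6)
      }
      expect_lt(abs(oracle_cos(fam[[i]], sh[[i]])), 1 - 1e-6)
    }
  }
  expect_error(make_b3(4, 0), "position")
  expect_error(make_shadow(4, 5), "offset")
})

test_that("unit normalization is idempotent and enforced", {
  ln <- make_a1(5, "+")
  again <- arrhythmia_line(ln$name, ln$direction, compensated = TRUE)
  expect_equal(again$direction, ln$direction)
  expect_error(arrhythmia_line("bad", c(1, 1), compensated = TRUE),
               "compensated")
  expect_error(arrhythmia_line("bad", c(1, -2), terminated = TRUE),
               "terminated")
})

test_that("default catalog has the six signature lines in report order", {
  cat5 <- default_catalog(5)
  expect_identical(names(cat5), c("A1+", "A1-", "A2+", "A2-", "B1", "B2"))
  for (nm in setdiff(names(cat5), "B2")) {
    expect_equal(sqrt(sum(cat5[[nm]]$direction^2)), 1, tolerance = 1e-12)
    expect_true(cat5[[nm]]$compensated)
    expect_equal(cat5[[nm]]$N, 5L)
  }
  expect_equal(cat5[["B2"]]$N, 6L)  # native order, cross-order entry
  frag <- default_catalog(5, b2_order = "fragments")
  expect_length(frag[["B2"]], 2)
  expect_error(default_catalog(6, b2_order = "fragments"), "N = 5")
})

test_that("catalogs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  cat5 <- default_catalog(5)
  cat5[["B3_4_2"]] <- make_b3(4, 2)
  catalog_to_json(cat5, path)
  back <- catalog_from_json(path)
  expect_identical(names(back), names(cat5))
  for (nm in names(cat5)) {
    expect_equal(back[[nm]]$direction, cat5[[nm]]$direction, tolerance = 1e-15)
    expect_identical(back[[nm]]$compensated, cat5[[nm]]$compensated)
  }
})
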