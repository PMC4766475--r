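test_that("cos_theta matches the brute-force inner product", {
  b1 <- make_b1(5)
  expect_equal(cos_theta(c(0, 0, -0.3, 0.3), b1), 1, tolerance = 1e-12)
  a2 <- make_a2(5, "+")
  w <- a2$direction[-5] * 0.2
  expect_equal(cos_theta(w, make_a2(5, "-")), -1, tolerance = 1e-12)
  # explicit arithmetic: (0.1, -0.1, 0, 0) is orthogonal to the canonical
  # pair position and at 60 degrees to the position-1 variant
  w <- c(0.1, -0.1, 0, 0)
  expect_equal(cos_theta(w, b1), 0, tolerance = 1e-12)
  expect_equal(cos_theta(w, make_b1(5, position = 1)), 0.5, tolerance = 1e-12)
  tr_line <- function(ln) { d <- ln$direction[-ln$N]; d / sqrt(sum(d^2)) }
  for (seed in 1:10) {
    set.seed(seed)
    w <- rnorm(4)
    expect_equal(cos_theta(w, b1), oracle_cos(w, tr_line(b1)),
                 tolerance = 1e-12)
  }
})

test_that("quiescent windows are non-evaluable", {
  expect_true(is.na(cos_theta(c(0, 0, 0, 0), make_b1(5))))
  expect_true(is.na(cos_theta(rep(1e-9, 4), make_b1(5))))
  expect_error(cos_theta(c(1, 2), make_b1(5)), "components")
})

test_that("one aligned ectopic pair in a flat record gives the printed presence", {
  rr <- rep(0.8, 105)
  rr[52] <- 0.8 * 0.8
  rr[53] <- 0.8 * 1.2
  p <- presence(delta_field(normalize_global(rr_series(rr)), 5), make_b1(5))
  expect_identical(p$m, 1L)
  expect_equal(p$presence_percent, 100 * 1 * 4 / 100, tolerance = 1e-12)
  expect_equal(p$matches$cos_theta, 1, tolerance = 1e-12)
  expect_gt(p$matches$amplitude, 0)
})

test_that("constant records have zero presence for every line", {
  f <- delta_field(rr_series(rep(0.8, 60)), 5)
  for (nm in c("A1+", "A1-", "A2+", "A2-", "B1")) {
    p <- presence(f, default_catalog(5)[[nm]])
    expect_identical(p$m, 0L)
    expect_identical(p$presence_percent, 0)
  }
})

test_that("presence follows the 100 m (N-1)/(M-N) formula", {
  rr <- rep(0.8, 4200)
  starts <- seq(50, by = 50, length.out = 42)
  rr[starts + 2] <- 0.8 * 0.75
  rr[starts + 3] <- 0.8 * 1.25
  p <- presence(delta_field(normalize_global(rr_series(rr)), 5), make_b1(5))
  expect_identical(p$m, 42L)
  expect_equal(p$presence_percent, 100 * 42 * 4 / 4195, tolerance = 1e-12)
  expect_equal(p$presence_percent, 4.00476758045292, tolerance = 1e-10)
})

test_that("overlap suppression converts window counts to event counts", {
  # every order-5 window inside a 12-beat linear ramp is exactly an A1+ ramp,
  # so the unsuppressed count sees 8 overlapping views of one episode while
  # suppression reduces them to ceiling(8 / 5) = 2 counted events
  rr <- rep(0.8, 200)
  rr[100:111] <- 0.8 * (1 + seq(0.06, -0.06, length.out = 12))
  f <- delta_field(normalize_global(rr_series(rr)), 5)
  on_ <- presence(f, make_a1(5, "+"), suppress_overlap = TRUE)
  off <- presence(f, make_a1(5, "+"), suppress_overlap = FALSE)
  expect_identical(on_$m, 2L)
  expect_gte(off$m, 8L)
  expect_gt(off$m, on_$m)
})

test_that("order mismatch between field and line is an explicit error", {
  f <- delta_field(rr_series(rep(c(0.8, 0.9), 30)), 5)
  expect_error(presence(f, make_b2(6)), "native order")
})

test_that("signatures reproduce the planted healthy/pathological ordering", {
  pr <- scenario_presets(seed = 42)
  sig_nsr <- signature(generate_rr(pr$nsr_like)$rr)
  sig_hf <- signature(generate_rr(pr$hf_like)$rr)
  expect_gt(sig_nsr$presences[["A1+"]], sig_nsr$presences[["B1"]])
  expect_gt(sig_hf$presences[["B1"]], sig_hf$presences[["A1+"]])
  expect_true(all(sig_nsr$presences >= 0))
  expect_gte(sig_nsr$phi, 0)
  # constant record: all-zero signature
  sig0 <- signature(rr_series(rep(0.8, 100)))
  expect_true(all(sig0$presences == 0))
  expect_identical(sig0$phi, 0)
  expect_error(signature(rr_series(rep(0.8, 10))), "at least")
})

test_that("signature space point projects the named entries verbatim", {
  sig0 <- signature(rr_series(rep(0.8, 100)))
  expect_equal(signature_space_point(sig0),
               c(a1_plus = 0, b1 = 0, phi = 0))
  sig <- signature(generate_rr(scenario_presets(seed = 9)$hf_like)$rr)
  pt <- signature_space_point(sig)
  expect_identical(pt[["a1_plus"]], sig$presences[["A1+"]])
  expect_identical(pt[["b1"]], sig$presences[["B1"]])
  expect_identical(pt[["phi"]], sig$phi)
})

test_that("presence is invariant under global rescaling", {
  out <- generate_rr(scenario_presets(seed = 2)$hf_like)
  f1 <- delta_field(normalize_global(out$rr), 5)
  rr2 <- rr_series(out$rr$intervals * 1000, unit = "seconds")
  f2 <- delta_field(normalize_global(rr2), 5)
  for (nm in c("A1+", "B1")) {
    p1 <- presence(f1, default_catalog(5)[[nm]])
    p2 <- presence(f2, default_catalog(5)[[nm]])
    expect_identical(p1$m, p2$m)
    expect_equal(p1$presence_percent, p2$presence_percent, tolerance = 1e-12)
  }
})
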