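test_that("a silent spec produces a constant series at mean_rr", {
  out <- generate_rr(synth_spec(100, mean_rr = 0.75))
  expect_equal(out$rr$intervals, rep(0.75, 100))
  expect_identical(nrow(out$truth), 0L)
})

test_that("an injected ectopic pair lands exactly on the B1 template", {
  spec <- synth_spec(200, events = data.frame(kind = "ectopic_pair",
                                              beat_index = 100,
                                              amplitude = 0.2))
  out <- generate_rr(spec)
  expect_equal(out$rr$intervals[100], 0.8 * 0.8)
  expect_equal(out$rr$intervals[101], 0.8 * 1.2)
  f <- delta_field(normalize_global(out$rr), 5)
  expect_equal(as.numeric(f$vectors[98, ]), c(0, 0, -0.2, 0.2, 0),
               tolerance = 1e-12)
  expect_identical(out$truth$line_name, "B1")
})

test_that("all event templates are zero-sum", {
  for (kind in c("ramp+", "ramp-", "ectopic_pair", "sinus_burst"))
    expect_lt(abs(sum(event_template(kind))), 1e-12)
  for (m in 2:6)
    expect_identical(sum(event_template("pause_tachy", m = m)), 0)
  expect_error(event_template("nope"), "unknown")
})

test_that("generation is deterministic in the seed", {
  spec <- synth_spec(500, noise_sd = 0.05, ar_coefficient = 0.6,
                     resp_amplitude = 0.02, seed = 7)
  a <- generate_rr(spec)
  b <- generate_rr(spec)
  expect_identical(a$rr$intervals, b$rr$intervals)
  spec2 <- synth_spec(500, noise_sd = 0.05, ar_coefficient = 0.6,
                      resp_amplitude = 0.02, seed = 8)
  expect_false(identical(generate_rr(spec2)$rr$intervals, a$rr$intervals))
})

test_that("generated mean stays within two standard errors of mean_rr", {
  # pooled over 30 independent realizations; AR(1) inflates the variance of
  # each record mean by (1 + phi)/(1 - phi) = 3
  means <- vapply(1:30, function(seed) {
    spec <- synth_spec(4000, mean_rr = 0.8, noise_sd = 0.04,
                       ar_coefficient = 0.5, resp_amplitude = 0.02,
                       seed = seed)
    mean(generate_rr(spec)$rr$intervals)
  }, 0)
  se_record <- 0.8 * 0.04 * sqrt(3 / 4000)
  expect_lt(abs(mean(means) - 0.8), 2 * se_record / sqrt(30))
})

test_that("overlapping or out-of-range events are rejected", {
  expect_error(generate_rr(synth_spec(100, events = data.frame(
    kind = c("ramp+", "ramp+"), beat_index = c(50, 52),
    amplitude = 0.1))), "overlaps")
  expect_error(generate_rr(synth_spec(100, events = data.frame(
    kind = "ramp+", beat_index = 98, amplitude = 0.1))), "fit")
  expect_error(generate_rr(synth_spec(100, events = data.frame(
    kind = c("ramp+", "ramp+"), beat_index = c(20, 30), amplitude = 0.1)),
    min_gap = 12), "fewer than")
})

test_that("noise-free recovery is exact for every template at its order", {
  for (kind in c("ramp+", "ramp-", "ectopic_pair", "pause_tachy",
                 "sinus_burst")) {
    out <- generate_rr(flat_event_spec(kind, rep(c(0.1, 0.3), 3)),
                       min_gap = 12)
    line <- line_for_kind(kind)
    f <- delta_field(normalize_global(out$rr), line$N)
    p <- presence(f, line)
    expect_identical(p$m, nrow(out$truth))
  }
})

test_that("recall at fixed tolerance degrades with noise on average", {
  recall_at <- function(noise_sd) {
    hits <- 0L
    total <- 0L
    for (seed in 1:10) {
      ev <- data.frame(kind = "ectopic_pair",
                       beat_index = seq(20, by = 15, length.out = 20),
                       amplitude = 0.2)
      spec <- synth_spec(350, noise_sd = noise_sd, ar_coefficient = 0.4,
                         events = ev, seed = 5000 + seed)
      out <- generate_rr(spec)
      p <- presence(delta_field(normalize_global(out$rr), 5), make_b1(5))
      hits <- hits + p$m
      total <- total + nrow(out$truth)
    }
    hits / total
  }
  r <- vapply(c(0.01, 0.05, 0.12), recall_at, 0)
  expect_gte(r[1], r[2])
  expect_gte(r[2], r[3])
  expect_gt(r[1], r[3])
})

test_that("presets define the documented regimes and round-trip as JSON", {
  pr <- scenario_presets(seed = 4)
  expect_identical(names(pr), c("nsr_like", "hf_like", "sd_like"))
  n_kind <- function(spec, kind) sum(spec$events$kind == kind)
  expect_gt(n_kind(pr$nsr_like, "ramp+") + n_kind(pr$nsr_like, "ramp-"),
            n_kind(pr$nsr_like, "ectopic_pair"))
  expect_gt(n_kind(pr$hf_like, "ectopic_pair") +
              n_kind(pr$hf_like, "pause_tachy"),
            n_kind(pr$hf_like, "ramp+") + n_kind(pr$hf_like, "ramp-"))
  path <- withr::local_tempfile(fileext = ".json")
  synth_spec_to_json(pr$hf_like, path)
  back <- synth_spec_from_json(path)
  expect_equal(back$events$beat_index, pr$hf_like$events$beat_index)
  expect_identical(generate_rr(back)$rr$intervals,
                   generate_rr(pr$hf_like)$rr$intervals)
})
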