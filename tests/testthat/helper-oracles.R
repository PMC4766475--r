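# Independent oracles and generators shared across the suite.

# residual of the orthogonal projection of a window onto the identity line,
# computed explicitly as p - (p . u) u with u = (1, ..., 1)/sqrt(N)
oracle_identity_residual <- function(p) {
  u <- rep(1, length(p)) / sqrt(length(p))
  p - sum(p * u) * u
}

# brute-force cosine between two vectors
oracle_cos <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))

# random positive RR series: lognormal multiplicative noise around 0.8 s
rand_rr <- function(M, seed, sd = 0.1) {
  set.seed(seed)
  rr_series(0.8 * exp(rnorm(M, sd = sd)), unit = "seconds")
}

# flat-baseline spec with one kind of event injected at regular spacing
flat_event_spec <- function(kind, amplitudes, M = 300, start = 20, by = 20) {
  ev <- data.frame(kind = kind, beat_index = seq(start, by = by,
                                                 length.out = length(amplitudes)),
                   amplitude = amplitudes)
  synth_spec(M, events = ev)
}

line_for_kind <- function(kind) {
  switch(kind,
         "ramp+" = make_a1(5, "+"),
         "ramp-" = make_a1(5, "-"),
         "ectopic_pair" = make_b1(5),
         "pause_tachy" = make_b2(6),
         "sinus_burst" = make_a2(5, "+"))
}
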