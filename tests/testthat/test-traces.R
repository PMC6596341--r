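test_that("normalization removes any positive-gain affine transform", {
  # sigmoid with exactly flat baseline and plateau windows
  tg <- seq(0, 400 * 29, by = 400)
  f <- c(rep(0, 5), 1 / (1 + exp(-seq(-6, 6, length.out = 20))), rep(1, 5))
  f <- (f - min(f)) / (max(f) - min(f))
  nt <- normalize_trace(tht_trace(tg, 250 + 730 * f))
  expect_equal(nt$mass_fraction, f, tolerance = 1e-12)
  # idempotence on an already-normalized trace
  nt2 <- normalize_trace(tht_trace(tg, nt$mass_fraction))
  expect_equal(nt2$mass_fraction, nt$mass_fraction, tolerance = 1e-12)
  # affine invariance holds for any completed model curve
  p <- ref_params(1)
  tgm <- seq(0, 4 * 3600, by = 400)
  fm <- closed_form_mass_fraction(p, tgm)
  expect_equal(normalize_trace(tht_trace(tgm, 250 + 730 * fm))$mass_fraction,
               normalize_trace(tht_trace(tgm, fm))$mass_fraction,
               tolerance = 1e-12)
})

test_that("normalization recovers the generating curve from a noisy plate trace", {
  p <- ref_params(1)
  sim <- simulate_tht_plate(p, baseline = 100, amplitude = 900,
                            noise_sd_fraction = 0.01, seed = 9)
  f <- sim$ground_truth$curves$control
  for (tr in sim$traces) {
    nt <- normalize_trace(tr)
    expect_lt(max(abs(nt$mass_fraction - f)), 0.03)
  }
})

test_that("flat or decreasing traces cannot be normalized", {
  tg <- seq(0, 4000, by = 400)
  expect_error(normalize_trace(tht_trace(tg, rep(5, length(tg)))),
               "flat or decreasing")
  expect_error(normalize_trace(tht_trace(tg, seq(10, 1, length.out = length(tg)))),
               "flat or decreasing")
})

test_that("trace constructor enforces its invariants", {
  expect_error(tht_trace(c(1, 2, 3), c(1, 2, 3)), "at least 4")
  expect_error(tht_trace(c(1, 2, 2, 3), 1:4), "strictly increasing")
  expect_error(tht_trace(1:4, 1:3), "equal length")
})

test_that("half-time interpolates the first upward 0.5-crossing", {
  # exact sample hit at 7200 s
  tr <- normalized_trace(c(0, 3600, 7200, 10800), c(0, 0.2, 0.5, 1))
  expect_equal(half_time(tr), 2.0)
  # logistic with midpoint 2880 s = 0.8 h
  tg <- seq(0, 8000, by = 400)
  lg <- normalized_trace(tg, 1 / (1 + exp(-(tg - 2880) / 400)))
  expect_lt(abs(half_time(lg) - 0.8), 400 / 3600)
  # incomplete reaction
  expect_error(half_time(normalized_trace(tg, rep(0.2, length(tg)))),
               "incomplete")
})

test_that("half-time is invariant under affine rescaling of the raw signal", {
  p <- ref_params(0.8)
  tg <- seq(0, 4 * 3600, by = 400)
  f <- closed_form_mass_fraction(p, tg)
  t1 <- half_time(normalize_trace(tht_trace(tg, f)))
  t2 <- half_time(normalize_trace(tht_trace(tg, 300 + 1700 * f)))
  expect_equal(t1, t2)
})

test_that("blank subtraction removes an additive dye-only signal", {
  p <- ref_params(1)
  tg <- seq(0, 4 * 3600, by = 400)
  f <- closed_form_mass_fraction(p, tg)
  drift <- 20 + 0.001 * tg
  raw <- tht_trace(tg, 100 + 900 * f + drift)
  blank <- tht_trace(tg, drift)
  corr <- subtract_blank(raw, blank)
  expect_equal(half_time(normalize_trace(corr)),
               half_time(normalize_trace(tht_trace(tg, 100 + 900 * f))),
               tolerance = 1e-6)
  expect_error(subtract_blank(raw, tht_trace(tg + 1, drift)), "time grid")
})

test_that("half-time comparison tables report fold changes against the reference", {
  th <- c(control = 0.8, treated = 3.5)
  tab <- compare_half_times(th, "control")
  expect_equal(tab$fold_change[tab$label == "treated"], 4.375)
  expect_equal(tab$fold_change[tab$label == "control"], 1)
  expect_equal(compare_half_times(c(only = 1.2), "only")$fold_change, 1)
  expect_error(compare_half_times(numeric(0), "x"), "empty")
  expect_error(compare_half_times(th, "missing"), "control")
})
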