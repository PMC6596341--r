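test_that("closed form starts at zero and saturates at one", {
  for (th in c(0.5, 1, 4)) {
    p <- ref_params(th)
    expect_equal(closed_form_mass_fraction(p, 0), 0, tolerance = 1e-10)
    expect_equal(closed_form_mass_fraction(p, 50 * th * 3600), 1,
                 tolerance = 1e-6)
    mf <- closed_form_mass_fraction(p, seq(0, 10 * th * 3600, length.out = 400))
    expect_true(all(diff(mf) >= -1e-12))
    expect_true(all(mf >= 0 & mf <= 1))
  }
})

test_that("closed form reaches one half at its half-time, confirmed by the ODE oracle", {
  p <- ref_params(1)  # 5 uM, n_c = n_2 = 2, rates set for t1/2 = 1 h
  expect_equal(closed_form_mass_fraction(p, 3600), 0.5, tolerance = 0.01)
  tg <- seq(0, 4 * 3600, by = 100)
  orc <- moment_ode_oracle(p, tg)
  t_orc <- half_time(orc) * 3600
  expect_equal(t_orc, 3600, tolerance = 0.01)
})

test_that("closed form matches the moment-equation oracle in the secondary-dominated regime", {
  set.seed(101)
  for (i in 1:8) {
    ratio <- 10^runif(1, 1, 3)
    kappa <- 10^runif(1, -4, -2.5)
    k_plus <- 1e6
    lambda <- kappa / ratio
    p <- kinetic_parameters(k_plus, lambda^2 / (2 * k_plus * 25e-12),
                            kappa^2 / (2 * k_plus * 125e-18), m0 = 5e-6)
    tg <- seq(0, 10 / kappa, length.out = 200)
    mf <- closed_form_mass_fraction(p, tg)
    orc <- moment_ode_oracle(p, tg)
    expect_lt(sqrt(mean((mf - orc$mass_fraction)^2)), 0.01)
  }
})

test_that("moment oracle conserves mass and is inert without nucleation", {
  p <- ref_params(1)
  tg <- seq(0, 2 * 3600, by = 200)
  orc <- moment_ode_oracle(p, tg)
  m <- attr(orc, "monomer")
  expect_equal(m + orc$mass_fraction * p$m0, rep(p$m0, length(tg)),
               tolerance = 1e-6)
  p0 <- kinetic_parameters(1e6, 0, 0, m0 = 5e-6)
  orc0 <- moment_ode_oracle(p0, tg)
  expect_equal(orc0$mass_fraction, rep(0, length(tg)))
})

test_that("degenerate parameters are rejected with a named message", {
  p2 <- kinetic_parameters(1e6, 8e-6, 0, m0 = 5e-6)
  expect_error(closed_form_mass_fraction(p2, 100), "k_2")
  pn <- kinetic_parameters(1e6, 0, 4000, m0 = 5e-6)
  expect_error(closed_form_mass_fraction(pn, 100), "k_n")
  expect_error(kinetic_parameters(-1, 1, 1), "k_plus")
  expect_error(kinetic_parameters(1, 1, 1, n_c = 0.5), "n_c")
  expect_error(kinetic_parameters(1, 1, 1, m0 = 0), "m0")
  expect_error(closed_form_mass_fraction(ref_params(1), -5), "t must be")
})

test_that("half-time falls with monomer, secondary nucleation and elongation rates", {
  base <- ref_params(1)
  th_of <- function(p) {
    tg <- seq(0, 20 * 3600, by = 100)
    half_time(normalized_trace(tg, closed_form_mass_fraction(p, tg)))
  }
  t0 <- th_of(base)
  for (fld in c("m0", "k_2", "k_plus")) {
    up <- base
    up[[fld]] <- 2 * base[[fld]]
    up <- kinetic_parameters(up$k_plus, up$k_n, up$k_2, up$n_c, up$n_2, up$m0)
    expect_lt(th_of(up), t0)
  }
})

test_that("half-time scales with monomer as the secondary-nucleation exponent predicts", {
  # log t1/2 vs log m0 slope ~ -(n_2 + 1)/2 in the secondary-dominated regime
  base <- ref_params(1)
  m0s <- 5e-6 * c(0.5, 1, 2, 4)
  th <- vapply(m0s, function(m) {
    p <- kinetic_parameters(base$k_plus, base$k_n, base$k_2, base$n_c, base$n_2, m)
    tg <- seq(0, 40 * 3600, by = 100)
    half_time(normalized_trace(tg, closed_form_mass_fraction(p, tg)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(th) ~ log(m0s)))[[2]]
  expected <- -(base$n_2 + 1) / 2
  expect_lt(abs(slope - expected) / abs(expected), 0.15)
})
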