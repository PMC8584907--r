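c_cm <- physical_constants()$c_cm

make_ref_pulse <- function(t0_ps = 8, tau_ps = 0.12, dt_ps = 0.05,
                           span_ps = 40) {
  t_ps <- seq(0, span_ps - dt_ps, by = dt_ps)
  tt <- (t_ps - t0_ps) * 1e-12
  tau <- tau_ps * 1e-12
  time_trace(t_ps, -tt / tau^2 * exp(-tt^2 / (2 * tau^2)))
}

test_that("a pure cosine transforms to a single spectral peak", {
  t_ps <- seq(0, 40, by = 0.05)
  nu0 <- 60
  x <- cos(2 * pi * nu0 * c_cm * t_ps * 1e-12) *
    exp(-((t_ps - 20) / 8)^2)          # smooth envelope to limit leakage
  sp <- fourier_spectrum(time_trace(t_ps, x), default_grid())
  amp <- Mod(sp$values)
  nu <- as.numeric(sp$grid)
  expect_lt(abs(nu[which.max(amp)] - nu0), 1)
  expect_lt(max(amp[abs(nu - nu0) > 15]) / max(amp), 0.01)
})

test_that("delaying a trace shifts phase by 2*pi*nu*c*dt and keeps amplitude", {
  tr <- make_ref_pulse()
  dt_ps <- 0.35
  tr_del <- time_trace(tr$time_ps, c(rep(0, 7), tr$field[1:(length(tr$field) - 7)]))
  g <- default_grid(n = 50)
  a <- fourier_spectrum(tr, g)
  b <- fourier_spectrum(tr_del, g)
  expect_equal(Mod(b$values), Mod(a$values), tolerance = 1e-6)
  dphi <- attr(a, "phase") - attr(b, "phase")
  expected <- 2 * pi * as.numeric(g) * c_cm * dt_ps * 1e-12
  expect_equal(dphi, expected, tolerance = 1e-6)
})

test_that("Gaussian-derivative pulse matches its continuous transform", {
  t0 <- 8; tau <- 0.12
  tr <- make_ref_pulse(t0_ps = t0, tau_ps = tau)
  g <- default_grid()
  sp <- fourier_spectrum(tr, g)
  # continuous FT of d/dt exp(-(t-t0)^2/(2 tau^2)):
  # 2*pi*i*f * sqrt(2*pi)*tau * exp(-2*pi^2*f^2*tau^2) * exp(-2*pi*i*f*t0)
  f_hz <- as.numeric(g) * c_cm
  analytic <- 2 * pi * f_hz * sqrt(2 * pi) * (tau * 1e-12) *
    exp(-2 * pi^2 * f_hz^2 * (tau * 1e-12)^2)
  dt_s <- 0.05e-12
  ratio <- Mod(sp$values) * dt_s / analytic
  expect_lt(max(abs(ratio - 1)), 0.005)
})

test_that("grid beyond Nyquist and non-uniform sampling are rejected", {
  tr <- make_ref_pulse(dt_ps = 0.5)      # Nyquist ~33 cm-1
  expect_error(fourier_spectrum(tr, default_grid()), "Nyquist")
})

test_that("identical traces give unit transmission and index", {
  tr <- make_ref_pulse()
  po <- optics_from_pair(tr, tr, dl_um = 50.2, grid = default_grid(),
                         n_anchor = 1)
  expect_equal(Re(po$transmission$values), rep(1, 250), tolerance = 1e-10)
  expect_equal(Re(po$index$values), rep(1, 250), tolerance = 1e-8)
  expect_equal(po$effective_thickness_um, 50.2)
})

test_that("a pure delay reads as a constant refractive index", {
  tr <- make_ref_pulse()
  lag <- 14L                              # 0.7 ps
  dt_ps <- 0.05
  delayed <- time_trace(tr$time_ps,
                        c(rep(0, lag), tr$field[1:(length(tr$field) - lag)]))
  dl_um <- 50.2
  n_expect <- 1 + c_cm * (lag * dt_ps * 1e-12) / (dl_um * 1e-4)
  po <- optics_from_pair(delayed, tr, dl_um = dl_um, grid = default_grid(),
                         n_anchor = n_expect)
  expect_equal(Re(po$index$values), rep(n_expect, 250), tolerance = 1e-6)
  expect_equal(Re(po$transmission$values), rep(1, 250), tolerance = 1e-8)
})

test_that("permittivity formulae are the exact square of n + i kappa", {
  g <- default_grid()
  nu <- as.numeric(g)
  set.seed(11)
  n_val <- stats::runif(250, 1.5, 3)
  tr_val <- stats::runif(250, 0.05, 0.95)
  l_um <- 50.2
  pair <- list(
    transmission = complex_spectrum(g, tr_val, kind = "transmission"),
    index = complex_spectrum(g, n_val, kind = "refractive_index"),
    effective_thickness_um = l_um)
  eps <- permittivity_from_optics(pair)
  kappa <- -log(tr_val) / (4 * pi * nu * l_um * 1e-4)
  expect_lt(max(Mod(eps$values - (complex(real = n_val, imaginary = kappa))^2)),
            1e-12)
  # lossless limit
  pair$transmission <- complex_spectrum(g, rep(1, 250), kind = "transmission")
  eps0 <- permittivity_from_optics(pair)
  expect_equal(Im(eps0$values), rep(0, 250))
  expect_equal(Re(eps0$values), n_val^2, tolerance = 1e-14)
})

test_that("hand-evaluated permittivity at a single point", {
  # n = 2.2, power transmission 0.5, nu = 50 cm-1, l = 50.2 um
  nu <- 50; l_cm <- 50.2e-4; n <- 2.2; tr <- 0.5
  kappa <- -log(tr) / (4 * pi * nu * l_cm)
  g <- frequency_grid(c(49, 50, 51))
  pair <- list(
    transmission = complex_spectrum(g, rep(tr, 3), kind = "transmission"),
    index = complex_spectrum(g, rep(n, 3), kind = "refractive_index"),
    effective_thickness_um = 50.2)
  eps <- permittivity_from_optics(pair)$values[2]
  expect_equal(Re(eps), n^2 - kappa^2, tolerance = 1e-14)
  expect_equal(Im(eps), -n * log(tr) / (2 * pi * nu * l_cm), tolerance = 1e-14)
})

test_that("etalon fringes invert to the cuvette gap", {
  g <- frequency_grid(seq(10, 1000, by = 0.5))
  nu <- as.numeric(g)
  # fringe spacing 99.88 cm-1 corresponds to a 50.06 um air gap
  tr <- 0.7 + 0.2 * cos(2 * pi * nu / 99.88)
  et <- etalon_thickness(complex_spectrum(g, tr, kind = "transmission"))
  expect_equal(et$thickness_um, 50.06, tolerance = 1e-3)
  # doubling the gap halves the fringe spacing
  tr2 <- 0.7 + 0.2 * cos(2 * pi * nu / (99.88 / 2))
  et2 <- etalon_thickness(complex_spectrum(g, tr2, kind = "transmission"))
  expect_equal(et2$fringe_spacing_cm / et$fringe_spacing_cm, 0.5,
               tolerance = 1e-2)
  expect_equal(et2$thickness_um, 2 * 50.06, tolerance = 0.5)
  # 1% amplitude noise on a 100.26 um gap: recovery within 0.5%
  set.seed(5)
  tr3 <- (0.7 + 0.2 * cos(4 * pi * nu * 100.26e-4)) *
    (1 + 0.01 * stats::rnorm(length(nu)))
  et3 <- etalon_thickness(complex_spectrum(g, tr3, kind = "transmission"))
  expect_lt(abs(et3$thickness_um - 100.26) / 100.26, 0.005)
  # narrow band: too few fringes
  g4 <- default_grid()
  tr4 <- 0.7 + 0.2 * cos(2 * pi * as.numeric(g4) / 99.88)
  expect_error(
    etalon_thickness(complex_spectrum(g4, tr4, kind = "transmission")),
    "fringes")
})

test_that("synthetic propagation recovers the generating permittivity", {
  g <- default_grid()
  eps_true <- water_spectrum(g)
  pair <- make_pulse_pair(eps_true)
  po <- optics_from_pair(pair$sample, pair$background,
                         dl_um = 100.26 - 50.06, grid = g)
  rec <- permittivity_from_optics(po)
  expect_lt(max(abs(Re(rec$values) - Re(eps_true$values)) /
                  abs(Re(eps_true$values))), 0.02)
  expect_lt(max(abs(Im(rec$values) - Im(eps_true$values)) /
                  abs(Im(eps_true$values))), 0.02)
  # recovered optics match the forward-model optics: n = Re sqrt(eps)
  n_true <- Re(sqrt(eps_true$values))
  expect_lt(max(abs(Re(po$index$values) - n_true) / n_true), 0.01)
})

test_that("vanishing background amplitude is reported with its wavenumber", {
  tr <- make_ref_pulse()
  zero <- time_trace(tr$time_ps, rep(0, length(tr$time_ps)))
  expect_error(optics_from_pair(tr, zero, 50.2, default_grid()),
               "cm-1")
})
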