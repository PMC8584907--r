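test_that("model evaluation matches an independent term-by-term computation", {
  p <- water_reference_params()
  cst <- physical_constants()
  for (nu in c(10, 110)) {
    w <- 2 * pi * cst$c_cm * nu
    w0 <- 2 * pi * cst$c_cm * p$w0
    gam <- 2 * pi * cst$c_cm * p$gam
    term1 <- p$de1 / complex(real = 1, imaginary = -w * 8.28e-12)
    term2 <- p$de2 / complex(real = 1, imaginary = -w * p$tau2 * 1e-12)
    term3 <- (p$aratio * w0^2) /
      complex(real = w0^2 - w^2, imaginary = -w * gam)
    expected <- term1 + term2 + term3 + 2.5
    got <- eval_model(p, frequency_grid(c(nu - 1, nu, nu + 1)))$values[2]
    expect_equal(Re(got), Re(expected), tolerance = 1e-13)
    expect_equal(Im(got), Im(expected), tolerance = 1e-13)
  }
})

test_that("static limit recovers the total relaxation strength", {
  p <- water_reference_params()
  eps <- eval_model(p, frequency_grid(0.001))$values
  static <- p$de1 + p$de2 + p$aratio + p$eps_inf
  expect_equal(Re(eps), static, tolerance = 1e-3 * static)
  expect_lt(Im(eps) / Re(eps), 0.002)   # loss vanishes relative to eps'
})

test_that("conductivity adds exactly sigma0/(eps0 w) to the loss", {
  g <- default_grid()
  p0 <- water_reference_params()
  p1 <- dielectric_params(de1 = p0$de1, de2 = p0$de2, tau2 = p0$tau2,
                          aratio = p0$aratio, w0 = p0$w0, gam = p0$gam,
                          sigma0 = 1.3)
  e0 <- eval_model(p0, g)$values
  e1 <- eval_model(p1, g)$values
  cst <- physical_constants()
  w <- wavenumber_to_angular(as.numeric(g))
  expect_equal(Re(e1), Re(e0), tolerance = 1e-14)
  expect_equal(Im(e1) - Im(e0), 1.3 / (cst$eps0 * w), tolerance = 1e-12)
})

test_that("each dispersive term has non-negative loss at all frequencies", {
  g <- frequency_grid(10^seq(-2, 4, length.out = 200))
  w <- wavenumber_to_angular(as.numeric(g))
  for (tau_ps in c(0.316, 8.28)) {
    expect_true(all(Im(1 / (1 - 1i * w * tau_ps * 1e-12)) >= 0))
  }
  w0 <- wavenumber_to_angular(207.2); gam <- wavenumber_to_angular(196.5)
  expect_true(all(Im(1 / (w0^2 - w^2 - 1i * w * gam)) >= 0))
})

test_that("fitting criterion has its closed-form values", {
  g <- default_grid()
  m <- water_spectrum(g)
  expect_equal(objective_s(m, m), 0)
  exp11 <- complex_spectrum(g, 1.1 * m$values, kind = "permittivity")
  expect_equal(objective_s(m, exp11), 0.02, tolerance = 1e-12)
  # naive-loop oracle on randomly perturbed spectra
  set.seed(31)
  pert <- complex_spectrum(
    g, m$values * complex(real = 1 + 0.05 * stats::rnorm(250),
                          imaginary = 1 + 0.05 * stats::rnorm(250)),
    kind = "permittivity")
  s_loop <- 0
  for (i in 1:250) {
    s_loop <- s_loop +
      ((Re(m$values[i]) - Re(pert$values[i])) / Re(m$values[i]))^2 +
      ((Im(m$values[i]) - Im(pert$values[i])) / Im(m$values[i]))^2
  }
  expect_equal(objective_s(m, pert), s_loop / 250, tolerance = 1e-14)
})

test_that("noiseless self-consistency: the fit recovers the truth", {
  truth <- water_reference_params()
  spec <- eval_model(truth, default_grid())
  fit <- fit_model(spec, offset_fit_config(multistart = 4))
  expect_lt(fit$s, 1e-8)
  for (p in c("de1", "de2", "tau2", "aratio", "w0", "gam")) {
    expect_lt(abs(fit$params[[p]] - truth[[p]]) / truth[[p]], 1e-3)
  }
  # idempotence: refitting the fitted model returns the same parameters
  fit2 <- fit_model(eval_model(fit$params, default_grid()),
                    fit_config(start = fit$params, multistart = 1))
  for (p in c("de1", "de2", "tau2", "aratio", "w0", "gam")) {
    expect_equal(fit2$params[[p]], fit$params[[p]], tolerance = 1e-6)
  }
})

test_that("all reference parameter sets are refit with s below 0.0021", {
  ref <- reference_parameters()
  for (smp in ref$sample) {
    p <- preset_params(smp)
    spec <- eval_model(p, default_grid())
    fit <- fit_model(spec, offset_fit_config(sigma0 = p$sigma0,
                                             multistart = 3))
    expect_lt(fit$s, 0.0021)
  }
})

test_that("free-water share reproduces the reference column", {
  # structure check of the statistic: published strengths reproduce the
  # published percentages within the rounding of the inputs
  ref <- reference_parameters()
  n <- mapply(free_water_from_strengths, ref$de2, ref$aratio)
  expect_true(all(abs(n - ref$n_pct) <= 0.05))
  expect_equal(free_water_from_strengths(2.691, 1.702), 3.78,
               tolerance = 0.05 / 3.78)
  expect_equal(free_water_from_strengths(2.931, 1.844), 3.86,
               tolerance = 0.05 / 3.86)
  expect_equal(free_water_from_strengths(0, 1.702), 0)
})

test_that("free-water share is monotone in its strengths", {
  de2_grid <- seq(0.5, 6, length.out = 25)
  n_de2 <- vapply(de2_grid, free_water_from_strengths, numeric(1),
                  aratio = 1.702)
  expect_true(all(diff(n_de2) > 0))
  ar_grid <- seq(0.5, 4, length.out = 25)
  n_ar <- vapply(ar_grid, function(a)
    free_water_from_strengths(2.691, a), numeric(1))
  expect_true(all(diff(n_ar) < 0))
})

test_that("free_water_fraction agrees with the strength interface", {
  p <- water_reference_params()
  expect_equal(free_water_fraction(p),
               free_water_from_strengths(p$de2, p$aratio))
})

test_that("replicate aggregation computes t-based confidence intervals", {
  fake_fit <- function(v) {
    structure(list(
      params = dielectric_params(de1 = v, de2 = 2.7, tau2 = 0.32,
                                 aratio = 1.7, w0 = 207, gam = 196),
      s = 0, n_free_pct = 3.8), class = "thz_fit")
  }
  # identical replicates: zero half-width
  agg0 <- aggregate_replicates(lapply(rep(68, 5), fake_fit))
  expect_equal(agg0$ci95, rep(0, 7))
  expect_identical(agg0$parameter,
                   c("de1", "de2", "tau2", "w0", "gam", "aratio", "n_pct"))
  expect_error(aggregate_replicates(list(fake_fit(68))), "2 replicates")
  # simulation oracle: CI half-width ~ t * sigma_hat / sqrt(n)
  set.seed(32)
  sigma <- 1.7; nrep <- 20; trials <- 400
  hw <- replicate(trials, {
    x <- stats::rnorm(nrep, 68.86, sigma)
    agg <- aggregate_replicates(lapply(x, fake_fit))
    agg$ci95[agg$parameter == "de1"]
  })
  t19 <- stats::qt(0.975, nrep - 1)
  c4 <- sqrt(2 / (nrep - 1)) * gamma(nrep / 2) / gamma((nrep - 1) / 2)
  expect_equal(mean(hw), t19 * c4 * sigma / sqrt(nrep), tolerance = 0.02)
})
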