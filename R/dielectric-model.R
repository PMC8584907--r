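#' Parameters of the relaxation-oscillation dielectric model
#'
#' The water-phase permittivity in the 10-110 cm^-1 band is modelled as the
#' sum of a slow Debye relaxation (cooperative reorientation of the hydrogen-
#' bond network), a fast Debye relaxation (free or weakly bound molecules), a
#' damped harmonic oscillator (intermolecular stretching of hydrogen-bonded
#' molecules), a high-frequency offset and a dc-conductivity term:
#' \deqn{\epsilon^*(\omega) = \frac{\Delta\epsilon_1}{1-i\omega\tau_1}
#'  + \frac{\Delta\epsilon_2}{1-i\omega\tau_2}
#'  + \frac{A}{\omega_0^2-\omega^2-i\omega\gamma}
#'  + \epsilon_\infty + \frac{i\sigma_0}{\epsilon_0\omega}.}
#'
#' The oscillator amplitude is supplied as the dimensionless ratio
#' `aratio = A/omega0^2` (its static contribution to the permittivity), the
#' form in which it is reported and bounded; `A` itself is `aratio * omega0^2`
#' with `omega0` in rad/s.
#'
#' @param de1,de2 Debye strengths (dimensionless, > 0).
#' @param tau1,tau2 Debye times, ps (> 0). `tau1` defaults to 8.28 ps, the
#'   pure-water value at 25 C, and is normally held fixed.
#' @param aratio dimensionless oscillator contribution A/omega0^2 (> 0).
#' @param w0,gam oscillator resonance and bandwidth, cm^-1 (> 0).
#' @param eps_inf high-frequency permittivity (>= 1); 2.5 for dilute aqueous
#'   solutions near the oscillator band.
#' @param sigma0 dc conductivity, S/m (>= 0).
#' @return named list of class `thz_params`.
#' @export
#' @examples
#' p <- water_reference_params()
#' eval_model(p, default_grid())
dielectric_params <- function(de1, de2, tau2, aratio, w0, gam,
                              tau1 = 8.28, eps_inf = 2.5, sigma0 = 0) {
  p <- list(de1 = de1, de2 = de2, tau1 = tau1, tau2 = tau2,
            aratio = aratio, w0 = w0, gam = gam,
            eps_inf = eps_inf, sigma0 = sigma0)
  with(p, {
    if (any(c(de1, de2, tau1, tau2, aratio, w0, gam) <= 0)) {
      stop("de1, de2, tau1, tau2, aratio, w0, gam must all be > 0")
    }
    if (eps_inf < 1) stop("eps_inf must be >= 1")
    if (sigma0 < 0) stop("sigma0 must be >= 0")
  })
  structure(p, class = "thz_params")
}

#' @export
print.thz_params <- function(x, ...) {
  cat(sprintf(
    "<thz_params> de1=%.4g de2=%.4g tau1=%.4g ps tau2=%.4g ps\n",
    x$de1, x$de2, x$tau1, x$tau2))
  cat(sprintf(
    "  A/w0^2=%.4g w0=%.4g cm-1 gam=%.4g cm-1 eps_inf=%.3g sigma0=%.3g S/m\n",
    x$aratio, x$w0, x$gam, x$eps_inf, x$sigma0))
  invisible(x)
}

#' Reference fitted parameter sets for water and carbohydrate solutions
#'
#' Published fitted model parameters (with 95% confidence half-widths of the
#' replicate means) for pure water and six ~3 vol% aqueous carbohydrate
#' solutions at 25 C, together with solution metadata: effective-medium
#' geometry, mass concentration, specific volume and dc conductivity. These
#' rows serve as simulation presets and as the scale reference for the noise
#' model.
#'
#' @return data.frame with one row per sample: columns `sample`, `de1`,
#'   `de2`, `tau2`, `w0`, `gam`, `aratio`, `n_pct`, matching `ci_*`
#'   half-widths, `geometry`, `mass_conc_g_cm3`, `specific_volume_cm3_g`,
#'   `sigma0_S_per_m`.
#' @export
reference_parameters <- function() {
  df <- data.frame(
    sample = c("water", "glucose", "galactose", "galacturonic_acid",
               "dextran", "amylopectin", "polygalacturonic_acid"),
    de1    = c(68.86, 62.45, 62.23, 63.20, 63.81, 65.97, 63.75),
    de2    = c(2.691, 2.939, 2.931, 3.006, 2.728, 2.688, 2.729),
    tau2   = c(0.316, 0.326, 0.327, 0.334, 0.321, 0.319, 0.312),
    w0     = c(207.2, 215.9, 221.3, 221.7, 210.6, 209.7, 219.1),
    gam    = c(196.5, 202.6, 217.3, 223.1, 200.0, 197.4, 208.2),
    aratio = c(1.702, 1.807, 1.844, 1.867, 1.719, 1.737, 1.801),
    n_pct  = c(3.78, 3.91, 3.86, 3.91, 3.80, 3.74, 3.72),
    ci_de1    = c(0.81, 0.48, 0.83, 0.46, 0.88, 0.84, 0.84),
    ci_de2    = c(0.042, 0.039, 0.046, 0.024, 0.052, 0.045, 0.051),
    ci_tau2   = c(0.006, 0.005, 0.004, 0.003, 0.005, 0.005, 0.004),
    ci_w0     = c(4.3, 3.9, 4.9, 4.7, 4.2, 4.5, 7.0),
    ci_gam    = c(11.1, 5.6, 9.0, 9.6, 10.0, 9.6, 13.0),
    ci_aratio = c(0.019, 0.038, 0.029, 0.022, 0.018, 0.016, 0.025),
    ci_n_pct  = c(0.04, 0.03, 0.04, 0.03, 0.05, 0.04, 0.06),
    geometry = c(NA, "spherical", "spherical", "spherical",
                 "fiber", "fiber", "fiber"),
    mass_conc_g_cm3 = c(0, 0.050, 0.050, 0.05387, 0.045, 0.045, 0.04887),
    specific_volume_cm3_g = c(NA, 0.62, 0.62, 0.55, 0.60, 0.60, 0.55),
    sigma0_S_per_m = c(0, 0, 0, 1.3, 0, 0, 1.86),
    stringsAsFactors = FALSE
  )
  df
}

#' @rdname reference_parameters
#' @param sample row of [reference_parameters()] to turn into a parameter
#'   object.
#' @return `preset_params`: a `thz_params` for the requested sample
#'   (`sigma0` from the solution metadata).
#' @export
preset_params <- function(sample = "water") {
  ref <- reference_parameters()
  row <- ref[ref$sample == sample, ]
  if (nrow(row) != 1) {
    stop("unknown sample '", sample, "'; see reference_parameters()$sample")
  }
  dielectric_params(de1 = row$de1, de2 = row$de2, tau2 = row$tau2,
                    aratio = row$aratio, w0 = row$w0, gam = row$gam,
                    sigma0 = row$sigma0_S_per_m)
}

#' @rdname reference_parameters
#' @export
water_reference_params <- function() preset_params("water")

#' Evaluate the dielectric model on a frequency grid
#'
#' @param params a [dielectric_params()].
#' @param grid a `thz_grid` (cm^-1).
#' @return `thz_spectrum` of kind `"permittivity"`.
#' @export
eval_model <- function(params, grid) {
  stopifnot(inherits(params, "thz_params"))
  if (!inherits(grid, "thz_grid")) grid <- frequency_grid(grid)
  cst <- physical_constants()
  w <- wavenumber_to_angular(as.numeric(grid))
  w0 <- wavenumber_to_angular(params$w0)
  g <- wavenumber_to_angular(params$gam)
  A <- params$aratio * w0^2
  eps <- params$de1 / (1 - 1i * w * params$tau1 * 1e-12) +
    params$de2 / (1 - 1i * w * params$tau2 * 1e-12) +
    A / (w0^2 - w^2 - 1i * w * g) +
    params$eps_inf +
    1i * params$sigma0 / (cst$eps0 * w)
  complex_spectrum(grid, eps, kind = "permittivity",
                   meta = list(sample = "model"))
}

#' Relative fitting criterion between model and experimental spectra
#'
#' \deqn{s = \frac{1}{N}\sum_{i=1}^{N}\Big[
#'   \Big(\frac{\epsilon'_{mod}-\epsilon'_{exp}}{\epsilon'_{mod}}\Big)^2 +
#'   \Big(\frac{\epsilon''_{mod}-\epsilon''_{exp}}{\epsilon''_{mod}}\Big)^2
#'   \Big].}
#' Note the normalisation by the MODEL value in each term (kept as the
#' published criterion, although normalising by the experiment is more
#' common).
#'
#' @param model,experiment `thz_spectrum`s on the same grid.
#' @return the dimensionless criterion s >= 0.
#' @export
objective_s <- function(model, experiment) {
  check_same_grid(model, experiment)
  rm_ <- Re(model$values); im_ <- Im(model$values)
  if (any(rm_ == 0) || any(im_ == 0)) {
    stop("model permittivity must be non-zero in both parts")
  }
  mean(((rm_ - Re(experiment$values)) / rm_)^2 +
       ((im_ - Im(experiment$values)) / im_)^2)
}

#' Fit configuration
#'
#' Six parameters are free: `de1`, `de2`, `tau2`, `aratio`, `w0`, `gam`.
#' `tau1` (8.28 ps), `eps_inf` (2.5) and the measured `sigma0` are fixed:
#' in the analysis band only the high-frequency wing of the slow Debye band
#' is visible, so its time and strength cannot be separated, and `eps_inf`
#' is characteristic of dilute aqueous solutions near the oscillator band.
#' Solutions with conductivity below 0.008 S/m use `sigma0 = 0` exactly.
#'
#' Bounds are generous envelopes around the water values, chosen to prevent
#' the two Debye terms from swapping roles during optimisation.
#'
#' @param sigma0 fixed dc conductivity of the spectrum being fitted, S/m.
#' @param tau1,eps_inf fixed parameter values.
#' @param start `thz_params` supplying starting values of the free
#'   parameters (default: the pure-water reference row).
#' @param lower,upper named numeric vectors of bounds on the free parameters.
#' @param multistart number of optimiser starts; the first uses `start`
#'   unperturbed, the rest jitter each free parameter uniformly by up to
#'   +/-30% (clipped to the bounds).
#' @param seed integer seed for the jitter.
#' @return list of class `thz_fit_config`.
#' @export
fit_config <- function(sigma0 = 0, tau1 = 8.28, eps_inf = 2.5,
                       start = water_reference_params(),
                       lower = c(de1 = 20, de2 = 0.1, tau2 = 0.05,
                                 aratio = 0.3, w0 = 120, gam = 50),
                       upper = c(de1 = 120, de2 = 10, tau2 = 2,
                                 aratio = 5, w0 = 350, gam = 500),
                       multistart = 8, seed = 0) {
  free <- c("de1", "de2", "tau2", "aratio", "w0", "gam")
  stopifnot(all(free %in% names(lower)), all(free %in% names(upper)),
            multistart >= 1)
  structure(list(sigma0 = sigma0, tau1 = tau1, eps_inf = eps_inf,
                 start = start, lower = lower[free], upper = upper[free],
                 multistart = multistart, seed = seed, free = free),
            class = "thz_fit_config")
}

params_from_vector <- function(v, config) {
  dielectric_params(de1 = v[["de1"]], de2 = v[["de2"]], tau2 = v[["tau2"]],
                    aratio = v[["aratio"]], w0 = v[["w0"]], gam = v[["gam"]],
                    tau1 = config$tau1, eps_inf = config$eps_inf,
                    sigma0 = config$sigma0)
}

# evaluate seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fit the dielectric model to an experimental water-phase spectrum
#'
#' Bounded Levenberg-Marquardt least squares on the stacked relative
#' residuals (real and imaginary parts, each normalised by the model value),
#' whose mean of squares is exactly the criterion of [objective_s()].
#' Multistart: the best of `config$multistart` seeded starts is returned.
#'
#' @param experiment `thz_spectrum` of kind permittivity (the water phase).
#' @param config a [fit_config()].
#' @return list of class `thz_fit`: `params` (fitted `thz_params`), `s`
#'   (criterion at the optimum), `n_free_pct` (free-water percentage from the
#'   fitted parameters), `convergence` (per-start diagnostics), `config`.
#' @export
fit_model <- function(experiment, config = fit_config()) {
  stopifnot(inherits(experiment, "thz_spectrum"),
            experiment$kind == "permittivity")
  grid <- experiment$grid
  er <- Re(experiment$values); ei <- Im(experiment$values)

  resid_fun <- function(v) {
    names(v) <- config$free
    p <- params_from_vector(v, config)
    m <- eval_model(p, grid)$values
    c((Re(m) - er) / Re(m), (Im(m) - ei) / Im(m))
  }

  s0 <- config$start
  base <- c(de1 = s0$de1, de2 = s0$de2, tau2 = s0$tau2,
            aratio = s0$aratio, w0 = s0$w0, gam = s0$gam)
  starts <- with_seed(config$seed, {
    lapply(seq_len(config$multistart), function(k) {
      if (k == 1) return(base)
      v <- base * stats::runif(length(base), 0.7, 1.3)
      pmin(pmax(v, config$lower + 1e-9), config$upper - 1e-9)
    })
  })

  runs <- lapply(starts, function(st) {
    tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = config$lower, upper = config$upper,
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = 400, ftol = 1e-15, ptol = 1e-12)),
      error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all optimiser starts failed")
  N <- length(grid)
  svals <- vapply(runs[ok], function(r) sum(r$fvec^2) / N, numeric(1))
  best <- runs[ok][[which.min(svals)]]
  v <- stats::coef(best)
  names(v) <- config$free
  at_bound <- v <= config$lower + 1e-8 | v >= config$upper - 1e-8
  if (any(at_bound)) {
    warning("parameter(s) pinned at bounds: ",
            paste(config$free[at_bound], collapse = ", "))
  }
  params <- params_from_vector(v, config)
  structure(list(
    params = params,
    s = min(svals),
    n_free_pct = free_water_fraction(params),
    convergence = data.frame(
      start = which(ok), s = svals,
      info = vapply(runs[ok], function(r) r$info, numeric(1))),
    config = config
  ), class = "thz_fit")
}

#' @export
print.thz_fit <- function(x, ...) {
  cat(sprintf("<thz_fit> s=%.3g, free water n=%.2f%%\n", x$s, x$n_free_pct))
  print(x$params)
  invisible(x)
}

#' Share of free water molecules from fitted model parameters
#'
#' The fast-relaxation strength is converted into the percentage of water
#' molecules with unoccupied hydrogen-bond vacancies through
#' \deqn{n = \frac{3\Delta\epsilon_2}{(\Delta\epsilon_2+E)\,E}\cdot
#'       \frac{9 k T \epsilon_0}{N p^2}\times 100\%,\qquad
#'       E = \epsilon_\infty + A/\omega_0^2 + 2,}
#' where k is the Boltzmann constant, p the dipole moment of a water
#' molecule, N the number density of water molecules and T the temperature
#' (see [physical_constants()]).
#'
#' @param params a `thz_params` (only `de2`, `aratio`, `eps_inf` are used).
#' @param constants list from [physical_constants()]; its `T` sets the
#'   temperature.
#' @return free-water share in percent.
#' @seealso [free_water_from_strengths()] for the raw-number interface.
#' @export
free_water_fraction <- function(params, constants = physical_constants()) {
  stopifnot(inherits(params, "thz_params"))
  free_water_from_strengths(params$de2, params$aratio,
                            eps_inf = params$eps_inf, constants = constants)
}

#' @rdname free_water_fraction
#' @param de2 fast Debye strength.
#' @param aratio dimensionless oscillator contribution A/omega0^2.
#' @param eps_inf high-frequency permittivity.
#' @export
#' @examples
#' free_water_from_strengths(2.691, 1.702)  # pure water, ~3.78%
free_water_from_strengths <- function(de2, aratio, eps_inf = 2.5,
                                      constants = physical_constants()) {
  stopifnot(de2 >= 0, aratio > 0, eps_inf >= 1)
  E <- eps_inf + aratio + 2
  ratio <- 9 * constants$k * constants$T * constants$eps0 /
    (constants$N_water * constants$p^2)
  100 * 3 * de2 / ((de2 + E) * E) * ratio
}

#' Aggregate replicate fits into a summary with 95% confidence intervals
#'
#' For each reported parameter (the six free parameters, with the oscillator
#' as A/omega0^2, plus the free-water share) the replicate mean and the 95%
#' confidence half-width of the mean (t-distribution, n-1 degrees of freedom)
#' are computed.
#'
#' @param results list of `thz_fit` objects (>= 2 replicates).
#' @param sample label carried into the summary.
#' @return data.frame of class `thz_summary`: columns `sample`, `parameter`
#'   (ordered `de1`, `de2`, `tau2`, `w0`, `gam`, `aratio`, `n_pct`), `mean`,
#'   `ci95`, `n_replicates`.
#' @export
aggregate_replicates <- function(results, sample = "sample") {
  if (length(results) < 2) stop("need at least 2 replicates to aggregate")
  stopifnot(all(vapply(results, inherits, logical(1), "thz_fit")))
  pars <- c("de1", "de2", "tau2", "w0", "gam", "aratio", "n_pct")
  mat <- t(vapply(results, function(r) {
    c(r$params$de1, r$params$de2, r$params$tau2, r$params$w0,
      r$params$gam, r$params$aratio, r$n_free_pct)
  }, numeric(length(pars))))
  colnames(mat) <- pars
  nrep <- nrow(mat)
  tcrit <- stats::qt(0.975, df = nrep - 1)
  out <- data.frame(
    sample = sample,
    parameter = pars,
    mean = colMeans(mat),
    ci95 = tcrit * apply(mat, 2, stats::sd) / sqrt(nrep),
    n_replicates = nrep,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("thz_summary", class(out))
  out
}
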