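#' Noise model for synthetic replicates
#'
#' Two noise sources emulate replicate-to-replicate variability of the
#' measured water-phase spectra:
#' \itemize{
#'   \item multiplicative point noise of relative sd `sigma_rel` applied
#'     independently to the real and imaginary parts at every grid point
#'     (residual instrument noise after 1800-pulse averaging);
#'   \item replicate-level jitter of the generating model parameters with
#'     per-parameter sd `jitter_scale` times the reference 95% CI
#'     half-widths (slow drifts between replicate measurements, the dominant
#'     contribution to the published confidence intervals).
#' }
#' The default `jitter_scale` is sqrt(20)/qt(0.975, 19) ~ 2.14, the factor
#' that makes a 20-replicate t-interval reproduce the reference CI
#' magnitudes.
#'
#' @param sigma_rel relative point noise sd (>= 0).
#' @param jitter_scale replicate-level parameter jitter in units of the
#'   reference CI half-widths (>= 0).
#' @param seed integer seed; identical seeds give identical output.
#' @return list of class `thz_noise`.
#' @export
noise_model <- function(sigma_rel = 0.002,
                        jitter_scale = sqrt(20) / stats::qt(0.975, 19),
                        seed = 0) {
  stopifnot(sigma_rel >= 0, jitter_scale >= 0)
  structure(list(sigma_rel = sigma_rel, jitter_scale = jitter_scale,
                 seed = seed),
            class = "thz_noise")
}

#' Smooth solute permittivity model
#'
#' The dry-carbohydrate permittivity in the 10-110 cm^-1 band is smooth and
#' featureless (amorphous samples, no phonon bands — essential, since sharp
#' crystal resonances are absent in the dissolved state and would corrupt
#' the effective-medium subtraction). It is modelled by low-order polynomials
#' in wavenumber for the real and imaginary parts.
#'
#' @param coef_real,coef_imag polynomial coefficients (constant term first)
#'   in the scaled variable `(nu - 60)/50`, dimensionless.
#' @param preset `"monosaccharide"` (eps ~ 3.0 + 0.2i) or
#'   `"polysaccharide"` (eps ~ 2.6 + 0.15i); ignored when coefficients are
#'   given.
#' @return function `f(grid) -> thz_spectrum` of class `thz_solute_model`.
#' @export
solute_model <- function(preset = c("monosaccharide", "polysaccharide"),
                         coef_real = NULL, coef_imag = NULL) {
  preset <- match.arg(preset)
  if (is.null(coef_real)) {
    coef_real <- if (preset == "monosaccharide") c(3.0, 0.1) else c(2.6, 0.08)
  }
  if (is.null(coef_imag)) {
    coef_imag <- if (preset == "monosaccharide") c(0.20, 0.05)
                 else c(0.15, 0.04)
  }
  f <- function(grid) {
    if (!inherits(grid, "thz_grid")) grid <- frequency_grid(grid)
    x <- (as.numeric(grid) - 60) / 50
    pre <- vapply(seq_along(x), function(i)
      sum(coef_real * x[i]^(seq_along(coef_real) - 1)), numeric(1))
    pim <- vapply(seq_along(x), function(i)
      sum(coef_imag * x[i]^(seq_along(coef_imag) - 1)), numeric(1))
    if (any(pim < 0)) stop("solute model loss must be non-negative in band")
    complex_spectrum(grid, complex(real = pre, imaginary = pim),
                     kind = "permittivity",
                     meta = list(sample = paste0("solute_", preset)))
  }
  class(f) <- c("thz_solute_model", class(f))
  attr(f, "preset") <- preset
  f
}

jitter_params <- function(params, noise, replicate) {
  if (noise$jitter_scale == 0) return(params)
  ref <- reference_parameters()
  ref <- ref[ref$sample == "water", ]
  sds <- noise$jitter_scale *
    c(de1 = ref$ci_de1, de2 = ref$ci_de2, tau2 = ref$ci_tau2,
      w0 = ref$ci_w0, gam = ref$ci_gam, aratio = ref$ci_aratio)
  with_seed(noise$seed * 10000L + 7L * replicate, {
    z <- stats::rnorm(6)
    dielectric_params(
      de1 = max(params$de1 + sds[["de1"]] * z[1], 1e-3),
      de2 = max(params$de2 + sds[["de2"]] * z[2], 1e-3),
      tau2 = max(params$tau2 + sds[["tau2"]] * z[3], 1e-3),
      w0 = max(params$w0 + sds[["w0"]] * z[4], 1),
      gam = max(params$gam + sds[["gam"]] * z[5], 1),
      aratio = max(params$aratio + sds[["aratio"]] * z[6], 1e-3),
      tau1 = params$tau1, eps_inf = params$eps_inf, sigma0 = params$sigma0)
  })
}

#' Generate a synthetic water-phase spectrum
#'
#' Evaluates the dielectric model and applies the noise model. With
#' `sigma_rel = 0` and `jitter_scale = 0` the output is exactly the model
#' spectrum. Deterministic under the noise seed; replicate indices get
#' independent streams.
#'
#' @param params generating `thz_params`.
#' @param grid target `thz_grid`.
#' @param noise a [noise_model()] (default: noiseless).
#' @param replicate replicate index (selects the noise stream).
#' @return `thz_spectrum` of kind permittivity; the per-replicate generating
#'   parameters (after jitter) are attached as attribute `"true_params"`.
#' @export
make_water_phase <- function(params, grid, noise = noise_model(0, 0),
                             replicate = 1L) {
  stopifnot(inherits(params, "thz_params"), inherits(noise, "thz_noise"))
  if (!inherits(grid, "thz_grid")) grid <- frequency_grid(grid)
  p_rep <- jitter_params(params, noise, replicate)
  spec <- eval_model(p_rep, grid)
  if (noise$sigma_rel > 0) {
    vals <- with_seed(noise$seed * 10000L + 7L * replicate + 3L, {
      n <- length(grid)
      complex(real = Re(spec$values) * (1 + noise$sigma_rel * stats::rnorm(n)),
              imaginary = Im(spec$values) *
                (1 + noise$sigma_rel * stats::rnorm(n)))
    })
    spec <- complex_spectrum(grid, vals, kind = "permittivity", spec$meta)
  }
  spec$meta$replicate <- replicate
  attr(spec, "true_params") <- p_rep
  spec
}

#' Mix a water-phase spectrum with a solute into a solution spectrum
#'
#' Forward effective-medium mixing (geometry-dispatched); the inverse of the
#' analysis step, used to produce synthetic solution spectra.
#'
#' @param water water-phase `thz_spectrum`.
#' @param solute a [solute_model()] or a solute `thz_spectrum`.
#' @param f solute volume fraction.
#' @param geometry `"spherical"` or `"fiber"`.
#' @return solution `thz_spectrum` with geometry and f in its metadata.
#' @export
make_solution <- function(water, solute, f,
                          geometry = c("spherical", "fiber")) {
  geometry <- match.arg(geometry)
  eps_c <- if (inherits(solute, "thz_solute_model")) solute(water$grid)
           else solute
  mix <- mixture_spec(geometry, f, eps_c,
                      sigma0 = water$meta$sigma0_S_per_m %||% 0)
  medium_forward(water, mix)
}

#' Synthesise a dual-thickness time-domain pulse pair
#'
#' A band-limited Gaussian-derivative reference pulse is propagated (in the
#' frequency domain) through the solution layer of each cuvette: positive-
#' frequency components are multiplied by
#' `exp(-2 pi nu kappa l) * exp(-2i pi nu (n-1) l)` with `n + i kappa =
#' sqrt(eps)`, then inverse-transformed to time. Internal cuvette
#' reflections are omitted by default — the differential two-cuvette scheme
#' is designed to suppress them — but can be injected to study the error
#' they cause.
#'
#' @param eps_solution solution permittivity `thz_spectrum`; values outside
#'   its band are extended by their edge values.
#' @param l_thin_um,l_thick_um inter-window distances of the two cuvettes
#'   (defaults 50.06 and 100.26 um, differing by the 50.2 um effective
#'   thickness).
#' @param pulse list: `t0_ps` pulse centre, `tau_ps` width (Gaussian-
#'   derivative, amplitude spectrum peaking at `1/(2 pi tau)`), `dt_ps`
#'   sampling step, `span_ps` trace length.
#' @param noise a [noise_model()]; `sigma_rel` is applied as additive field
#'   noise relative to the pulse peak.
#' @param replicate replicate index for the noise stream.
#' @param etalon if TRUE, add the first internal (window-liquid-window)
#'   round-trip reflection.
#' @return list `(sample, background)` of `thz_trace` (sample = thick
#'   cuvette).
#' @export
make_pulse_pair <- function(eps_solution,
                            l_thin_um = 50.06, l_thick_um = 100.26,
                            pulse = list(t0_ps = 8, tau_ps = 0.12,
                                         dt_ps = 0.05, span_ps = 40),
                            noise = noise_model(0, 0), replicate = 1L,
                            etalon = FALSE) {
  if (!(l_thick_um > l_thin_um && l_thin_um > 0)) {
    stop("need l_thick_um > l_thin_um > 0")
  }
  cst <- physical_constants()
  dt_s <- pulse$dt_ps * 1e-12
  t_ps <- seq(0, pulse$span_ps - pulse$dt_ps, by = pulse$dt_ps)
  n <- length(t_ps)
  tt <- (t_ps - pulse$t0_ps) * 1e-12
  tau <- pulse$tau_ps * 1e-12
  ref <- -tt / tau^2 * exp(-tt^2 / (2 * tau^2))

  # band coverage check: amplitude spectrum omega*exp(-omega^2 tau^2/2)
  nu_max <- max(eps_solution$grid)
  w_max <- wavenumber_to_angular(nu_max)
  w_pk <- 1 / tau
  rel_amp <- (w_max / w_pk) * exp(-(w_max^2 - w_pk^2) * tau^2 / 2)
  if (rel_amp < 1e-6) {
    stop(sprintf(
      "pulse bandwidth insufficient: relative amplitude %.2g at %.4g cm-1",
      rel_amp, nu_max))
  }

  X <- stats::fft(ref)
  kpos <- seq_len(n %/% 2)                   # bins 2..n/2+1
  nu_cm <- kpos / (n * dt_s) / cst$c_cm
  nref <- sqrt(eps_solution$values)          # principal root: n,kappa >= 0
  n_of <- stats::approx(as.numeric(eps_solution$grid), Re(nref),
                        xout = nu_cm, rule = 2)$y
  k_of <- stats::approx(as.numeric(eps_solution$grid), Im(nref),
                        xout = nu_cm, rule = 2)$y

  propagate <- function(l_um) {
    l_cm <- l_um * 1e-4
    H <- exp(-2 * pi * nu_cm * k_of * l_cm) *
      exp(-2i * pi * nu_cm * (n_of - 1) * l_cm)
    if (etalon) {
      # one internal round trip between the windows (reflection at the
      # liquid/window interface approximated against vacuum)
      r <- (complex(real = n_of, imaginary = k_of) - 1) /
           (complex(real = n_of, imaginary = k_of) + 1)
      H <- H * (1 + r^2 * exp(-4 * pi * nu_cm * k_of * l_cm) *
                  exp(-4i * pi * nu_cm * n_of * l_cm))
    }
    Y <- X
    Y[kpos + 1] <- Y[kpos + 1] * H
    Y[n + 1 - kpos] <- Conj(Y[kpos + 1])
    if (n %% 2 == 0) Y[n / 2 + 1] <- complex(real = Re(Y[n / 2 + 1]))
    Re(stats::fft(Y, inverse = TRUE)) / n
  }

  add_noise <- function(y, offset) {
    if (noise$sigma_rel == 0) return(y)
    with_seed(noise$seed * 10000L + 7L * replicate + offset, {
      y + noise$sigma_rel * max(abs(ref)) * stats::rnorm(length(y))
    })
  }

  list(
    sample = time_trace(t_ps, add_noise(propagate(l_thick_um), 11L),
                        meta = list(thickness_um = l_thick_um)),
    background = time_trace(t_ps, add_noise(propagate(l_thin_um), 13L),
                            meta = list(thickness_um = l_thin_um))
  )
}

#' Simulate replicate solution spectra for a preset sample
#'
#' Generates `n_replicates` water-phase spectra from the preset's reference
#' parameters (with replicate noise), mixes each with the preset solute at
#' the preset volume fraction, and returns spectra plus ground truth.
#'
#' @param sample a row name of [reference_parameters()] (`"water"` skips the
#'   mixing stage).
#' @param n_replicates number of replicates (>= 1).
#' @param noise a [noise_model()].
#' @param grid analysis grid.
#' @return list of class `thz_simulation`: `solution` (list of spectra),
#'   `water` (list of noise-free... see details), `true_params` (list of
#'   per-replicate generating `thz_params`), `mixture` (`thz_mixture` or
#'   NULL), `sample`, `f`.
#' @export
simulate_replicates <- function(sample = "glucose", n_replicates = 20,
                                noise = noise_model(), grid = default_grid()) {
  ref <- reference_parameters()
  row <- ref[ref$sample == sample, ]
  if (nrow(row) != 1) stop("unknown sample '", sample, "'")
  params <- preset_params(sample)
  is_solution <- !is.na(row$geometry)
  mix <- NULL
  if (is_solution) {
    f <- volume_fraction(row$mass_conc_g_cm3, row$specific_volume_cm3_g)
    preset <- if (row$geometry == "spherical") "monosaccharide"
              else "polysaccharide"
    sol_model <- solute_model(preset)
    mix <- mixture_spec(row$geometry, f, sol_model(grid),
                        sigma0 = row$sigma0_S_per_m)
  }
  water <- vector("list", n_replicates)
  solution <- vector("list", n_replicates)
  truth <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    w <- make_water_phase(params, grid, noise, replicate = r)
    w$meta$sample <- sample
    truth[[r]] <- attr(w, "true_params")
    water[[r]] <- w
    solution[[r]] <- if (is_solution) medium_forward(w, mix) else w
  }
  structure(list(solution = solution, water = water, true_params = truth,
                 mixture = mix, sample = sample,
                 f = if (is_solution) mix$f else 0),
            class = "thz_simulation")
}
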