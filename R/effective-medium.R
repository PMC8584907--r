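#' Solution bookkeeping: volume fraction and molar concentration
#'
#' The volume fraction of the solute in solution is the product of its mass
#' concentration (g/cm^3) and its specific volume (cm^3/g). Typical specific
#' volumes: 0.62 cm^3/g for glucose and galactose, 0.60 for dextran and
#' amylopectin, 0.55 for galacturonic and polygalacturonic acids.
#'
#' @param mass_concentration g/cm^3, >= 0.
#' @param specific_volume cm^3/g, >= 0.
#' @return dimensionless volume fraction f.
#' @export
#' @examples
#' volume_fraction(0.050, 0.62)   # ~3% for a 50 mg/mL glucose solution
volume_fraction <- function(mass_concentration, specific_volume) {
  if (mass_concentration < 0 || specific_volume < 0) {
    stop("mass concentration and specific volume must be non-negative")
  }
  mass_concentration * specific_volume
}

#' @rdname volume_fraction
#' @param mass_conc_mg_ml mass concentration in mg/mL.
#' @param molar_mass_g_mol molar mass in g/mol.
#' @return `molar_concentration`: concentration in mM.
#' @export
#' @examples
#' molar_concentration(50, 180.16)  # 277.5 mM glucose
molar_concentration <- function(mass_conc_mg_ml, molar_mass_g_mol) {
  stopifnot(mass_conc_mg_ml >= 0, molar_mass_g_mol > 0)
  mass_conc_mg_ml / molar_mass_g_mol * 1000
}

#' Mixture specification for effective-medium subtraction
#'
#' @param geometry `"spherical"` (Maxwell Garnett, monosaccharides and other
#'   small or chaotically oriented inclusions) or `"fiber"` (low-concentration
#'   fiber-inclusion model, polysaccharides).
#' @param f solute volume fraction, `0 <= f < 0.3` (both models are dilute
#'   approximations; the intended operating point is f ~ 0.03).
#' @param solute_eps `thz_spectrum` of the dry solute permittivity, on the
#'   same grid as the solution spectra it will be combined with.
#' @param sigma0 dc conductivity of the solution, S/m (carried through to
#'   fitting; not used by the mixing rules themselves).
#' @return object of class `thz_mixture`.
#' @export
mixture_spec <- function(geometry = c("spherical", "fiber"), f,
                         solute_eps, sigma0 = 0) {
  geometry <- match.arg(geometry)
  if (f < 0 || f >= 0.3) {
    stop("volume fraction must satisfy 0 <= f < 0.3 (dilute models)")
  }
  if (f > 0.1) warning("f > 0.1: outside the validated dilute range")
  stopifnot(inherits(solute_eps, "thz_spectrum"), sigma0 >= 0)
  structure(list(geometry = geometry, f = f, solute_eps = solute_eps,
                 sigma0 = sigma0),
            class = "thz_mixture")
}

# ---- Maxwell Garnett (spherical inclusions) -------------------------------

#' Maxwell Garnett mixing for spherical inclusions
#'
#' Forward map: given host (water-phase) permittivity `eps_w`, inclusion
#' permittivity `eps_c` and volume fraction `f`, the mixture permittivity
#' `eps_s` solves
#' \deqn{\frac{\epsilon_s-\epsilon_w}{\epsilon_s+2\epsilon_w} =
#'       f\,\frac{\epsilon_c-\epsilon_w}{\epsilon_c+2\epsilon_w}.}
#' The closed form is `eps_s = eps_w (1+2F)/(1-F)` with
#' `F = f (eps_c-eps_w)/(eps_c+2 eps_w)`. Vectorised over grid points.
#'
#' @param eps_w,eps_c complex host and inclusion permittivities.
#' @param f volume fraction, `0 <= f < 1`.
#' @return complex mixture permittivity `eps_s`.
#' @export
mg_forward <- function(eps_w, eps_c, f) {
  stopifnot(all(f >= 0), all(f < 1))
  den <- eps_c + 2 * eps_w
  if (any(Mod(den) < 1e-300)) stop("degenerate input: eps_c + 2*eps_w = 0")
  F <- f * (eps_c - eps_w) / den
  eps_w * (1 + 2 * F) / (1 - F)
}

# select the physical root per grid point: non-negative loss, positive eps',
# closest to `ref`, then continuity along the grid
select_root <- function(r1, r2, ref) {
  n <- length(r1)
  pick <- complex(n)
  for (i in seq_len(n)) {
    cand <- c(r1[i], r2[i])
    ok <- Im(cand) >= -1e-9 & Re(cand) > 0
    if (!any(ok)) {
      stop(sprintf(
        "no physical root at grid point %d (roots %s, %s)",
        i, format(cand[1]), format(cand[2])))
    }
    cand <- cand[ok]
    if (length(cand) == 2) {
      target <- if (i > 1) pick[i - 1] else ref[i]
      cand <- cand[order(Mod(cand - target))]
    }
    pick[i] <- cand[1]
  }
  pick
}

#' Invert the Maxwell Garnett relation for the host permittivity
#'
#' Clearing denominators in the Maxwell Garnett relation gives a complex
#' quadratic in `eps_w`:
#' \deqn{2(f-1)\,\epsilon_w^2 + [(2+f)\epsilon_s-(1+2f)\epsilon_c]\,\epsilon_w
#'       + (1-f)\epsilon_s\epsilon_c = 0.}
#' Both roots are computed; the physical one (non-negative loss, positive real
#' part, closest to `eps_s`, continuous along the grid) is returned.
#'
#' @inheritParams mg_forward
#' @param eps_s complex mixture (solution) permittivity.
#' @return complex host (water-phase) permittivity `eps_w`.
#' @export
mg_invert <- function(eps_s, eps_c, f) {
  stopifnot(f >= 0, f < 1)
  if (f == 0) return(eps_s)
  a2 <- 2 * (f - 1)
  a1 <- (2 + f) * eps_s - (1 + 2 * f) * eps_c
  a0 <- (1 - f) * eps_s * eps_c
  disc <- sqrt(a1^2 - 4 * a2 * a0)
  select_root((-a1 + disc) / (2 * a2), (-a1 - disc) / (2 * a2), eps_s)
}

# ---- fiber inclusions (dilute limit) --------------------------------------

#' Effective-medium mixing for dilute fiber-like inclusions
#'
#' Dilute limit of the fiber-inclusion effective-medium model used for
#' polysaccharide solutions:
#' \deqn{\epsilon_s = \epsilon_w +
#'   f\,\frac{(\epsilon_c-\epsilon_w)(5\epsilon_w+\epsilon_c)}
#'           {3(\epsilon_w+\epsilon_c)}.}
#'
#' @inheritParams mg_forward
#' @return complex mixture permittivity `eps_s`.
#' @export
fiber_forward <- function(eps_w, eps_c, f) {
  stopifnot(all(f >= 0))
  if (any(f > 0.3)) warning("f > 0.3: beyond the dilute fiber approximation")
  den <- eps_w + eps_c
  if (any(Mod(den) < 1e-300)) stop("degenerate input: eps_w + eps_c = 0")
  eps_w + f * (eps_c - eps_w) * (5 * eps_w + eps_c) / (3 * den)
}

# quadratic coefficients of the fiber relation in eps_w:
# (3-5f) eps_w^2 + [(3+4f) eps_c - 3 eps_s] eps_w + f eps_c^2 - 3 eps_s eps_c = 0
fiber_quad_coefs <- function(eps_s, eps_c, f) {
  list(a2 = 3 - 5 * f,
       a1 = (3 + 4 * f) * eps_c - 3 * eps_s,
       a0 = f * eps_c^2 - 3 * eps_s * eps_c)
}

#' Invert the fiber-inclusion mixing relation
#'
#' `fiber_invert()` returns the host permittivity satisfying the fiber
#' forward relation exactly: the relation is a complex quadratic in `eps_w`
#' and the physical root is selected as in [mg_invert()].
#'
#' `fiber_invert_closed()` is the explicit closed form of the same root,
#' written with the real auxiliary quantities
#' `a = (3+4f) eps_c' - 3 eps_s'`, `b = (3+4f) eps_c'' - 3 eps_s''`,
#' `c, d` (real and imaginary parts of one third of the discriminant) and
#' `e = 2(5f-3)`:
#' \deqn{\epsilon_w' = \frac{1}{e}\Big(a - \sqrt{\tfrac32\big(\sqrt{c^2+d^2}+c\big)}\Big),\quad
#'       \epsilon_w'' = \frac{1}{e}\Big(b - \mathrm{sgn}(d)\sqrt{\tfrac32\big(\sqrt{c^2+d^2}-c\big)}\Big).}
#' The `sgn(d)` factor makes the expression the principal complex square root
#' for either sign of `d`; for physical spectra `d > 0`. The two routes agree
#' to machine precision and are cross-checked in the test-suite.
#'
#' @inheritParams mg_invert
#' @return complex host permittivity `eps_w`.
#' @export
fiber_invert <- function(eps_s, eps_c, f) {
  stopifnot(f >= 0, f < 0.6)   # e = 2(5f-3) must stay away from 0
  if (f == 0) return(eps_s)
  co <- fiber_quad_coefs(eps_s, eps_c, f)
  disc <- sqrt(co$a1^2 - 4 * co$a2 * co$a0)
  select_root((-co$a1 + disc) / (2 * co$a2),
              (-co$a1 - disc) / (2 * co$a2), eps_s)
}

#' @rdname fiber_invert
#' @export
fiber_invert_closed <- function(eps_s, eps_c, f) {
  es1 <- Re(eps_s); es2 <- Im(eps_s)
  ec1 <- Re(eps_c); ec2 <- Im(eps_c)
  a <- (3 + 4 * f) * ec1 - 3 * es1
  b <- (3 + 4 * f) * ec2 - 3 * es2
  cc <- 3 * (es1^2 - es2^2) + (6 - 28 * f) * ec1 * es1 -
    2 * (3 - 14 * f) * ec2 * es2 +
    (3 + 4 * f + 12 * f^2) * (ec1^2 - ec2^2)
  d <- (6 - 28 * f) * ec2 * es1 + 6 * es1 * es2 +
    ec1 * ((6 - 28 * f) * es2 + (6 + 8 * f + 24 * f^2) * ec2)
  e <- 2 * (5 * f - 3)
  hyp <- sqrt(cc^2 + d^2)
  sgn <- ifelse(d >= 0, 1, -1)
  ew1 <- (a - sqrt(1.5 * (hyp + cc))) / e
  ew2 <- (b - sgn * sqrt(pmax(1.5 * (hyp - cc), 0))) / e
  complex(real = ew1, imaginary = ew2)
}

#' Apply / remove the solute contribution of a mixture
#'
#' Convenience wrappers dispatching on the mixture geometry; operate on whole
#' spectra and keep metadata.
#'
#' @param water,solution `thz_spectrum` of kind permittivity.
#' @param mixture a [mixture_spec()].
#' @return a `thz_spectrum`: the mixed solution (`medium_forward`) or the
#'   recovered water phase (`medium_invert`).
#' @export
medium_forward <- function(water, mixture) {
  stopifnot(inherits(water, "thz_spectrum"), inherits(mixture, "thz_mixture"))
  check_same_grid(water, mixture$solute_eps)
  fun <- if (mixture$geometry == "spherical") mg_forward else fiber_forward
  vals <- fun(water$values, mixture$solute_eps$values, mixture$f)
  meta <- water$meta
  meta$geometry <- mixture$geometry
  meta$f <- mixture$f
  meta$sigma0_S_per_m <- mixture$sigma0
  complex_spectrum(water$grid, vals, kind = "permittivity", meta = meta)
}

#' @rdname medium_forward
#' @export
medium_invert <- function(solution, mixture) {
  stopifnot(inherits(solution, "thz_spectrum"),
            inherits(mixture, "thz_mixture"))
  check_same_grid(solution, mixture$solute_eps)
  fun <- if (mixture$geometry == "spherical") mg_invert else fiber_invert
  vals <- fun(solution$values, mixture$solute_eps$values, mixture$f)
  # tolerate tiny negative loss from cancellation near f -> 0
  vals[Im(vals) < 0 & Im(vals) > -1e-9] <-
    complex(real = Re(vals[Im(vals) < 0 & Im(vals) > -1e-9]), imaginary = 0)
  meta <- solution$meta
  meta$geometry <- NULL
  complex_spectrum(solution$grid, vals, kind = "permittivity", meta = meta)
}

check_same_grid <- function(x, y) {
  if (length(x$grid) != length(y$grid) ||
      max(abs(as.numeric(x$grid) - as.numeric(y$grid))) > 1e-9) {
    stop("spectra must share the same frequency grid")
  }
  invisible(TRUE)
}
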