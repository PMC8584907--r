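#' Fourier amplitude spectrum of a time-domain trace
#'
#' Computes the discrete Fourier transform of a pulse (zero-padded), then
#' interpolates amplitude and unwrapped phase onto the requested wavenumber
#' grid. Interpolating amplitude and unwrapped phase separately (rather than
#' real/imaginary parts) keeps the phase smooth between DFT bins, which
#' matters because the refractive index is read off the phase.
#'
#' The DFT convention is `stats::fft`: a delay by `dt` multiplies the
#' positive-frequency spectrum by `exp(-2i pi f dt)`.
#'
#' @param trace a [time_trace()].
#' @param grid target `thz_grid` (cm^-1); its maximum must lie below the
#'   Nyquist wavenumber `1/(2 c dt)`.
#' @param window `"none"` (default) or `"hann"` (Hann taper over the trailing
#'   half of the trace, suppressing truncation ripple from late reflections).
#' @param pad_to zero-padded transform length (default 4096, or the next
#'   power of two above the trace length if longer).
#' @return a `thz_spectrum` of kind `"amplitude"`; attribute `"phase"` holds
#'   the unwrapped phase (rad) on the grid.
#' @export
fourier_spectrum <- function(trace, grid, window = c("none", "hann"),
                             pad_to = 4096) {
  window <- match.arg(window)
  stopifnot(inherits(trace, "thz_trace"))
  if (!inherits(grid, "thz_grid")) grid <- frequency_grid(grid)
  c_cm <- physical_constants()$c_cm
  dt_s <- (trace$time_ps[2] - trace$time_ps[1]) * 1e-12
  nyquist_cm <- 1 / (2 * dt_s * c_cm)
  if (max(grid) >= nyquist_cm) {
    stop(sprintf("grid maximum %.3g cm-1 exceeds Nyquist limit %.3g cm-1",
                 max(grid), nyquist_cm))
  }
  x <- trace$field
  n0 <- length(x)
  if (window == "hann") {
    half <- seq_len(n0) > n0 / 2
    idx <- seq_len(sum(half))
    x[half] <- x[half] * 0.5 * (1 + cos(pi * idx / sum(half)))
  }
  nfft <- max(pad_to, 2^ceiling(log2(n0)))
  X <- stats::fft(c(x, rep(0, nfft - n0)))
  pos <- seq_len(nfft %/% 2)          # positive-frequency bins (excl. DC)
  f_hz <- (pos) / (nfft * dt_s)       # bin i+1 -> frequency i/(N dt)
  nu_cm <- f_hz / c_cm
  Xp <- X[pos + 1]
  amp <- stats::approx(nu_cm, Mod(Xp), xout = as.numeric(grid))$y
  ph_raw <- signal::unwrap(Arg(Xp))
  ph <- stats::approx(nu_cm, ph_raw, xout = as.numeric(grid))$y
  # include the time origin so phase is referenced to absolute t, not sample 1
  ph <- ph - 2 * pi * as.numeric(grid) * c_cm * trace$time_ps[1] * 1e-12
  out <- complex_spectrum(grid, amp * exp(1i * ph), kind = "amplitude",
                          meta = trace$meta)
  attr(out, "phase") <- ph
  out
}

#' Optical pair (transmission + refractive index) from a dual-thickness
#' pulse pair
#'
#' The differential two-cuvette scheme: the same solution is measured in two
#' cuvettes whose inter-window distances differ by `dl_um`. The thick-cuvette
#' trace acts as "sample" and the thin-cuvette trace as "background", so that
#' windows, reflections at the window/liquid interface, and the source
#' spectrum cancel, leaving the response of a solution layer of thickness
#' `dl_um`.
#'
#' Transmission is reported as POWER transmission (the squared field-amplitude
#' ratio), the convention under which the permittivity formulae of
#' [permittivity_from_optics()] are exact. The refractive index comes from the
#' unwrapped phase difference, `n = 1 + dphi/(2 pi nu dl)`; the residual 2*pi
#' branch is fixed by requiring `n >= 1` and picking the branch closest to a
#' water-like band-average index (see `n_anchor`).
#'
#' @param sample trace through the thick cuvette.
#' @param background trace through the thin cuvette.
#' @param dl_um thickness difference (um), > 0.
#' @param grid analysis `thz_grid`.
#' @param window passed to [fourier_spectrum()].
#' @param n_anchor expected band-average refractive index used to resolve the
#'   2*pi phase ambiguity (default 2.3, mid water-like range).
#' @return list of class `thz_optical_pair` with elements `transmission`,
#'   `index` (both `thz_spectrum`) and `effective_thickness_um`.
#' @export
optics_from_pair <- function(sample, background, dl_um, grid,
                             window = "none", n_anchor = 2.3) {
  if (dl_um <= 0) stop("dl_um must be > 0")
  if (!inherits(grid, "thz_grid")) grid <- frequency_grid(grid)
  S <- fourier_spectrum(sample, grid, window = window)
  B <- fourier_spectrum(background, grid, window = window)
  bad <- Mod(B$values) <= .Machine$double.eps *
    max(Mod(B$values), .Machine$double.xmin)
  if (any(bad)) {
    stop(sprintf("background amplitude vanishes at %.4g cm-1",
                 as.numeric(grid)[which(bad)[1]]))
  }
  nu <- as.numeric(grid)
  dl_cm <- dl_um * 1e-4
  tr_amp <- Mod(S$values) / Mod(B$values)
  # phase lag of the sample relative to the background: positive for n > 1
  dphi <- attr(B, "phase") - attr(S, "phase")
  n_raw <- 1 + dphi / (2 * pi * nu * dl_cm)
  # residual 2*pi branch: adding 2*pi*m to dphi shifts n by m/(nu*dl)
  m_cand <- -5:5
  score <- vapply(m_cand, function(m) {
    nm <- n_raw + m / (nu * dl_cm)
    if (any(nm < 1)) Inf else mean(abs(nm - n_anchor))
  }, numeric(1))
  if (all(!is.finite(score))) {
    score <- vapply(m_cand, function(m)
      mean(abs(n_raw + m / (nu * dl_cm) - n_anchor)), numeric(1))
  }
  n_val <- n_raw + m_cand[which.min(score)] / (nu * dl_cm)
  structure(list(
    transmission = complex_spectrum(grid, tr_amp^2, kind = "transmission",
                                    meta = sample$meta),
    index = complex_spectrum(grid, n_val, kind = "refractive_index",
                             meta = sample$meta),
    effective_thickness_um = dl_um
  ), class = "thz_optical_pair")
}

#' Complex permittivity from transmission and refractive index
#'
#' For a layer of thickness l (cm) with power transmission Tr and refractive
#' index n at wavenumber nu (cm^-1):
#' \deqn{\epsilon' = n^2 - [\ln Tr/(4\pi\nu l)]^2, \quad
#'       \epsilon'' = -n \ln Tr/(2\pi\nu l),}
#' which is exactly \eqn{(n + i\kappa)^2} with the extinction coefficient
#' \eqn{\kappa = -\ln Tr/(4\pi\nu l)}.
#'
#' @param pair a `thz_optical_pair` from [optics_from_pair()], or a list with
#'   elements `transmission`, `index`, `effective_thickness_um`.
#' @return `thz_spectrum` of kind `"permittivity"`.
#' @export
permittivity_from_optics <- function(pair) {
  tr <- Re(pair$transmission$values)
  n <- Re(pair$index$values)
  if (any(tr <= 0)) stop("transmission must be strictly positive")
  nu <- as.numeric(pair$transmission$grid)
  l_cm <- pair$effective_thickness_um * 1e-4
  kappa <- -log(tr) / (4 * pi * nu * l_cm)
  eps <- complex(real = n^2 - kappa^2, imaginary = 2 * n * kappa)
  meta <- pair$transmission$meta
  meta$thickness_um <- pair$effective_thickness_um
  complex_spectrum(pair$transmission$grid, eps, kind = "permittivity",
                   meta = meta)
}

#' Cuvette gap thickness from etalon fringes
#'
#' An empty cuvette acts as a Fabry-Perot etalon: multiple reflections
#' between the parallel windows imprint interference fringes on the
#' transmission spectrum with spacing `dnu = 1/(2 n_gap d)` (d in cm). The
#' gap is recovered from the mean fringe spacing of detected transmission
#' maxima: the maxima positions are regressed on their index, the slope being
#' the spacing. The quoted uncertainty is the standard error of the
#' individual fringe intervals.
#'
#' @param empty_cuvette_spectrum `thz_spectrum` of kind `"transmission"`
#'   covering enough band to show at least 3 fringe maxima.
#' @param n_gap refractive index of the gap medium (1 for air).
#' @param smooth_span width (points) of the running-mean smoother applied
#'   before peak detection; 1 disables smoothing.
#' @return list with `thickness_um`, `thickness_se_um`, `fringe_spacing_cm`,
#'   `n_fringes`.
#' @export
etalon_thickness <- function(empty_cuvette_spectrum, n_gap = 1,
                             smooth_span = 5) {
  stopifnot(inherits(empty_cuvette_spectrum, "thz_spectrum"))
  nu <- as.numeric(empty_cuvette_spectrum$grid)
  y <- Re(empty_cuvette_spectrum$values)
  if (smooth_span > 1) {
    y <- stats::filter(y, rep(1 / smooth_span, smooth_span), sides = 2)
    keep <- !is.na(y)
    y <- as.numeric(y[keep]); nu <- nu[keep]
  }
  # coarse fringe-period estimate from the periodogram of the detrended
  # signal, used only to set the minimum separation between extrema
  dnu <- stats::median(diff(nu))
  n <- length(y)
  ydt <- y - mean(y)
  wide <- max(5, round(n / 8))
  base <- stats::filter(ydt, rep(1 / wide, wide), sides = 2)
  ok <- !is.na(base)
  ydt[ok] <- ydt[ok] - base[ok]
  P <- Mod(stats::fft(ydt))^2
  kmax <- which.max(P[2:(n %/% 2)])          # skip the DC bin
  spacing_est <- n * dnu / kmax
  minsep <- max(1, floor(0.6 * spacing_est / dnu))
  pk <- pracma::findpeaks(y, minpeakdistance = minsep)
  if (is.null(pk) || nrow(pk) < 3) {
    stop("fewer than 3 etalon fringes detected; need a wider band")
  }
  peak_nu <- sort(nu[pk[, 2]])
  fit <- stats::lm(peak_nu ~ seq_along(peak_nu))
  spacing <- unname(stats::coef(fit)[2])
  intervals <- diff(peak_nu)
  se_spacing <- stats::sd(intervals) / sqrt(length(intervals))
  d_cm <- 1 / (2 * n_gap * spacing)
  list(thickness_um = d_cm * 1e4,
       thickness_se_um = d_cm * 1e4 * se_spacing / spacing,
       fringe_spacing_cm = spacing,
       n_fringes = length(peak_nu))
}
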