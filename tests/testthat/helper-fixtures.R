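# shared fixtures: random physical permittivities and a reference water spectrum

rand_eps <- function(n, re_range = c(1, 10), im_range = c(0.05, 10)) {
  complex(real = stats::runif(n, re_range[1], re_range[2]),
          imaginary = stats::runif(n, im_range[1], im_range[2]))
}

water_spectrum <- function(grid = default_grid()) {
  eval_model(water_reference_params(), grid)
}

# fit configuration whose starting point is NOT the truth, so that
# self-consistency tests exercise the optimiser rather than the start
offset_fit_config <- function(...) {
  start <- dielectric_params(de1 = 55, de2 = 2.0, tau2 = 0.45,
                             aratio = 1.3, w0 = 240, gam = 160)
  fit_config(start = start, ...)
}
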