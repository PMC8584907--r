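#' Frequency grid in wavenumbers
#'
#' A strictly increasing vector of wavenumbers (cm^-1) on which all spectra
#' live. The default analysis grid spans 10-110 cm^-1 on 250 points, the band
#' where the two Debye wings and the low-frequency tail of the intermolecular
#' stretching band of water are all visible.
#'
#' @param wavenumbers_cm numeric vector of wavenumbers, cm^-1, strictly
#'   increasing and strictly positive (the conductivity term of the dielectric
#'   model diverges at zero frequency).
#' @return numeric vector of class `thz_grid`.
#' @export
#' @examples
#' g <- default_grid()
#' range(g); length(g)
frequency_grid <- function(wavenumbers_cm) {
  wavenumbers_cm <- as.numeric(wavenumbers_cm)
  if (length(wavenumbers_cm) < 1 || any(!is.finite(wavenumbers_cm))) {
    stop("grid must be a non-empty finite numeric vector")
  }
  if (any(wavenumbers_cm <= 0)) {
    stop("all wavenumbers must be > 0")
  }
  if (length(wavenumbers_cm) > 1 && any(diff(wavenumbers_cm) <= 0)) {
    stop("wavenumbers must be strictly increasing")
  }
  structure(wavenumbers_cm, class = "thz_grid")
}

#' @rdname frequency_grid
#' @param from,to,n grid limits (cm^-1) and number of points for the default
#'   analysis grid.
#' @export
default_grid <- function(from = 10, to = 110, n = 250) {
  frequency_grid(seq(from, to, length.out = n))
}

#' Complex spectrum on a frequency grid
#'
#' Container for a frequency-resolved quantity: complex permittivity
#' (convention eps* = eps' + i eps'', so passive media have eps'' >= 0),
#' power transmission, refractive index, or a raw complex field amplitude.
#'
#' @param grid a `thz_grid` (or numeric vector passed to [frequency_grid()]).
#' @param values complex (or numeric) vector, same length as `grid`.
#' @param kind one of `"permittivity"`, `"transmission"`,
#'   `"refractive_index"`, `"amplitude"`.
#' @param meta named list of metadata (sample label, thickness_um,
#'   temperature_K, sigma0_S_per_m, ...).
#' @return object of class `thz_spectrum`: list with elements `grid`,
#'   `values`, `kind`, `meta`.
#' @export
#' @examples
#' g <- default_grid(n = 50)
#' s <- complex_spectrum(g, complex(real = 4 + 0 * g, imaginary = 1 + 0 * g))
complex_spectrum <- function(grid, values,
                             kind = c("permittivity", "transmission",
                                      "refractive_index", "amplitude"),
                             meta = list()) {
  kind <- match.arg(kind)
  if (!inherits(grid, "thz_grid")) grid <- frequency_grid(grid)
  values <- as.complex(values)
  if (length(values) != length(grid)) {
    stop("values and grid must have the same length")
  }
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values)))) {
    stop("spectrum values must be finite")
  }
  if (kind == "permittivity" && any(Im(values) < -1e-9)) {
    stop("permittivity of a passive medium must have non-negative imaginary part")
  }
  if (kind == "transmission") {
    if (any(Re(values) <= 0)) stop("transmission must be strictly positive")
    if (any(Re(values) > 1 + 1e-9)) {
      warning("transmission exceeds 1 at ", sum(Re(values) > 1 + 1e-9),
              " grid point(s)")
    }
  }
  structure(list(grid = grid, values = values, kind = kind,
                 meta = as.list(meta)),
            class = "thz_spectrum")
}

#' @export
print.thz_spectrum <- function(x, ...) {
  cat(sprintf("<thz_spectrum> kind=%s, %d points, %.4g-%.4g cm-1\n",
              x$kind, length(x$grid), min(x$grid), max(x$grid)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Time-domain electric-field trace
#'
#' Sampled electric field of a picosecond pulse, the raw observable of
#' THz time-domain spectroscopy.
#'
#' @param time_ps uniformly spaced time axis in picoseconds, length >= 64.
#' @param field electric field in arbitrary units, same length.
#' @param meta named list (cuvette inter-window distance `thickness_um`,
#'   averaging count, ...).
#' @return object of class `thz_trace`.
#' @export
time_trace <- function(time_ps, field, meta = list()) {
  time_ps <- as.numeric(time_ps)
  field <- as.numeric(field)
  if (length(time_ps) < 64) stop("trace must have at least 64 samples")
  if (length(field) != length(time_ps)) {
    stop("time and field vectors must have the same length")
  }
  dt <- diff(time_ps)
  if (any(!is.finite(dt)) ||
      max(abs(dt - dt[1])) > 1e-9 * abs(dt[1])) {
    stop("time axis must be uniformly spaced")
  }
  if (dt[1] <= 0) stop("time axis must be increasing")
  structure(list(time_ps = time_ps, field = field, meta = as.list(meta)),
            class = "thz_trace")
}

#' @export
print.thz_trace <- function(x, ...) {
  cat(sprintf("<thz_trace> %d samples, dt=%.4g ps, span %.4g ps\n",
              length(x$time_ps), x$time_ps[2] - x$time_ps[1],
              diff(range(x$time_ps))))
  invisible(x)
}

# ---- file I/O -------------------------------------------------------------
# Format: '#'-prefixed 'key: value' metadata header, then a CSV header line
# and the numeric table. Deterministic column order and number formatting so
# that repeated writes are byte-identical.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_header <- function(con, meta) {
  for (nm in names(meta)) {
    cat(sprintf("# %s: %s\n", nm, format(meta[[nm]])), file = con)
  }
}

read_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Write a spectrum to a header-commented CSV file
#'
#' Columns are `wavenumber_cm-1` followed by `eps_real, eps_imag`
#' (permittivity / amplitude), `transmission`, or `n` depending on the kind.
#' Metadata are written as `# key: value` lines before the header. Two writes
#' of the same spectrum are byte-identical.
#'
#' @param spectrum a `thz_spectrum`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "thz_spectrum"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write_header(con, c(list(kind = spectrum$kind), spectrum$meta))
  g <- fmt_num(as.numeric(spectrum$grid))
  if (spectrum$kind %in% c("permittivity", "amplitude")) {
    cat("wavenumber_cm-1,eps_real,eps_imag\n", file = con)
    cat(paste(g, fmt_num(Re(spectrum$values)), fmt_num(Im(spectrum$values)),
              sep = ","), sep = "\n", file = con)
  } else {
    col <- if (spectrum$kind == "transmission") "transmission" else "n"
    cat(sprintf("wavenumber_cm-1,%s\n", col), file = con)
    cat(paste(g, fmt_num(Re(spectrum$values)), sep = ","),
        sep = "\n", file = con)
  }
  invisible(path)
}

#' Read a spectrum from a header-commented CSV file
#'
#' @param path file written by [write_spectrum()] (or hand-made in the same
#'   layout).
#' @param kind expected kind; defaults to the `kind` recorded in the header,
#'   falling back to `"permittivity"`.
#' @return a `thz_spectrum`.
#' @export
read_spectrum <- function(path, kind = NULL) {
  lines <- readLines(path)
  meta <- read_header(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("no data rows in ", path)
  df <- utils::read.csv(text = body, check.names = FALSE)
  if (!"wavenumber_cm-1" %in% names(df)) {
    stop("missing 'wavenumber_cm-1' column in ", path)
  }
  if (is.null(kind)) kind <- meta$kind %||% "permittivity"
  meta$kind <- NULL
  grid <- frequency_grid(df[["wavenumber_cm-1"]])
  if (all(c("eps_real", "eps_imag") %in% names(df))) {
    vals <- complex(real = df$eps_real, imaginary = df$eps_imag)
  } else if ("transmission" %in% names(df)) {
    vals <- as.complex(df$transmission)
  } else if ("n" %in% names(df)) {
    vals <- as.complex(df$n)
  } else {
    stop("no recognised value columns in ", path)
  }
  complex_spectrum(grid, vals, kind = kind, meta = meta)
}

#' Write / read a time-domain trace
#'
#' Same header scheme as spectra; columns `time_ps, field_au`.
#'
#' @param trace a `thz_trace`.
#' @param path file path.
#' @return `write_trace`: invisibly `path`; `read_trace`: a `thz_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "thz_trace"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write_header(con, trace$meta)
  cat("time_ps,field_au\n", file = con)
  cat(paste(fmt_num(trace$time_ps), fmt_num(trace$field), sep = ","),
      sep = "\n", file = con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- read_header(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = body, check.names = FALSE)
  if (!all(c("time_ps", "field_au") %in% names(df))) {
    stop("trace file must have columns time_ps, field_au")
  }
  time_trace(df$time_ps, df$field_au, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
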