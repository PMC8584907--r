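#' Run configuration for the full analysis pipeline
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Exactly one of `f` or the pair (`mass_conc_g_cm3`,
#' `specific_volume_cm3_g`) must be provided when an effective-medium
#' inversion stage runs; `geometry` is required in that case too.
#'
#' @param input one of:
#'   \itemize{
#'     \item `list(simulate = list(sample=, n_replicates=, ...))` — generate
#'       inputs with [simulate_replicates()];
#'     \item `list(solution_files = c(...))` — paths to solution permittivity
#'       CSVs (one per replicate);
#'     \item `list(trace_pairs = list(list(sample=, background=), ...),
#'       dl_um =)` — paths to time-trace CSV pairs, processed through the
#'       time-domain stage first.
#'   }
#' @param geometry `"spherical"`, `"fiber"` or `NA` (no inversion stage,
#'   e.g. pure water).
#' @param f solute volume fraction; alternative to the concentration pair.
#' @param mass_conc_g_cm3,specific_volume_cm3_g mass concentration and
#'   specific volume from which `f` is computed.
#' @param solute_file path to the dry-solute permittivity CSV; default uses
#'   the built-in [solute_model()] preset matching the geometry.
#' @param sigma0 dc conductivity (S/m) passed to the fit; values below
#'   0.008 S/m are treated as exactly zero.
#' @param grid analysis grid.
#' @param fit a [fit_config()] (its `sigma0` is overwritten by the
#'   pipeline-level value).
#' @param out_dir output directory, or `NULL` for an in-memory run.
#' @param sample_label label used in reports.
#' @param seed integer seed recorded in the manifest and used for simulation.
#' @return list of class `thz_run_config`.
#' @export
run_config <- function(input, geometry = NA, f = NULL,
                       mass_conc_g_cm3 = NULL, specific_volume_cm3_g = NULL,
                       solute_file = NULL, sigma0 = 0,
                       grid = default_grid(), fit = fit_config(),
                       out_dir = NULL, sample_label = "sample", seed = 0) {
  has_f <- !is.null(f)
  has_cv <- !is.null(mass_conc_g_cm3) || !is.null(specific_volume_cm3_g)
  if (has_f && has_cv) {
    stop("provide either f or (mass_conc_g_cm3, specific_volume_cm3_g), not both")
  }
  if (has_cv) {
    if (is.null(mass_conc_g_cm3) || is.null(specific_volume_cm3_g)) {
      stop("mass_conc_g_cm3 and specific_volume_cm3_g must be given together")
    }
    f <- volume_fraction(mass_conc_g_cm3, specific_volume_cm3_g)
  }
  if (!is.null(f) && f > 0 && (is.na(geometry) || is.null(geometry))) {
    stop("geometry is required when the effective-medium inversion runs")
  }
  if (!is.na(geometry) && !is.null(geometry)) {
    geometry <- match.arg(geometry, c("spherical", "fiber"))
  }
  if (sigma0 < 0.008) sigma0 <- 0
  structure(list(input = input, geometry = geometry, f = f %||% 0,
                 solute_file = solute_file, sigma0 = sigma0, grid = grid,
                 fit = fit, out_dir = out_dir, sample_label = sample_label,
                 seed = seed),
            class = "thz_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `grid` may be
#' given as `{from, to, n}`. Fit-level keys (`multistart`, `fit_seed`)
#' override the defaults of [fit_config()].
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return a `thz_run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  g <- if (is.null(y$grid)) default_grid() else
    default_grid(y$grid$from %||% 10, y$grid$to %||% 110, y$grid$n %||% 250)
  fc <- fit_config(sigma0 = y$sigma0 %||% 0,
                   multistart = y$multistart %||% 8,
                   seed = y$fit_seed %||% 0)
  run_config(input = y$input,
             geometry = y$geometry %||% NA,
             f = y$f,
             mass_conc_g_cm3 = y$mass_conc_g_cm3,
             specific_volume_cm3_g = y$specific_volume_cm3_g,
             solute_file = y$solute_file,
             sigma0 = y$sigma0 %||% 0,
             grid = g, fit = fc,
             out_dir = y$out_dir,
             sample_label = y$sample_label %||% "sample",
             seed = y$seed %||% 0)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL      # hash the analysis, not where it is written
  saveRDS(cfg, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

load_solution_spectra <- function(config) {
  inp <- config$input
  if (!is.null(inp$simulate)) {
    sim <- do.call(simulate_replicates, c(
      inp$simulate,
      list(noise = noise_model(
        sigma_rel = inp$simulate_sigma_rel %||% formals(noise_model)$sigma_rel,
        seed = config$seed)),
      list(grid = config$grid)))
    return(list(spectra = sim$solution, simulation = sim))
  }
  if (!is.null(inp$solution_files)) {
    return(list(spectra = lapply(inp$solution_files, read_spectrum,
                                 kind = "permittivity"),
                simulation = NULL))
  }
  if (!is.null(inp$trace_pairs)) {
    if (is.null(inp$dl_um)) stop("trace input needs dl_um")
    specs <- lapply(inp$trace_pairs, function(pr) {
      s <- if (inherits(pr$sample, "thz_trace")) pr$sample
           else read_trace(pr$sample)
      b <- if (inherits(pr$background, "thz_trace")) pr$background
           else read_trace(pr$background)
      permittivity_from_optics(
        optics_from_pair(s, b, inp$dl_um, config$grid))
    })
    return(list(spectra = specs, simulation = NULL))
  }
  stop("config$input must contain simulate, solution_files, or trace_pairs")
}

#' Run the full hydration-shell analysis pipeline
#'
#' Stages: (optional) time-domain processing -> (optional) effective-medium
#' inversion -> per-replicate model fit -> replicate aggregation. With
#' `out_dir` set, writes per-replicate water-phase spectra
#' (`eps_w_repNN.csv`), `fits.json`, `table1.csv` and `manifest.json`
#' (config hash, seed, package version). Reruns with the same configuration
#' are bit-identical.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return list of class `thz_run`: `fits` (list of `thz_fit`), `summary`
#'   (from [aggregate_replicates()]), `water_spectra`, `table` (formatted
#'   report), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "thz_run_config"))
  loaded <- load_solution_spectra(config)
  spectra <- loaded$spectra

  water <- if (config$f > 0) {
    eps_c <- if (!is.null(config$solute_file)) {
      read_spectrum(config$solute_file, kind = "permittivity")
    } else if (!is.null(loaded$simulation) &&
               !is.null(loaded$simulation$mixture)) {
      loaded$simulation$mixture$solute_eps
    } else {
      preset <- if (config$geometry == "spherical") "monosaccharide"
                else "polysaccharide"
      solute_model(preset)(config$grid)
    }
    mix <- mixture_spec(config$geometry, config$f, eps_c,
                        sigma0 = config$sigma0)
    lapply(spectra, medium_invert, mixture = mix)
  } else {
    spectra
  }

  fc <- config$fit
  fc$sigma0 <- config$sigma0
  fits <- vector("list", length(water))
  for (i in seq_along(water)) {
    fit <- tryCatch(fit_model(water[[i]], fc), error = function(e) {
      stop(sprintf("fit stage failed for replicate %d: %s",
                   i, conditionMessage(e)))
    })
    if (fit$s > 0.0021) {
      warning(sprintf(
        "replicate %d: s = %.3g exceeds 0.0021, the worst value seen in practice",
        i, fit$s))
    }
    message(sprintf("[fit] %s replicate %d/%d: s = %.3g, n = %.2f%%",
                    config$sample_label, i, length(water), fit$s,
                    fit$n_free_pct))
    fits[[i]] <- fit
  }

  summary <- if (length(fits) >= 2) {
    aggregate_replicates(fits, sample = config$sample_label)
  } else NULL
  table <- if (!is.null(summary)) format_parameter_table(list(summary))
           else NULL
  manifest <- list(
    package = "thzhydrate",
    version = as.character(utils::packageVersion("thzhydrate")),
    seed = config$seed,
    n_replicates = length(fits),
    config_md5 = config_hash(config))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(water)) {
      write_spectrum(water[[i]],
                     file.path(config$out_dir,
                               sprintf("eps_w_rep%02d.csv", i)))
    }
    jsonlite::write_json(
      lapply(fits, function(fit) list(
        params = unclass(fit$params), s = fit$s,
        n_free_pct = fit$n_free_pct)),
      file.path(config$out_dir, "fits.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(table)) {
      utils::write.csv(table, file.path(config$out_dir, "table1.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(fits = fits, summary = summary, water_spectra = water,
                 table = table, manifest = manifest),
            class = "thz_run")
}

#' @export
print.thz_run <- function(x, ...) {
  cat(sprintf("<thz_run> %d replicate fit(s)\n", length(x$fits)))
  if (!is.null(x$table)) print(x$table)
  invisible(x)
}

#' Format replicate summaries as a publication-style parameter table
#'
#' One row per sample; columns in the conventional order with "mean +/- ci"
#' entries at the conventional precision: 2 decimals for the slow Debye
#' strength, 3 for the fast strength and its time, 1 for the oscillator
#' position and width, 3 for A/omega0^2 and 2 for the free-water percentage.
#'
#' @param summaries list of `thz_summary` data.frames
#'   (from [aggregate_replicates()]).
#' @return data.frame of character columns: `Carbohydrate`, `de1`, `de2`,
#'   `tau2_ps`, `w0_cm-1`, `gamma_cm-1`, `A_w0sq`, `n_pct`.
#' @export
format_parameter_table <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  digits <- c(de1 = 2, de2 = 3, tau2 = 3, w0 = 1, gam = 1,
              aratio = 3, n_pct = 2)
  rows <- lapply(summaries, function(sm) {
    ent <- vapply(names(digits), function(p) {
      i <- match(p, sm$parameter)
      sprintf(paste0("%.", digits[[p]], "f ± %.", digits[[p]], "f"),
              sm$mean[i], sm$ci95[i])
    }, character(1))
    c(Carbohydrate = sm$sample[1], ent)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("Carbohydrate", "de1", "de2", "tau2_ps", "w0_cm-1",
                  "gamma_cm-1", "A_w0sq", "n_pct")
  rownames(out) <- NULL
  out
}
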