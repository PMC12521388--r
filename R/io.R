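#' Read a 1D scattering curve from columnar ASCII
#'
#' Parses 2- or 3-column whitespace-separated text (q in 1/Angstrom,
#' intensity, optional sigma); `#` comment lines are skipped. Malformed
#' rows are reported with their line numbers; a non-increasing q axis is
#' rejected.
#'
#' @param path File path.
#' @return A `saxs_curve` tibble (columns `q`, `intensity`, optionally
#'   `sigma`).
#' @export
read_saxs_curve <- function(path) {
  m <- read_columnar(path, min_cols = 2, max_cols = 3,
                     axis_name = "q")
  out <- tibble::tibble(q = m[, 1], intensity = m[, 2])
  if (ncol(m) == 3) out$sigma <- m[, 3]
  new_saxs_curve(out)
}

#' Read a Raman spectrum from columnar ASCII
#'
#' Two-column whitespace-separated text (wavenumber in 1/cm, intensity)
#' with `#` comments.
#'
#' @param path File path.
#' @return A `raman_spectrum` tibble.
#' @export
read_raman_spectrum <- function(path) {
  m <- read_columnar(path, min_cols = 2, max_cols = 2,
                     axis_name = "wavenumber")
  out <- tibble::tibble(wavenumber = m[, 1], intensity = m[, 2])
  class(out) <- c("raman_spectrum", class(out))
  out
}

read_columnar <- function(path, min_cols, max_cols, axis_name) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  ncols <- lengths(parts)
  bad <- ncols < min_cols | ncols > max_cols
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- bad | vapply(vals, anyNA, logical(1))
  if (any(bad)) {
    abort(paste0("malformed rows in ", path, " at line(s): ",
                 paste(head(idx[bad], 10), collapse = ", ")))
  }
  if (length(vals) < 2) abort(paste0("too few data rows in ", path))
  nc <- min(ncols)
  m <- do.call(rbind, lapply(vals, function(v) v[seq_len(nc)]))
  if (any(diff(m[, 1]) <= 0)) {
    abort(paste0("non-monotone ", axis_name, " axis in ", path,
                 ": values must be strictly increasing"))
  }
  m
}

provenance_header <- function(seed = NULL, extra = character()) {
  c(paste0("# depotmap ", as.character(utils::packageVersion("depotmap"))),
    if (!is.null(seed)) paste0("# seed ", seed),
    extra)
}

#' Write a scattering curve or Raman spectrum to columnar ASCII
#'
#' Two- or three-column whitespace-separated text with a `#` provenance
#' header; the round trip through [read_saxs_curve()] /
#' [read_raman_spectrum()] is lossless to numeric precision.
#'
#' @param x The curve or spectrum.
#' @param path Output file.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_saxs_curve <- function(x, path, seed = NULL) {
  cols <- c("q", "intensity", if ("sigma" %in% names(x)) "sigma")
  body <- do.call(paste, c(lapply(cols, function(cn) {
    formatC(x[[cn]], format = "g", digits = 15)
  }), list(sep = " ")))
  readr::write_lines(c(provenance_header(seed,
                                         paste0("# columns ",
                                                paste(cols, collapse = " "))),
                       body), path)
  invisible(path)
}

#' @rdname write_saxs_curve
#' @export
write_raman_spectrum <- function(x, path, seed = NULL) {
  body <- paste(formatC(x$wavenumber, format = "g", digits = 15),
                formatC(x$intensity, format = "g", digits = 15))
  readr::write_lines(c(provenance_header(seed, "# columns wavenumber intensity"),
                       body), path)
  invisible(path)
}

#' Write a raster scan to disk
#'
#' One ASCII curve file per pixel plus a CSV manifest
#' (`pixel_x_mm, pixel_y_mm, filename`) and a YAML ground-truth sidecar.
#'
#' @param scan A `raster_scan`.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in headers.
#' @return The manifest path, invisibly.
#' @export
write_raster <- function(scan, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- sprintf("pixel_%04d.dat", seq_len(nrow(scan)))
  for (i in seq_len(nrow(scan))) {
    write_saxs_curve(scan$curve[[i]], file.path(dir, fn[i]), seed = seed)
  }
  manifest <- tibble::tibble(pixel_x_mm = scan$pixel_x_mm,
                             pixel_y_mm = scan$pixel_y_mm,
                             filename = fn)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  truth <- list(pixel_pitch_mm = attr(scan, "pixel_pitch_mm"),
                truth = lapply(seq_len(nrow(scan)), function(i) {
                  list(phase = scan$truth_phase[i],
                       lattice_a = scan$truth_lattice_a[i])
                }))
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yml"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a raster scan from a manifest
#'
#' @param manifest_path CSV manifest with columns `pixel_x_mm`,
#'   `pixel_y_mm`, `filename` (paths relative to the manifest).
#' @return A `raster_scan` tibble (without ground-truth columns).
#' @export
read_raster <- function(manifest_path) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  need <- c("pixel_x_mm", "pixel_y_mm", "filename")
  if (!all(need %in% names(manifest))) {
    abort("manifest needs columns pixel_x_mm, pixel_y_mm, filename")
  }
  if (anyDuplicated(manifest[, c("pixel_x_mm", "pixel_y_mm")])) {
    abort("duplicate pixel coordinates in the raster manifest")
  }
  base <- dirname(manifest_path)
  curves <- lapply(manifest$filename, function(f) {
    read_saxs_curve(file.path(base, f))
  })
  out <- tibble::tibble(pixel_x_mm = manifest$pixel_x_mm,
                        pixel_y_mm = manifest$pixel_y_mm,
                        curve = curves)
  attr(out, "pixel_pitch_mm") <-
    median(diff(sort(unique(out$pixel_x_mm))))
  class(out) <- c("raster_scan", class(out))
  out
}

#' Run the end-to-end depot analysis pipeline
#'
#' Orchestrates simulate -> index -> map -> profile -> segment for the
#' SAXS chain and simulate -> fit -> ratios -> estimates for the Raman
#' chain, writing CSV artifacts with provenance headers (configuration
#' hash and seed) plus a YAML run log. The configuration is a list (or
#' YAML file) with elements `scenario` (`"one_day"`, `"one_week"`,
#' `"four_week"` or a `depot_scenario`), `pixel_pitch_mm`, `seed`,
#' `outdir`, `window`, `fraction_threshold`, `modules` (subset of
#' `"saxs"`, `"raman"`) and for the Raman chain `positions_mm`.
#'
#' @param config List or path to a YAML file.
#' @return A list with the computed artifacts (`map`, `profile`,
#'   `layers`, `ratios`, paths of written files), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(scenario = "one_day", pixel_pitch_mm = 0.25,
                   seed = 1L, outdir = tempfile("depotmap_run_"),
                   window = c(0.058, 0.085), fraction_threshold = 0.2,
                   modules = c("saxs", "raman"),
                   positions_mm = 0:4)
  config <- utils::modifyList(defaults, config)
  config$window <- as.numeric(unlist(config$window))
  config$positions_mm <- as.numeric(unlist(config$positions_mm))
  config$modules <- as.character(unlist(config$modules))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  scenario <- stage("scenario", {
    if (inherits(config$scenario, "depot_scenario")) config$scenario
    else switch(config$scenario,
                one_day = scenario_one_day(noise_seed = config$seed),
                one_week = scenario_one_week(noise_seed = config$seed),
                four_week = scenario_four_week(noise_seed = config$seed),
                abort(paste0("unknown scenario '", config$scenario, "'")))
  })
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_for_hash <- config[setdiff(names(config), "outdir")]
  hash <- rlang::hash(cfg_for_hash)
  header <- c(paste0("# depotmap ",
                     as.character(utils::packageVersion("depotmap"))),
              paste0("# config_hash ", hash),
              paste0("# seed ", config$seed))
  write_with_header <- function(df, file) {
    path <- file.path(config$outdir, file)
    readr::write_lines(header, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
    path
  }
  out <- list(config = config, config_hash = hash, files = character())
  timings <- list()
  if ("saxs" %in% config$modules) {
    t0 <- Sys.time()
    scan <- stage("simulate", generate_raster(
      scenario, pixel_pitch_mm = config$pixel_pitch_mm))
    map <- stage("map", assemble_map(scan, window = config$window))
    prof <- stage("profile", radial_profile(map))
    layers <- stage("segment", segment_layers(
      prof, fraction_threshold = config$fraction_threshold))
    out$map <- map
    out$profile <- prof
    out$layers <- layers
    out$files <- c(out$files,
                   write_with_header(tibble::as_tibble(map), "phase_map.csv"),
                   write_with_header(tibble::as_tibble(prof),
                                     "radial_profile.csv"),
                   write_with_header(layers, "layers.csv"))
    timings$saxs_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  if ("raman" %in% config$modules) {
    t0 <- Sys.time()
    ratios <- stage("raman", {
      rows <- lapply(config$positions_mm, function(pos) {
        r <- min(pos, scenario$depot_radius_mm)
        sp <- generate_raman(
          spc_fraction = scenario$spc_profile(r),
          water_fraction = scenario$water_profile(r),
          noise_seed = config$seed + round(100 * pos),
          position_mm = pos, age_days = scenario$hydration_age_days)
        fit <- fit_bands(sp)
        rt <- intensity_ratios(fit)
        x <- as.numeric(estimate_composition(rt$r1264))
        tibble::tibble(position_mm = pos,
                       age_days = scenario$hydration_age_days,
                       r715 = rt$r715, r1264 = rt$r1264, x_spc = x,
                       water_frac = as.numeric(estimate_hydration(
                         rt$r715, x)))
      })
      dplyr::bind_rows(rows)
    })
    out$ratios <- ratios
    out$files <- c(out$files, write_with_header(ratios, "raman_ratios.csv"))
    timings$raman_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  log <- list(package = "depotmap",
              version = as.character(utils::packageVersion("depotmap")),
              config_hash = hash, seed = config$seed,
              scenario_age_days = scenario$hydration_age_days,
              parameters = cfg_for_hash, timings = timings)
  yaml::write_yaml(log, file.path(config$outdir, "run_log.yml"))
  out$files <- c(out$files, file.path(config$outdir, "run_log.yml"))
  invisible(out)
}
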