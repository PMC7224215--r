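#' Read a colony-size table
#'
#' Expects columns `condition`, `timepoint_weeks`, `colony_size_cells`;
#' unknown columns are preserved but ignored. Non-numeric or sub-unit
#' sizes raise parse errors naming the offending row.
#'
#' @param path CSV file path.
#' @return Data frame with validated, typed columns.
#' @export
read_colony_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("condition", "timepoint_weeks", "colony_size_cells")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_config("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df)
  for (col in c("timepoint_weeks", "colony_size_cells")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_config(sprintf("non-numeric %s on row %d: '%s'", col, bad[1],
                          df[[col]][bad[1]]))
    df[[col]] <- v
  }
  bad <- which(df$colony_size_cells < 1)
  if (length(bad))
    stop_config(sprintf("colony_size_cells < 1 on row %d", bad[1]))
  df
}

#' Split a colony table into per-(condition, timepoint) samples
#'
#' @param df a [read_colony_csv()]-shaped data frame.
#' @return Named list of size vectors, names `condition/week`.
#' @export
colony_samples <- function(df) {
  key <- paste(df$condition, df$timepoint_weeks, sep = "/")
  split(df$colony_size_cells, key)
}

#' Write a colony-size table (with sidecar metadata)
#'
#' @param sizes colony sizes (cells).
#' @param path output CSV path.
#' @param condition,timepoint_weeks labels recycled across rows.
#' @param metadata named list recorded in the sidecar manifest.
#' @return `path`, invisibly.
#' @export
write_colony_csv <- function(sizes, path, condition = "condition",
                             timepoint_weeks = 0, metadata = list()) {
  df <- data.frame(condition = condition, timepoint_weeks = timepoint_weeks,
                   colony_size_cells = sizes)
  write.csv(df, path, row.names = FALSE)
  write_run_manifest(path, c(list(rows = nrow(df)), metadata))
  invisible(path)
}

#' Read / write limiting-dilution plate tables
#'
#' Plate CSVs carry one row per dose level with columns
#' `dose_cells_per_well`, `wells_total`, `wells_negative`.
#'
#' @param path CSV file path.
#' @return `read_ld_plate_csv`: an `ld_plate` data frame.
#' @export
read_ld_plate_csv <- function(path) {
  df <- read.csv(path)
  req <- c("dose_cells_per_well", "wells_total", "wells_negative")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_config("missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("ld_plate", "data.frame")
  df
}

#' @rdname read_ld_plate_csv
#' @param plate an `ld_plate` data frame.
#' @param metadata named list recorded in the sidecar manifest.
#' @export
write_ld_plate_csv <- function(plate, path, metadata = list()) {
  write.csv(as.data.frame(plate), path, row.names = FALSE)
  write_run_manifest(path, metadata)
  invisible(path)
}

#' Read / write barcode count tables
#'
#' Barcode CSVs have a `barcode` id column followed by one column per
#' sample, and a `#role` line (second line of the file) assigning each
#' sample its role (`baseline` or a condition label).
#'
#' @param path CSV file path.
#' @return `read_barcode_csv`: a [barcode_table()].
#' @export
read_barcode_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[2], "#role"))
    stop_config("barcode CSV must carry a '#role' line after the header")
  roles <- strsplit(lines[2], ",")[[1]][-1]
  df <- read.csv(textConnection(lines[-2]), check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  barcode_table(counts, roles = roles)
}

#' @rdname read_barcode_csv
#' @param table a [barcode_table()].
#' @param metadata named list recorded in the sidecar manifest.
#' @export
write_barcode_csv <- function(table, path, metadata = list()) {
  stopifnot(inherits(table, "barcode_table"))
  header <- paste(c("barcode", colnames(table)), collapse = ",")
  role_line <- paste(c("#role", attr(table, "roles")), collapse = ",")
  body <- apply(cbind(rownames(table), unclass(table)), 1, paste,
                collapse = ",")
  writeLines(c(header, role_line, body), path)
  write_run_manifest(path, metadata)
  invisible(path)
}

#' Read / write luminescence plate tables
#'
#' Columns: `role` ("drug", "dmso", "empty"), `concentration`, `replicate`,
#' `signal`.
#'
#' @param path CSV file path.
#' @return `read_luminescence_csv`: a `luminescence_plate` data frame.
#' @export
read_luminescence_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("role", "concentration", "replicate", "signal")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_config("missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("luminescence_plate", "data.frame")
  df
}

#' @rdname read_luminescence_csv
#' @param plate a `luminescence_plate` data frame.
#' @param metadata named list recorded in the sidecar manifest.
#' @export
write_luminescence_csv <- function(plate, path, metadata = list()) {
  write.csv(as.data.frame(plate), path, row.names = FALSE)
  write_run_manifest(path, metadata)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline output is accompanied by a plain-text sidecar
#' (`<output>.manifest.txt`) recording the generating parameters, seed,
#' package version, timestamp and input-file digests, so any table can be
#' traced back to the exact invocation that produced it.
#'
#' @param output_path the data file the manifest describes.
#' @param params named list of parameters/seeds (flattened one per line).
#' @param inputs paths of input files to digest (md5).
#' @return Manifest path, invisibly.
#' @export
write_run_manifest <- function(output_path, params = list(),
                               inputs = character(0)) {
  flat <- unlist(params)
  lines <- c(
    sprintf("output: %s", basename(output_path)),
    sprintf("tool_version: gradres %s",
            as.character(packageVersion("gradres"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (length(flat)) sprintf("%s: %s", names(flat), as.character(flat)),
    if (length(inputs))
      sprintf("input_md5 %s: %s", basename(inputs),
              as.character(tools::md5sum(inputs))))
  manifest <- paste0(output_path, ".manifest.txt")
  writeLines(lines, manifest)
  invisible(manifest)
}

#' Run an end-to-end analysis stage
#'
#' Config-driven umbrella entry point binding the pipeline stages: each
#' call runs one named stage on its inputs, writes the stage outputs plus a
#' manifest into `out_dir`, and is byte-reproducible given the same config
#' and seed. `config` is a named list with elements:
#' \describe{
#'   \item{stage}{one of `"synth"`, `"graduality"`, `"limiting_dilution"`,
#'     `"dose_response"`, `"barcode"`.}
#'   \item{seed}{integer seed for every stochastic step.}
#'   \item{...}{stage-specific entries, see Details.}
#' }
#'
#' @details
#' `synth` writes synthetic colony, limiting-dilution, barcode and
#' luminescence tables. `graduality` needs `observed` (colony CSV path),
#' `tolerant`, `resistant` (colony CSV paths) and optional `mu_values`,
#' `n_values`, `reps`; it calibrates, sweeps the grid, extracts the
#' best-fit region and runs the mixture test. `limiting_dilution` needs
#' `plate` (plate CSV); `dose_response` needs `plate` (luminescence CSV);
#' `barcode` needs `table` (barcode CSV).
#'
#' @param config named list (see above), or the path of a YAML file holding
#'   one (requires the `yaml` package).
#' @param out_dir output directory, created if absent.
#' @return Named list of result objects, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$stage))
  for (p in c("observed", "tolerant", "resistant", "plate", "table"))
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop_config("input not found: ", config[[p]])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- switch(
    config$stage,
    synth = pipeline_synth(config, out_dir, seed),
    graduality = pipeline_graduality(config, out_dir, seed),
    limiting_dilution = pipeline_ld(config, out_dir, seed),
    dose_response = pipeline_dr(config, out_dir, seed),
    barcode = pipeline_barcode(config, out_dir, seed),
    stop_config("unknown stage: ", config$stage))
  invisible(out)
}

pipeline_synth <- function(config, out_dir, seed) {
  tol <- colony_population_spec("tolerant", meanlog = 2.2, sdlog = 0.6)
  res <- colony_population_spec("resistant", meanlog = 5.5, sdlog = 0.6)
  write_colony_csv(generate_colony_sizes(tol, 200, seed),
                   file.path(out_dir, "tolerant_sizes.csv"),
                   condition = "tolerant",
                   metadata = list(seed = seed))
  write_colony_csv(generate_colony_sizes(res, 200, seed + 1),
                   file.path(out_dir, "resistant_sizes.csv"),
                   condition = "resistant",
                   metadata = list(seed = seed + 1))
  write_ld_plate_csv(
    generate_limiting_dilution_plates(1 / 500, seed = seed + 2),
    file.path(out_dir, "ld_plate.csv"),
    metadata = list(seed = seed + 2, per_cell_freq = 1 / 500))
  write_barcode_csv(
    generate_barcode_experiment(barcode_sim_spec(), seed = seed + 3),
    file.path(out_dir, "barcode_counts.csv"),
    metadata = list(seed = seed + 3))
  write_luminescence_csv(
    generate_dose_response_plate(dose_response_truth(), seed = seed + 4),
    file.path(out_dir, "luminescence.csv"),
    metadata = list(seed = seed + 4))
  list(out_dir = out_dir)
}

pipeline_graduality <- function(config, out_dir, seed) {
  obs_df <- read_colony_csv(config$observed)
  tolerant <- read_colony_csv(config$tolerant)$colony_size_cells
  resistant <- read_colony_csv(config$resistant)$colony_size_cells
  weeks <- sort(unique(obs_df$timepoint_weeks))
  observed <- lapply(weeks,
                     function(w) obs_df$colony_size_cells[
                       obs_df$timepoint_weeks == w])
  params <- simulation_params()
  n_upd <- 7L * params$updates_per_day
  map <- build_rate_size_map(n_upd, reps = config$map_reps %||% 200,
                             seed = seed)
  cal <- calibrate_cohort(tolerant, resistant, map)
  grid <- sweep_parameter_grid(
    observed, weeks,
    mu_values = config$mu_values %||% c(0.005, 0.01, 0.05, 0.1),
    n_values = config$n_values %||% c(1, 3, 10, 30, 100, 300),
    calibration = cal, base_params = params,
    reps = config$reps %||% 2000, seed = seed + 1)
  region <- best_fit_region(grid, tolerance = config$tolerance %||% 0.1)
  mix <- ks_mixture_test(unlist(observed), tolerant, resistant,
                         n_boot = config$n_boot %||% 1000, seed = seed + 2)
  grid_df <- data.frame(mu = rep(grid$mu_values, length(grid$n_values)),
                        n = rep(grid$n_values, each = length(grid$mu_values)),
                        kl_nats = as.vector(grid$divergence))
  write.csv(grid_df, file.path(out_dir, "kl_grid.csv"), row.names = FALSE)
  write_run_manifest(file.path(out_dir, "kl_grid.csv"),
                     list(seed = seed, reps = grid$reps,
                          p_init = cal$p_init, p_max_ref = cal$p_max_ref,
                          mixture_alpha = mix$alpha_hat,
                          mixture_p = mix$p_value),
                     inputs = c(config$observed, config$tolerant,
                                config$resistant))
  write.csv(as.data.frame(region), file.path(out_dir, "best_fit_region.csv"),
            row.names = FALSE)
  list(calibration = cal, grid = grid, region = region, mixture = mix)
}

pipeline_ld <- function(config, out_dir, seed) {
  plate <- read_ld_plate_csv(config$plate)
  fit <- fit_limiting_dilution(plate,
                               intercept = config$intercept %||% "zero")
  est <- ric_frequency(fit)
  df <- data.frame(slope = est$slope, slope_se = est$slope_se,
                   per_cell_frequency = est$per_cell_frequency,
                   cells_per_ric = est$cells_per_ric,
                   cells_per_ric_error = est$cells_per_ric_error)
  write.csv(df, file.path(out_dir, "ric_estimate.csv"), row.names = FALSE)
  write_run_manifest(file.path(out_dir, "ric_estimate.csv"),
                     list(seed = seed), inputs = config$plate)
  list(fit = fit, estimate = est)
}

pipeline_dr <- function(config, out_dir, seed) {
  plate <- read_luminescence_csv(config$plate)
  norm <- normalize_viability(plate)
  fit <- fit_dose_response(norm$concentration, norm$viability)
  df <- data.frame(b = fit$b, k = fit$k, ic50 = fit$ic50,
                   residual_sse = fit$residual_sse,
                   converged = fit$converged)
  write.csv(df, file.path(out_dir, "dose_response_fit.csv"),
            row.names = FALSE)
  write_run_manifest(file.path(out_dir, "dose_response_fit.csv"),
                     list(seed = seed), inputs = config$plate)
  fit
}

pipeline_barcode <- function(config, out_dir, seed) {
  table <- read_barcode_csv(config$table)
  res <- analyze_barcodes(table)
  enr_df <- data.frame(
    sample = rep(names(res$enrichment$enriched),
                 lengths(res$enrichment$enriched)),
    barcode = unlist(res$enrichment$enriched, use.names = FALSE))
  write.csv(enr_df, file.path(out_dir, "enriched_barcodes.csv"),
            row.names = FALSE)
  write.csv(data.frame(sample = names(res$diversity),
                       H_nats = as.numeric(res$diversity)),
            file.path(out_dir, "diversity.csv"), row.names = FALSE)
  if (!is.null(res$correlation))
    write.csv(as.data.frame(res$correlation),
              file.path(out_dir, "correlation.csv"))
  write_run_manifest(file.path(out_dir, "enriched_barcodes.csv"),
                     list(seed = seed, threshold = res$threshold),
                     inputs = config$table)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
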