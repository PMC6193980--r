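# File formats and pipeline plumbing. Tabular data travel as CSV with
# documented headers, image stacks as multi-page TIFF with a JSON sidecar
# carrying the generating truth, configs and results as JSON. Distances are
# nm, track coordinates px (pixel size carried in metadata), times s,
# densities per um^2.

#' Column schemas for the package's CSV formats
#'
#' @format named list of character vectors (required columns, in order):
#' `flimp` (r_obs_nm, sigma_nm, ci_lo_nm, ci_hi_nm, condition), `tracks`
#' (track_id, channel, frame, x_px, y_px), `fret` (cell_id, density_um2,
#' efficiency), `pbics_curve` (p, cd), `composition` (size, fraction).
#' @export
oligoscope_schemas <- list(
  flimp = c("r_obs_nm", "sigma_nm", "ci_lo_nm", "ci_hi_nm", "condition"),
  tracks = c("track_id", "channel", "frame", "x_px", "y_px"),
  fret = c("cell_id", "density_um2", "efficiency"),
  pbics_curve = c("p", "cd"),
  composition = c("size", "fraction")
)

#' Read a CSV against one of the package schemas
#'
#' The header must contain exactly the schema's columns (order free); a
#' missing or unknown column is a schema error naming the column. Zero data
#' rows are allowed.
#'
#' @param path CSV file path.
#' @param schema schema name (see [oligoscope_schemas]) or a character
#'   vector of required column names.
#' @return data.frame with columns in schema order.
#' @export
read_table_checked <- function(path, schema) {
  cols <- if (is.character(schema) && length(schema) == 1 &&
                schema %in% names(oligoscope_schemas))
    oligoscope_schemas[[schema]] else as.character(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), cols)
  if (length(extra) > 0)
    stop("schema error: unknown column(s) ", paste(extra, collapse = ", "))
  df[, cols, drop = FALSE]
}

#' Write a table for one of the package schemas
#'
#' @param df data.frame carrying at least the schema's columns.
#' @inheritParams read_table_checked
#' @export
write_table_checked <- function(df, path, schema) {
  cols <- if (is.character(schema) && length(schema) == 1 &&
                schema %in% names(oligoscope_schemas))
    oligoscope_schemas[[schema]] else as.character(schema)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Write / read an image stack as multi-page TIFF (float32)
#'
#' Images are rescaled to [0, 1] for TIFF storage with the scale recorded in
#' the JSON sidecar (written next to the TIFF when `truth` is supplied).
#'
#' @param images list of numeric matrices (one per page) or a T x H x W
#'   array.
#' @param path output .tif path.
#' @param truth optional list serialised to `<path>.json`.
#' @export
write_stack_tiff <- function(images, path, truth = NULL) {
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[1]), function(t) images[t, , ])
  mx <- max(1e-12, max(vapply(images, max, numeric(1))))
  tiff::writeTIFF(lapply(images, function(m) m / mx), path,
                  bits.per.sample = 32L)
  meta <- list(scale = mx)
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @return `read_stack_tiff`: list of matrices on the original intensity
#'   scale, with attribute `meta` when a sidecar exists.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  out <- lapply(pages, function(m) m * scale)
  attr(out, "meta") <- meta
  out
}

#' Derive a stage seed from the master seed
#'
#' Every stochastic stage draws its stream from (master seed, stage name) so
#' pipelines are reproducible end to end without stages sharing a stream.
#' The result stays below 2^31.
#'
#' @param master_seed integer master seed.
#' @param stage stage name (character).
#' @export
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647)
}

#' Run one pipeline stage from a config
#'
#' Executes simulate -> analyse -> report for the named stage and writes the
#' result JSON (with a provenance block: package version, config, derived
#' seed) to `config$out`. Supported stages: `"flimp"` (simulate separations,
#' CI-filter, BIC decomposition), `"pbics"` (simulate stack, bleach curve,
#' composition fit), `"coloc"` (simulate tracks, corrected colocalisation),
#' `"fret"` (simulate titration, DOCA fit). Invalid parameters fail
#' validation before any computation.
#'
#' @param config named list: `stage`, `seed`, optional `out` (JSON path),
#'   plus stage parameters (see the stage functions' defaults).
#' @return the result list, invisibly written to `config$out` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$stage), !is.null(config$seed))
  stage <- match.arg(config$stage, c("flimp", "pbics", "coloc", "fret"))
  seed <- derive_seed(config$seed, stage)
  cfg <- function(name, default) config[[name]] %||% default
  if (!is.null(config$ci_max) && config$ci_max <= 0)
    stop("validation error: ci_max must be positive")
  result <- switch(stage,
    flimp = {
      geom <- chain_geometry(cfg("repeat_spacing_nm", 11),
                             cfg("turn_angle_deg", 32))
      comp <- oligomer_composition(cfg("composition",
                                       exponential_composition()$fractions))
      ds <- simulate_flimp_measurements(
        geom, comp, labeling_scheme("internal_1to1", cfg("p_label", 0.2)),
        loc_sigma_nm = cfg("loc_sigma_nm", 1.5),
        n_measurements = cfg("n_measurements", 100), seed = seed)
      ds <- filter_ci(ds, cfg("ci_max", 7))
      dec <- select_K(ds, K_max = cfg("k_max", 6), restarts = 3,
                      seed = seed + 1)
      list(n_measurements = nrow(ds), K = dec$K,
           components = dec$components, bic_table = dec$bic_table)
    },
    pbics = {
      comp <- oligomer_composition(cfg("composition", c(0.6, 0.25, 0.1, 0.05)))
      st <- simulate_pbics_stack(comp, cfg("cluster_density_per_um2", 0.5),
                                 cfg("survival_per_round", 0.7),
                                 n_rounds = cfg("n_rounds", 7),
                                 image_px = cfg("image_px", 256),
                                 omega_px = cfg("omega_px", 3), seed = seed)
      curve <- measure_bleach_curve(st)
      fit <- fit_composition(curve, j_max = cfg("j_max", 8),
                             restarts = cfg("restarts", 30), seed = seed + 1)
      list(curve = as.data.frame(curve), c_j = fit$c_j,
           fractions = fit$fractions,
           oligomer_fraction = fit$oligomer_fraction)
    },
    coloc = {
      sim <- simulate_tracks(cfg("n_free_per_channel", 100),
                             cfg("n_pairs", 30),
                             tau_on_mean_s = cfg("tau_on_mean_s", 1),
                             n_frames = cfg("n_frames", 100), seed = seed)
      res <- coloc_analysis(sim$channelA, sim$channelB,
                            dist_px = cfg("dist", 1),
                            min_total_frames = cfg("min_frames", 5),
                            fwhm_frames = cfg("fwhm", 4),
                            n_rand = cfg("n_rand", 50), seed = seed + 1)
      list(corrected_A = res$corrected_A, corrected_B = res$corrected_B,
           coincidental_A = res$coincidental_A,
           coincidental_B = res$coincidental_B,
           raw_A = res$raw$fraction_A, raw_B = res$raw$fraction_B,
           mean_tau_on_s = mean(res$tau_on_s))
    },
    fret = {
      dens <- cfg("densities_um2", c(5000, 10000, 20000, 50000, 100000))
      resp <- fret_response(dens, R0 = cfg("r0", 5),
                            n_config = cfg("n_config", 200), seed = seed)
      obs <- simulate_fret(cfg("h_true_nm", 8), dens, R0 = cfg("r0", 5),
                           n_cells_per_density = cfg("n_cells_per_density", 8),
                           noise_sd = cfg("noise_sd", 0.05),
                           seed = seed + 1, response = resp)
      est <- fit_doca(obs, R0 = cfg("r0", 5),
                      n_boot = cfg("n_boot", 3000), seed = seed + 2,
                      response = resp)
      list(mean_h = est$mean_h, sd_h = est$sd_h, h_point = est$h_point)
    })
  bundle <- list(stage = stage, result = result,
                 provenance = list(
                   package = "oligoscope",
                   version = as.character(utils::packageVersion("oligoscope")),
                   master_seed = config$seed, derived_seed = seed,
                   config = config[setdiff(names(config), "out")]))
  if (!is.null(config$out))
    jsonlite::write_json(bundle, config$out, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  invisible(bundle)
}
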