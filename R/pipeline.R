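# End-to-end pipeline: simulate -> maps -> extract -> stats, as plain R
# functions with a JSON-serializable configuration. The command-line entry
# point (inst/cli/radiomap.R) is a thin dispatcher over these functions; both
# routes produce byte-identical outputs for the same config and seed.

#' Pipeline configuration
#'
#' Bundles every tunable of the four stages. Serializable to/from JSON; every
#' random operation derives from the single \code{seed}.
#'
#' @param cohort A \code{\link{cohort_config}}.
#' @param cell_size Map grid pitch in mm (default 2 x 2 x 3).
#' @param bin_width,n_bins,alpha Feature discretization / GLDM settings.
#' @param overlap_threshold VOI transfer threshold (default 0.5).
#' @param analysis An \code{\link{analysis_config}}.
#' @param gzip Write \code{.nii.gz} (default) or \code{.nii}.
#' @param seed Master seed; overrides the cohort and analysis seeds.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            cell_size = c(2, 2, 3),
                            bin_width = 25, n_bins = NULL, alpha = 0,
                            overlap_threshold = 0.5,
                            analysis = analysis_config(),
                            gzip = TRUE,
                            seed = 20240503) {
  cohort$seed <- as.integer(seed)
  analysis$seed <- as.integer(seed)
  structure(list(cohort = cohort, cell_size = as.numeric(cell_size),
                 bin_width = bin_width, n_bins = n_bins, alpha = alpha,
                 overlap_threshold = overlap_threshold, analysis = analysis,
                 gzip = gzip, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A \code{pipeline_config}.
#' @param path JSON file path.
#' @return \code{write_pipeline_config}: the path, invisibly;
#'   \code{read_pipeline_config}: the \code{pipeline_config}.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$analysis <- unclass(x$analysis)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("cohort", "cell_size", "overlap_threshold", "analysis", "seed")
  if (!all(req %in% names(x))) {
    stop("malformed pipeline config: missing ",
         paste(setdiff(req, names(x)), collapse = ", "))
  }
  ch <- x$cohort
  cfg <- cohort_config(
    n_noPCa_PZ = ch$counts[1, 1], n_noPCa_TZ = ch$counts[1, 2],
    n_ciPCa_PZ = ch$counts[2, 1], n_ciPCa_TZ = ch$counts[2, 2],
    n_csPCa_PZ = ch$counts[3, 1], n_csPCa_TZ = ch$counts[3, 2],
    psa_median_by_group = unlist(ch$psa_median),
    volume_median_by_group = unlist(ch$volume_median),
    psa_sdlog = ch$psa_sdlog, volume_sdlog = ch$volume_sdlog,
    lesion_effect = as.list(ch$lesion_effect),
    image_shape = ch$image_shape, spacing = ch$spacing,
    bg_mean = ch$bg_mean, bg_sd = ch$bg_sd,
    lesion_radii_mm = ch$lesion_radii_mm,
    rater2_flip_prob = ch$rater2_flip_prob, seed = ch$seed)
  an <- x$analysis
  acfg <- analysis_config(strata = an$strata, psad_modes = an$psad_modes,
                          bootstrap_n = an$bootstrap_n, lambda = an$lambda,
                          sig_level = an$sig_level, adjust_bh = an$adjust_bh,
                          seed = an$seed)
  pipeline_config(cohort = cfg, cell_size = x$cell_size,
                  bin_width = x$bin_width,
                  n_bins = if (is.null(x$n_bins)) NULL else x$n_bins,
                  alpha = x$alpha, overlap_threshold = x$overlap_threshold,
                  analysis = acfg, gzip = isTRUE(x$gzip), seed = x$seed)
}

# polynomial rolling hash of the serialized config, for reproducibility logging
.config_hash <- function(config) {
  s <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 33 + b) %% 1000000007
  }
  sprintf("%08x", h)
}

.log_info <- function(fmt, ...) message(sprintf(paste0("[radiomaps] ", fmt), ...))

.nii_ext <- function(config) if (isTRUE(config$gzip)) ".nii.gz" else ".nii"

#' Simulate a phantom cohort to disk
#'
#' Writes one T2w-like volume and two rater masks per case (NIfTI) plus the
#' cohort CSV and the effective config JSON.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory.
#' @return Paths written (named list), invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  t0 <- Sys.time()
  dir.create(file.path(out_dir, "cases"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- generate_cohort(config$cohort, with_images = TRUE)
  ext <- .nii_ext(config)
  for (id in cohort$records$id) {
    cs <- cohort$cases[[id]]
    write_volume(cs$volume, file.path(out_dir, "cases",
                                      paste0(id, "_t2w", ext)))
    write_volume(cs$mask_rater1, file.path(out_dir, "cases",
                                           paste0(id, "_mask_r1", ext)))
    write_volume(cs$mask_rater2, file.path(out_dir, "cases",
                                           paste0(id, "_mask_r2", ext)))
  }
  csv <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(cohort, csv)
  cfg_json <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_json)
  .log_info("simulate: %d cases in %.1fs (seed %d, config %s)",
            nrow(cohort$records), as.numeric(Sys.time() - t0, units = "secs"),
            config$seed, .config_hash(config))
  invisible(list(cohort_csv = csv, config_json = cfg_json,
                 cases_dir = file.path(out_dir, "cases")))
}

.settings_of <- function(config) {
  feature_settings(bin_width = config$bin_width, n_bins = config$n_bins,
                   alpha = config$alpha)
}

#' Compute and write the feature maps of one volume
#'
#' @param volume_path NIfTI volume path.
#' @param out_dir Output directory for the 93 per-feature NIfTI maps and the
#'   geometry sidecar.
#' @param config A \code{\link{pipeline_config}}.
#' @return The output directory, invisibly.
#' @export
pipeline_maps <- function(volume_path, out_dir, config = pipeline_config()) {
  if (!file.exists(volume_path)) stop("input volume not found: ", volume_path)
  t0 <- Sys.time()
  vol <- read_volume(volume_path)
  grid <- build_grid(vol, cell_size = config$cell_size)
  stack <- compute_maps(vol, grid, settings = .settings_of(config))
  nan_frac <- mean(is.nan(stack$maps))
  if (nan_frac > 0.2) {
    warning(sprintf("NaN-heavy maps: %.0f%% of cells undefined",
                    100 * nan_frac))
  }
  write_maps(stack, out_dir, gzip = isTRUE(config$gzip))
  .log_info("maps: %s -> %d maps in %.1fs", basename(volume_path),
            dim(stack$maps)[4], as.numeric(Sys.time() - t0, units = "secs"))
  invisible(out_dir)
}

#' Extract map means for every cohort case
#'
#' For each case: transfers each rater's VOI onto the map grid and appends
#' the 93 per-feature map means to the cohort table (columns named by
#' registry name for rater 1, suffix \code{_r2} for rater 2).
#'
#' @param sim_dir Directory produced by \code{\link{pipeline_simulate}}
#'   (expects \code{cases/} and \code{cohort.csv}).
#' @param maps_dir Directory with one \code{<id>_maps/} stack per case, as
#'   written by \code{\link{pipeline_run}} / \code{\link{pipeline_maps}}.
#' @param out_csv Output feature-table CSV path.
#' @param config A \code{\link{pipeline_config}}.
#' @return The feature table data.frame, invisibly.
#' @export
pipeline_extract <- function(sim_dir, maps_dir, out_csv,
                             config = pipeline_config()) {
  csv <- file.path(sim_dir, "cohort.csv")
  if (!file.exists(csv)) stop("cohort table not found: ", csv)
  records <- utils::read.csv(csv, stringsAsFactors = FALSE)
  ext <- .nii_ext(config)
  nms <- feature_names()
  f1 <- matrix(NA_real_, nrow(records), length(nms),
               dimnames = list(NULL, nms))
  f2 <- matrix(NA_real_, nrow(records), length(nms),
               dimnames = list(NULL, paste0(nms, "_r2")))
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    stack <- read_maps(file.path(maps_dir, paste0(id, "_maps")))
    vol_dim <- stack$grid$vol_dim
    dummy <- image_volume(array(0, vol_dim), spacing = stack$grid$spacing,
                          origin = stack$grid$origin)
    grid <- build_grid(dummy, cell_size = stack$grid$cell_size)
    m1 <- read_volume(file.path(sim_dir, "cases",
                                paste0(id, "_mask_r1", ext)), mask = TRUE)
    m2 <- read_volume(file.path(sim_dir, "cases",
                                paste0(id, "_mask_r2", ext)), mask = TRUE)
    f1[i, ] <- extract_map_means(stack, transfer_voi(
      m1, grid, config$overlap_threshold))
    f2[i, ] <- extract_map_means(stack, transfer_voi(
      m2, grid, config$overlap_threshold))
  }
  out <- cbind(records, as.data.frame(f1), as.data.frame(f2))
  utils::write.csv(out, out_csv, row.names = FALSE)
  .log_info("extract: %d cases x %d features (x2 raters) -> %s",
            nrow(records), length(nms), out_csv)
  invisible(out)
}

#' Run the statistical stage on a feature table
#'
#' @param feature_csv Feature table CSV (from \code{\link{pipeline_extract}}).
#' @param out_dir Directory for the report CSVs.
#' @param config A \code{\link{pipeline_config}}.
#' @return The \code{radiomap_analysis}, invisibly.
#' @export
pipeline_stats <- function(feature_csv, out_dir, config = pipeline_config()) {
  if (!file.exists(feature_csv)) {
    stop("feature table not found: ", feature_csv)
  }
  records <- utils::read.csv(feature_csv, stringsAsFactors = FALSE,
                             check.names = FALSE)
  need <- c("label", "zone", "psad")
  if (!all(need %in% names(records))) {
    stop("malformed feature table: missing column(s) ",
         paste(setdiff(need, names(records)), collapse = ", "))
  }
  analysis <- run_full_analysis(records, config$analysis)
  write_analysis(analysis, out_dir)
  .log_info("stats: %d features, strata %s -> %s", length(analysis$features),
            paste(config$analysis$strata, collapse = "/"), out_dir)
  invisible(analysis)
}

#' Run the whole pipeline end to end
#'
#' simulate -> per-case maps -> extract -> stats, under one output directory:
#' \code{sim/}, \code{maps/}, \code{features.csv}, \code{reports/}.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output root directory.
#' @return The \code{radiomap_analysis}, invisibly.
#' @export
pipeline_run <- function(config, out_dir) {
  sim_dir <- file.path(out_dir, "sim")
  maps_dir <- file.path(out_dir, "maps")
  pipeline_simulate(config, sim_dir)
  records <- utils::read.csv(file.path(sim_dir, "cohort.csv"))
  ext <- .nii_ext(config)
  for (id in records$id) {
    pipeline_maps(file.path(sim_dir, "cases", paste0(id, "_t2w", ext)),
                  file.path(maps_dir, paste0(id, "_maps")), config)
  }
  feature_csv <- file.path(out_dir, "features.csv")
  pipeline_extract(sim_dir, maps_dir, feature_csv, config)
  pipeline_stats(feature_csv, file.path(out_dir, "reports"), config)
}
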