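#' Run the full zonation pipeline on a two-channel image
#'
#' Detection, center/border partition at a fixed intensity fraction,
#' marker quantification per zone, and the center-vs-border enrichment
#' test when at least three plaques yield measurable zones.
#'
#' @param image a [multichannel_image()].
#' @param threshold_fraction zone cut as a fraction of the center
#'   reference (default 0.6).
#' @param min_diameter_px minimum plaque equivalent diameter (default 10).
#' @param paired paired enrichment test (default TRUE).
#' @return List with `regions`, `partitions`, `records`, `table`
#'   (via [zone_records_table()]) and `test` (NULL if < 3 usable plaques).
#' @export
zonate_field <- function(image, threshold_fraction = 0.6,
                         min_diameter_px = 10, paired = TRUE) {
  regions <- detect_plaques(image, min_diameter_px = min_diameter_px)
  partitions <- lapply(regions, partition_zones, image = image,
                       threshold_fraction = threshold_fraction)
  records <- lapply(partitions, quantify_marker_zones, image = image)
  test <- NULL
  usable <- vapply(records, function(r) is.finite(r$center_border_ratio), TRUE)
  if (sum(usable) >= 3L)
    test <- zone_enrichment_test(records[usable], paired = paired)
  list(regions = regions, partitions = partitions, records = records,
       table = if (length(records)) zone_records_table(records) else NULL,
       test = test)
}

#' Compute virtual mRNA levels for a qPCR table
#'
#' @param table a data.frame from [read_qpcr_csv()] or
#'   [simulate_qpcr_run()] (needs `ct_standard`, `slope` and either
#'   `ct_target` or `ct_rep*` columns).
#' @param mode `"literal"` or `"exponential"` (see [virtual_mrna_level()]).
#' @return The table with added columns `level` and `mode`.
#' @export
qpcr_levels <- function(table, mode = c("literal", "exponential")) {
  mode <- match.arg(mode)
  if (!"ct_target" %in% names(table)) {
    reps <- grep("^ct_rep", names(table), value = TRUE)
    if (length(reps) == 0L) stop("table needs ct_target or ct_rep columns")
    table$ct_target <- rowMeans(table[, reps, drop = FALSE])
  }
  table$level <- as.numeric(virtual_mrna_level(table$ct_target,
                                               table$ct_standard,
                                               table$slope, mode = mode))
  table$mode <- mode
  table
}

.pipeline_commands <- c("simulate-tht", "simulate-plaques", "simulate-qpcr",
                        "fit-tht", "zonate", "qpcr")

# Allowed config keys per subcommand, beyond the common ones.
.pipeline_keys <- list(
  "simulate-tht" = c("t_half_hours", "m0", "n_c", "n_2", "read_interval",
                     "duration", "n_replicates", "baseline", "amplitude",
                     "noise_sd_fraction", "inhibition_factors"),
  "simulate-plaques" = c("image_shape", "n_plaques", "plaque_radius_range",
                         "center_plateau_fraction", "border_intensity_fraction",
                         "center_intensity", "marker_base",
                         "marker_center_border_ratio", "background_level",
                         "noise_sd"),
  "simulate-qpcr" = c("true_levels", "slope", "ct_standard", "noise_sd_ct",
                      "n_technical"),
  "fit-tht" = c("input", "wells", "m0", "n_c", "n_2", "n_starts"),
  "zonate" = c("plaque", "marker", "threshold_fraction", "min_diameter_px",
               "paired"),
  "qpcr" = c("input", "mode")
)

#' Run a pipeline subcommand from a validated configuration
#'
#' Dispatches to the simulation, kinetics-fitting, zonation or qPCR
#' operations, writes the result files under `out`, and records a JSON run
#' report (`run_report.json`: command, configuration, seed, package
#' version, outputs, warnings) sufficient to reproduce the run.
#'
#' @param config a named list (or path to a JSON file) with at least
#'   `command` (one of `simulate-tht`, `simulate-plaques`, `simulate-qpcr`,
#'   `fit-tht`, `zonate`, `qpcr`) and `out` (output directory); `seed` is
#'   required wherever randomness is involved. Unknown keys are rejected.
#' @return Invisibly, a list with the command's results and `report`, the
#'   report path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  if (is.null(config$command) || !config$command %in% .pipeline_commands)
    stop("config$command must be one of: ",
         paste(.pipeline_commands, collapse = ", "))
  if (is.null(config$out)) stop("config$out (output directory) is required")
  cmd <- config$command
  common <- c("command", "out", "seed", "verbose")
  unknown <- setdiff(names(config), c(common, .pipeline_keys[[cmd]]))
  if (length(unknown))
    stop("unknown config key(s) for '", cmd, "': ",
         paste(unknown, collapse = ", "))
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warns <- character()
  result <- withCallingHandlers(
    .pipeline_dispatch(cmd, config, out_dir),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  report <- list(command = cmd,
                 config = config[setdiff(names(config), "command")],
                 seed = config$seed,
                 package_version = as.character(utils::packageVersion("plaquekin")),
                 outputs = result$outputs, warnings = warns)
  report_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(result, list(report = report_path)))
}

.pipeline_dispatch <- function(cmd, cfg, out_dir) {
  g <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  switch(cmd,
    "simulate-tht" = {
      params <- params_for_half_time(g("t_half_hours", 0.8),
                                     m0 = g("m0", 5e-6),
                                     n_c = g("n_c", 2), n_2 = g("n_2", 2))
      inh <- unlist(g("inhibition_factors", list(control = 1)))
      sim <- simulate_tht_plate(params,
                                read_interval = g("read_interval", 400),
                                duration = g("duration", NULL),
                                n_replicates = g("n_replicates", 3L),
                                baseline = g("baseline", 100),
                                amplitude = g("amplitude", 900),
                                noise_sd_fraction = g("noise_sd_fraction", 0.01),
                                inhibition_factors = inh,
                                seed = cfg$seed, dir = out_dir)
      list(simulation = sim, outputs = as.list(sim$files))
    },
    "simulate-plaques" = {
      sim <- simulate_plaque_field(
        image_shape = g("image_shape", c(512L, 512L)),
        n_plaques = g("n_plaques", 10L),
        plaque_radius_range = g("plaque_radius_range", c(18, 30)),
        center_plateau_fraction = g("center_plateau_fraction", 0.6),
        border_intensity_fraction = g("border_intensity_fraction", 0.6),
        center_intensity = g("center_intensity", 1000),
        marker_base = g("marker_base", 100),
        marker_center_border_ratio = g("marker_center_border_ratio", 1.5),
        background_level = g("background_level", 50),
        noise_sd = g("noise_sd", 5),
        seed = cfg$seed, dir = out_dir)
      list(simulation = sim, outputs = as.list(sim$files))
    },
    "simulate-qpcr" = {
      sim <- simulate_qpcr_run(unlist(cfg$true_levels),
                               slope = g("slope", -3.32),
                               ct_standard = g("ct_standard", 20),
                               noise_sd_ct = g("noise_sd_ct", 0.1),
                               n_technical = g("n_technical", 3L),
                               seed = cfg$seed,
                               path = file.path(out_dir, "qpcr.csv"))
      list(simulation = sim,
           outputs = list(qpcr = file.path(out_dir, "qpcr.csv")))
    },
    "fit-tht" = {
      if (is.null(cfg$input)) stop("fit-tht requires config$input (plate CSV)")
      traces <- read_plate_csv(cfg$input, wells = cfg$wells)
      by_cond <- split(traces, vapply(traces, `[[`, character(1), "condition"))
      fits <- lapply(by_cond, function(trs)
        fit_secondary_nucleation(lapply(trs, normalize_trace),
                                 m0 = g("m0", 5e-6),
                                 n_c = g("n_c", 2), n_2 = g("n_2", 2),
                                 n_starts = g("n_starts", 25L),
                                 seed = g("seed", 1L)))
      fit_path <- file.path(out_dir, "fit.json")
      jsonlite::write_json(lapply(fits, function(f)
        list(lambda_per_s = f$lambda, kappa_per_s = f$kappa,
             k_n_k_plus = f$k_n_k_plus, k_2_k_plus = f$k_2_k_plus,
             n_c = f$n_c, n_2 = f$n_2, m0 = f$m0,
             t_half_hours = f$t_half, residual_rms = f$residual_rms,
             converged = f$converged, n_restarts_used = f$n_restarts_used,
             seed = f$seed)),
        fit_path, auto_unbox = TRUE, digits = NA)
      list(fits = fits, outputs = list(fit = fit_path))
    },
    "zonate" = {
      if (is.null(cfg$plaque) || is.null(cfg$marker))
        stop("zonate requires config$plaque and config$marker (TIFF paths)")
      img <- read_multichannel_tiff(c(cfg$plaque, cfg$marker))
      z <- zonate_field(img,
                        threshold_fraction = g("threshold_fraction", 0.6),
                        min_diameter_px = g("min_diameter_px", 10),
                        paired = g("paired", TRUE))
      tab_path <- file.path(out_dir, "zones.csv")
      if (!is.null(z$table)) utils::write.csv(z$table, tab_path, row.names = FALSE)
      test_path <- file.path(out_dir, "enrichment_test.json")
      if (!is.null(z$test))
        jsonlite::write_json(z$test, test_path, auto_unbox = TRUE, digits = NA)
      list(zonation = z,
           outputs = list(zones = tab_path,
                          test = if (is.null(z$test)) NULL else test_path))
    },
    "qpcr" = {
      if (is.null(cfg$input)) stop("qpcr requires config$input (ct CSV)")
      tab <- qpcr_levels(read_qpcr_csv(cfg$input), mode = g("mode", "literal"))
      lv_path <- file.path(out_dir, "levels.csv")
      utils::write.csv(tab, lv_path, row.names = FALSE)
      list(levels = tab, outputs = list(levels = lv_path))
    })
}
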