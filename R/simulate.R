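#' Simulate a ThT plate-reader aggregation experiment
#'
#' Generates sigmoidal plate-reader traces from the closed-form
#' primary + secondary nucleation model: per condition,
#' `intensity(t) = baseline + amplitude * M(t)/M(inf) + Gaussian noise`,
#' sampled on a regular read grid. Conditions are defined by multipliers
#' applied to the secondary nucleation rate constant (and optionally the
#' primary rate), emulating aggregation inhibitors that delay the reaction.
#' The defaults mirror a quiescent unseeded assay at 5 uM monomer read
#' every 400 s in triplicate.
#'
#' @param params generating [kinetic_parameters()]; default gives a
#'   half-time of 0.8 h at 5 uM monomer, the uninhibited reference
#'   condition.
#' @param read_interval seconds between reads (default 400).
#' @param duration total assay duration in seconds; default spans 5
#'   half-times of the slowest condition.
#' @param n_replicates replicates per condition (default 3).
#' @param baseline,amplitude raw fluorescence offset and dynamic range
#'   (a.u.; defaults 100 and 900).
#' @param noise_sd_fraction Gaussian noise SD as a fraction of amplitude
#'   (default 0.01).
#' @param inhibition_factors named numeric vector of multipliers applied to
#'   `k_2` per condition (default `c(control = 1)`).
#' @param also_scale_k_n apply the multipliers to `k_n` too (default FALSE).
#' @param seed integer seed (mandatory).
#' @param dir optional output directory: writes `plate.csv` (column
#'   `time_s` plus one column per well), `wells.json` (well -> condition,
#'   replicate) and `ground_truth.json`.
#' @return List with `traces` (list of [tht_trace()]), `ground_truth`
#'   (generating `t_half` hours per condition, generating parameters,
#'   noiseless curves) and, when `dir` is given, `files`.
#' @export
simulate_tht_plate <- function(params = params_for_half_time(0.8),
                               read_interval = 400, duration = NULL,
                               n_replicates = 3L, baseline = 100,
                               amplitude = 900, noise_sd_fraction = 0.01,
                               inhibition_factors = c(control = 1),
                               also_scale_k_n = FALSE, seed, dir = NULL) {
  stopifnot(inherits(params, "kinetic_parameters"), read_interval > 0,
            n_replicates >= 1L, noise_sd_fraction >= 0,
            length(inhibition_factors) >= 1L,
            !is.null(names(inhibition_factors)))
  if (missing(seed)) stop("seed is required; generators are never unseeded")
  cond_params <- lapply(inhibition_factors, function(f) {
    kinetic_parameters(params$k_plus, params$k_n * (if (also_scale_k_n) f else 1),
                       params$k_2 * f, params$n_c, params$n_2, params$m0)
  })
  t_half_true <- vapply(cond_params, function(p) {
    lk <- lambda_kappa(p)
    .half_time_lk(lk[["lambda"]], lk[["kappa"]], p$n_c, p$n_2) / 3600
  }, numeric(1))
  if (is.null(duration)) duration <- 5 * max(t_half_true) * 3600
  if (duration < max(t_half_true) * 3600)
    warning("duration is shorter than the slowest generating half-time; ",
            "curves will be incomplete")
  tg <- seq(0, duration, by = read_interval)
  curves <- lapply(cond_params, closed_form_mass_fraction, t = tg)
  traces <- with_seed(seed, {
    out <- list()
    for (cond in names(inhibition_factors)) {
      for (r in seq_len(n_replicates)) {
        noise <- stats::rnorm(length(tg), 0, noise_sd_fraction * amplitude)
        out[[paste0(cond, "_r", r)]] <-
          tht_trace(tg, baseline + amplitude * curves[[cond]] + noise,
                    condition = cond, replicate = r)
      }
    }
    out
  })
  gt <- list(t_half = t_half_true, params = cond_params, curves = curves,
             times = tg, baseline = baseline, amplitude = amplitude,
             noise_sd_fraction = noise_sd_fraction, seed = seed)
  res <- list(traces = traces, ground_truth = gt)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    plate <- file.path(dir, "plate.csv")
    wellsf <- file.path(dir, "wells.json")
    gtf <- file.path(dir, "ground_truth.json")
    write_plate_csv(traces, plate)
    write_wells_json(traces, wellsf)
    jsonlite::write_json(list(t_half_hours = as.list(t_half_true), seed = seed),
                         gtf, auto_unbox = TRUE, digits = NA)
    res$files <- c(plate = plate, wells = wellsf, ground_truth = gtf)
  }
  res
}

#' Simulate a two-channel plaque field with ground truth
#'
#' Builds a plaque channel of non-overlapping radially structured deposits
#' — a bright inner plateau, a short linear ramp, and a border annulus at
#' `border_intensity_fraction` of the center intensity, the "steep drop"
#' morphology of zinc-stained amyloid plaques — over a uniform background
#' with Gaussian noise. The marker channel is flat at `marker_base` over
#' each plaque and `marker_center_border_ratio`-fold higher over the true
#' center zone, so the generating center/border marker ratio is known
#' exactly.
#'
#' @param image_shape integer pair (rows, cols), default `c(512, 512)`.
#' @param n_plaques number of plaques (default 10).
#' @param plaque_radius_range min/max outer radius in pixels (default
#'   `c(18, 30)`, i.e. deposits roughly 40-60 um across at ~1 um/px).
#' @param center_plateau_fraction inner-plateau radius as a fraction of the
#'   outer radius (default 0.5).
#' @param border_intensity_fraction border plateau as a fraction of center
#'   intensity (default 0.6, the published figure).
#' @param center_intensity plaque-channel center level (a.u., default 1000).
#' @param marker_base marker level over the border zone (a.u., default 100).
#' @param marker_center_border_ratio marker enrichment of the center zone
#'   (default 1.5).
#' @param background_level,noise_sd background offset and Gaussian noise SD
#'   (defaults 50 and 5 a.u.).
#' @param ramp_px width of the center-to-border ramp (default 2 px).
#' @param zone_rule_fraction fraction of center intensity defining the true
#'   zone boundary on the noiseless profile (default 0.6, the published
#'   rule). When it does not exceed `border_intensity_fraction` the rule
#'   cannot separate the plateaus and the true boundary is placed at the
#'   ramp midpoint instead.
#' @param seed integer seed (mandatory).
#' @param dir optional directory: writes `plaque.tif`, `marker.tif` and
#'   `ground_truth.json` (centers, radii, ratio).
#' @return List with `image` (a [multichannel_image()]) and `ground_truth`:
#'   per-plaque `center` (row, col), `radius`, `center_mask` and
#'   `border_mask` (coordinate matrices; zones per `zone_rule_fraction`
#'   applied to the noiseless profile), and the generating `marker_ratio`.
#' @export
simulate_plaque_field <- function(image_shape = c(512L, 512L), n_plaques = 10L,
                                  plaque_radius_range = c(18, 30),
                                  center_plateau_fraction = 0.6,
                                  border_intensity_fraction = 0.6,
                                  center_intensity = 1000, marker_base = 100,
                                  marker_center_border_ratio = 1.5,
                                  background_level = 50, noise_sd = 5,
                                  ramp_px = 2, zone_rule_fraction = 0.6,
                                  seed, dir = NULL) {
  stopifnot(length(image_shape) == 2L, n_plaques >= 0L,
            center_plateau_fraction > 0, center_plateau_fraction <= 1,
            border_intensity_fraction > 0, border_intensity_fraction <= 1,
            marker_center_border_ratio > 0, noise_sd >= 0)
  if (missing(seed)) stop("seed is required; generators are never unseeded")
  nr <- image_shape[1]; nc <- image_shape[2]
  res <- with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    attempts <- 0L
    while (length(radii) < n_plaques) {
      attempts <- attempts + 1L
      if (attempts > 1e4)
        stop("could not place ", n_plaques, " non-overlapping plaques in ",
             nr, " x ", nc, "; reduce n_plaques or plaque_radius_range")
      r <- stats::runif(1, plaque_radius_range[1], plaque_radius_range[2])
      margin <- r + ramp_px + 3
      cy <- stats::runif(1, margin, nr - margin)
      cx <- stats::runif(1, margin, nc - margin)
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(dd < radii + r + 2 * ramp_px + 6)) next
      }
      centers <- rbind(centers, c(cy, cx))
      radii <- c(radii, r)
    }
    plaque <- matrix(background_level, nr, nc)
    marker <- matrix(background_level, nr, nc)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    gt <- list()
    for (i in seq_len(length(radii))) {
      r_out <- radii[i]
      r_in <- center_plateau_fraction * r_out
      d <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
      b <- border_intensity_fraction
      prof <- ifelse(d <= r_in, 1,
              ifelse(d <= r_in + ramp_px, 1 - (1 - b) * (d - r_in) / ramp_px,
              ifelse(d <= r_out, b,
              ifelse(d <= r_out + ramp_px, b * (1 - (d - r_out) / ramp_px), 0))))
      plaque <- plaque + center_intensity * prof
      # true zones: the zone rule applied to the noiseless radial profile;
      # when the border plateau is not strictly below the rule the rule
      # cannot separate the plateaus and the split falls back to the
      # geometric ramp midpoint
      d_zone <- if (zone_rule_fraction > b)
        r_in + ramp_px * (1 - zone_rule_fraction) / (1 - b)
      else r_in + ramp_px / 2
      in_center <- d <= d_zone
      in_border <- d > d_zone & d <= r_out
      in_fade <- d > r_out & d <= r_out + ramp_px
      marker[in_center] <- marker_center_border_ratio * marker_base
      marker[in_border] <- marker_base
      marker[in_fade] <- marker_base  # marker follows the deposit to its rim
      gt[[i]] <- list(center = centers[i, ], radius = r_out,
                      center_mask = which(in_center, arr.ind = TRUE),
                      border_mask = which(in_border, arr.ind = TRUE))
    }
    if (noise_sd > 0) {
      plaque <- plaque + stats::rnorm(nr * nc, 0, noise_sd)
      marker <- marker + stats::rnorm(nr * nc, 0, noise_sd)
    }
    plaque <- pmax(plaque, 0)
    marker <- pmax(marker, 0)
    list(image = multichannel_image(plaque, marker),
         ground_truth = list(plaques = gt,
                             marker_ratio = marker_center_border_ratio,
                             border_intensity_fraction = border_intensity_fraction,
                             background_level = background_level, seed = seed))
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pp <- file.path(dir, "plaque.tif"); mp <- file.path(dir, "marker.tif")
    write_multichannel_tiff(res$image, pp, mp)
    gtf <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(list(
      centers = lapply(res$ground_truth$plaques, function(p) p$center),
      radii = vapply(res$ground_truth$plaques, `[[`, numeric(1), "radius"),
      marker_ratio = res$ground_truth$marker_ratio, seed = seed),
      gtf, auto_unbox = TRUE, digits = NA)
    res$files <- c(plaque = pp, marker = mp, ground_truth = gtf)
  }
  res
}

#' Simulate single-plaque diameter profiles
#'
#' Generates radial two-plateau intensity profiles (center plateau,
#' 2-px ramp, border plateau) like those extracted from plaque images,
#' with per-profile variation of the border fraction and additive noise.
#' Used to exercise [derive_zone_threshold()] with known truth.
#'
#' @param n number of profiles.
#' @param center_intensity center plateau level (a.u., default 1000).
#' @param border_fraction mean border/center fraction (default 0.6).
#' @param border_fraction_sd across-profile SD of the fraction (default 0).
#' @param r_inner,r_outer plateau radii in pixels (defaults 8 and 20).
#' @param ramp_px ramp width (default 2).
#' @param noise_sd additive Gaussian noise SD (a.u., default 0).
#' @param seed integer seed (mandatory).
#' @return List with `profiles` (list of `diameter_profile`) and
#'   `ground_truth` (per-profile border fraction).
#' @export
simulate_diameter_profiles <- function(n, center_intensity = 1000,
                                       border_fraction = 0.6,
                                       border_fraction_sd = 0,
                                       r_inner = 8, r_outer = 20, ramp_px = 2,
                                       noise_sd = 0, seed) {
  stopifnot(n >= 1L, border_fraction > 0, border_fraction < 1,
            r_outer > r_inner + ramp_px)
  if (missing(seed)) stop("seed is required; generators are never unseeded")
  with_seed(seed, {
    fr <- pmin(pmax(stats::rnorm(n, border_fraction, border_fraction_sd), 0.05), 0.95)
    pos <- seq(-r_outer, r_outer, by = 1)
    profiles <- lapply(seq_len(n), function(i) {
      d <- abs(pos)
      y <- ifelse(d <= r_inner, 1,
           ifelse(d <= r_inner + ramp_px,
                  1 - (1 - fr[i]) * (d - r_inner) / ramp_px, fr[i]))
      structure(list(position = pos,
                     intensity = center_intensity * y +
                       stats::rnorm(length(pos), 0, noise_sd)),
                class = "diameter_profile")
    })
    list(profiles = profiles, ground_truth = list(border_fraction = fr))
  })
}

#' Simulate per-plaque zone intensity records
#'
#' Record-level generator for power and calibration studies of
#' [zone_enrichment_test()]: per plaque, the border-zone marker mean is
#' log-normally distributed across plaques and the center mean is
#' `ratio`-fold higher, with independent log-normal measurement noise on
#' each zone mean.
#'
#' @param n_plaques number of plaques (default 25).
#' @param ratio generating center/border ratio (1 = null; default 1.5).
#' @param border_mean typical border-zone marker mean (a.u., default 100).
#' @param between_sd_log SD of log border mean across plaques (default 0.2).
#' @param measurement_sd_log SD of log measurement noise per zone mean
#'   (default 0.1).
#' @param seed integer seed (mandatory).
#' @return List with `records` (list of [zone_intensity_record()]) and
#'   `ground_truth` (the generating ratio).
#' @export
simulate_zone_records <- function(n_plaques = 25L, ratio = 1.5,
                                  border_mean = 100, between_sd_log = 0.2,
                                  measurement_sd_log = 0.1, seed) {
  stopifnot(n_plaques >= 1L, ratio > 0)
  if (missing(seed)) stop("seed is required; generators are never unseeded")
  with_seed(seed, {
    b <- border_mean * exp(stats::rnorm(n_plaques, 0, between_sd_log))
    obs_b <- b * exp(stats::rnorm(n_plaques, 0, measurement_sd_log))
    obs_c <- ratio * b * exp(stats::rnorm(n_plaques, 0, measurement_sd_log))
    records <- lapply(seq_len(n_plaques), function(i)
      zone_intensity_record(i, obs_c[i], obs_b[i]))
    list(records = records, ground_truth = list(ratio = ratio))
  })
}

#' Simulate a qPCR run with known expression levels
#'
#' Inverts the exponential standard-curve formula: for each sample,
#' `ct_target = ct_standard + slope * log10(true_level) + noise`, with
#' technical replicates drawn independently.
#'
#' @param true_levels named numeric vector of generating expression levels
#'   (> 0), one per sample.
#' @param slope standard-curve slope (default -3.32, 100% efficiency).
#' @param ct_standard internal-standard ct (default 20 cycles).
#' @param noise_sd_ct per-replicate Gaussian ct noise (default 0.1 cycles).
#' @param n_technical technical replicates per sample (default 3).
#' @param gene,standard_gene labels for the output table.
#' @param seed integer seed (mandatory).
#' @param path optional CSV path written in the qPCR table dialect
#'   (`sample_id, gene, ct_rep1..., standard_gene, ct_standard, slope`).
#' @return List with `table` (the data.frame) and `ground_truth`
#'   (`true_levels`, `slope`).
#' @export
simulate_qpcr_run <- function(true_levels, slope = -3.32, ct_standard = 20,
                              noise_sd_ct = 0.1, n_technical = 3L,
                              gene = "target", standard_gene = "HMBS",
                              seed, path = NULL) {
  stopifnot(is.numeric(true_levels), length(true_levels) >= 1L, slope != 0,
            n_technical >= 1L)
  if (any(true_levels <= 0))
    stop("true expression levels must be positive")
  if (missing(seed)) stop("seed is required; generators are never unseeded")
  if (is.null(names(true_levels)))
    names(true_levels) <- paste0("sample", seq_along(true_levels))
  tab <- with_seed(seed, {
    reps <- t(vapply(true_levels, function(lv)
      ct_standard + slope * log10(lv) + stats::rnorm(n_technical, 0, noise_sd_ct),
      numeric(n_technical)))
    df <- data.frame(sample_id = names(true_levels), gene = gene,
                     stringsAsFactors = FALSE)
    for (j in seq_len(n_technical)) df[[paste0("ct_rep", j)]] <- reps[, j]
    df$standard_gene <- standard_gene
    df$ct_standard <- ct_standard
    df$slope <- slope
    df
  })
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  list(table = tab, ground_truth = list(true_levels = true_levels, slope = slope))
}
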