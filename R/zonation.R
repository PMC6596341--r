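#' Two-channel fluorescence image
#'
#' Container for a plaque-reporting channel (e.g. Zinpyr-1 or Thioflavin
#' staining of amyloid deposits) and a marker channel (e.g. an S100
#' immunostain) acquired on the same field.
#'
#' @param plaque,marker numeric matrices of equal shape, finite and >= 0;
#'   rows are image y, columns image x.
#' @param pixel_size optional micrometers per pixel (metadata only; all
#'   geometry is computed in pixel units).
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(plaque, marker, pixel_size = NULL) {
  stopifnot(is.matrix(plaque), is.matrix(marker))
  if (!all(dim(plaque) == dim(marker)))
    stop("plaque and marker channels must have the same shape")
  if (any(!is.finite(plaque)) || any(!is.finite(marker)))
    stop("intensities must be finite")
  if (min(plaque) < 0 || min(marker) < 0)
    stop("intensities must be non-negative")
  structure(list(plaque = plaque, marker = marker, pixel_size = pixel_size),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("Two-channel image %d x %d px%s\n", nrow(x$plaque), ncol(x$plaque),
              if (is.null(x$pixel_size)) "" else
                sprintf(" (%g um/px)", x$pixel_size)))
  invisible(x)
}

#' Detect plaques in the plaque channel
#'
#' Gaussian smoothing, a global Otsu threshold and connected-component
#' labelling. Components smaller than `min_diameter_px` (equivalent
#' diameter) or touching the image border are discarded; border plaques
#' have incomplete diameter profiles and cannot be zoned reliably.
#'
#' @param image a [multichannel_image()].
#' @param min_diameter_px minimum equivalent diameter in pixels.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @return A list of `plaque_region` objects, each with `region_id`,
#'   `pixels` (n x 2 matrix of row, col), intensity-weighted `centroid`
#'   (row, col) and `equivalent_diameter` in pixels. Empty list if nothing
#'   is detected.
#' @export
detect_plaques <- function(image, min_diameter_px = 5, smooth_sigma = 2) {
  stopifnot(inherits(image, "multichannel_image"))
  img <- image$plaque
  rng <- range(img)
  if (diff(rng) == 0) return(list())
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  norm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  labels <- EBImage::bwlabel(norm > thr)
  lab <- as.integer(labels)
  dim(lab) <- dim(img)
  regions <- list()
  k <- 0L
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (any(idx[, 1] == 1L) || any(idx[, 1] == nrow(img)) ||
        any(idx[, 2] == 1L) || any(idx[, 2] == ncol(img))) next
    eq_d <- 2 * sqrt(nrow(idx) / pi)
    if (eq_d < min_diameter_px) next
    w <- img[idx]
    centroid <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
    k <- k + 1L
    regions[[k]] <- structure(list(region_id = k, pixels = unname(idx),
                                   centroid = centroid,
                                   equivalent_diameter = eq_d),
                              class = "plaque_region")
  }
  regions
}

#' @export
print.plaque_region <- function(x, ...) {
  cat(sprintf("Plaque region %d: %d px, centroid (%.1f, %.1f), eq. diameter %.1f px\n",
              x$region_id, nrow(x$pixels), x$centroid[1], x$centroid[2],
              x$equivalent_diameter))
  invisible(x)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
.bilinear <- function(m, r, c) {
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
  r0 <- pmin(floor(r[ok]), nrow(m) - 1L); c0 <- pmin(floor(c[ok]), ncol(m) - 1L)
  fr <- r[ok] - r0; fc <- c[ok] - c0
  out[ok] <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  out
}

#' Average intensity profile along plaque diameters
#'
#' Samples the plaque channel along `n_diameters` evenly rotated lines
#' through the intensity-weighted centroid, spanning the region's maximal
#' radius, and averages them per position. This is the "plot profile along
#' the diameter" quantification used to characterize the fall from a bright
#' fibrillar center to the border plateau.
#'
#' @param image a [multichannel_image()].
#' @param region a `plaque_region` from [detect_plaques()].
#' @param n_diameters number of rotated diameters to average (default 8).
#' @return An object of class `diameter_profile`: list with `position`
#'   (pixels, negative to positive across the centroid) and `intensity`.
#' @export
diameter_profile <- function(image, region, n_diameters = 8L) {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(region, "plaque_region"), n_diameters >= 1L)
  if (nrow(region$pixels) <= 2L)
    stop("degenerate region (<= 2 px): no diameter to profile")
  ctr <- region$centroid
  d <- sqrt((region$pixels[, 1] - ctr[1])^2 + (region$pixels[, 2] - ctr[2])^2)
  R <- max(d)
  pos <- seq(-floor(R), floor(R), by = 1)
  prof <- matrix(NA_real_, nrow = n_diameters, ncol = length(pos))
  for (k in seq_len(n_diameters)) {
    th <- pi * (k - 1) / n_diameters
    prof[k, ] <- .bilinear(image$plaque, ctr[1] + pos * sin(th),
                           ctr[2] + pos * cos(th))
  }
  structure(list(position = pos, intensity = colMeans(prof, na.rm = TRUE)),
            class = "diameter_profile")
}

#' Derive the border/center intensity fraction from diameter profiles
#'
#' For each profile the center value is the mean over the central 20% of
#' positions and the border value the mean over the outer plateau, located
#' past the steepest drop of the 3-point-smoothed radial profile. The
#' returned threshold fraction is the across-profile mean of border/center
#' — on real Zinpyr-1 data this is the ~60% figure used to split plaques
#' into zones.
#'
#' @param profiles a list of `diameter_profile` objects.
#' @param center_fraction central window as a fraction of the radius
#'   (default 0.2).
#' @param min_drop minimum relative center-to-border drop for a profile to
#'   count as having a detectable border (default 0.1); profiles without it
#'   are excluded with a warning.
#' @param edge_trim fraction of the outermost positions excluded from the
#'   border window (default 0.1), guarding against the fade into
#'   background at the detection boundary.
#' @return Mean border/center fraction (dimensionless, in (0, 1)).
#' @export
derive_zone_threshold <- function(profiles, center_fraction = 0.2,
                                  min_drop = 0.1, edge_trim = 0.1) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "diameter_profile")))
  fracs <- vapply(profiles, function(p) {
    r <- .radial_fold(p)
    R <- max(r$radius)
    center <- mean(r$intensity[r$radius <= center_fraction * R])
    sm <- stats::filter(r$intensity, rep(1 / 3, 3), sides = 2)
    g <- diff(as.numeric(sm))
    g[is.na(g)] <- 0
    drop_i <- which.min(g)  # steepest descent; which.min ties toward center
    lo <- drop_i + 2L
    hi <- which(r$radius <= (1 - edge_trim) * R)
    hi <- if (length(hi)) max(hi) else length(r$radius)
    if (lo > hi) return(NA_real_)
    border <- mean(r$intensity[lo:hi])
    if (!is.finite(border) || !is.finite(center) || center <= 0) return(NA_real_)
    if ((center - border) / center < min_drop) return(NA_real_)
    border / center
  }, numeric(1))
  bad <- !is.finite(fracs)
  if (any(bad))
    warning(sum(bad), " profile(s) without a detectable center-to-border drop excluded")
  if (all(bad)) stop("no profile shows a detectable center-to-border drop")
  mean(fracs[!bad])
}

# Fold a diameter profile about its center into a radial profile.
.radial_fold <- function(profile) {
  pos <- profile$position
  int <- profile$intensity
  rad <- abs(pos)
  agg <- tapply(int, rad, mean, na.rm = TRUE)
  list(radius = as.numeric(names(agg)), intensity = as.numeric(agg))
}

#' Partition a plaque into center and border zones
#'
#' Implements the intensity-fraction rule: the per-plaque reference is the
#' mean plaque-channel intensity over the central 20% of the region (pixels
#' within `center_fraction` of the maximal radius); pixels whose
#' background-corrected intensity is at or above `threshold_fraction` times
#' the background-corrected reference form the center zone, pixels below
#' it but above the detection floor (median intensity outside the region,
#' the background estimate) form the border zone. The correction makes the
#' fraction a property of the fluorophore signal rather than of the camera
#' offset, so the rule is invariant under both gain and offset changes.
#'
#' @param image a [multichannel_image()].
#' @param region a `plaque_region`.
#' @param threshold_fraction fraction of the center reference in (0, 1)
#'   separating the zones (0.6 reproduces the published rule).
#' @param center_fraction radius fraction defining the reference window.
#' @return An object of class `zone_partition`: `region_id`, `center_mask`
#'   and `border_mask` (n x 2 coordinate matrices), `threshold_fraction`,
#'   `center_reference_intensity`, `detection_floor`.
#' @export
partition_zones <- function(image, region, threshold_fraction = 0.6,
                            center_fraction = 0.2) {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(region, "plaque_region"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  img <- image$plaque
  px <- region$pixels
  d <- sqrt((px[, 1] - region$centroid[1])^2 + (px[, 2] - region$centroid[2])^2)
  ctr_idx <- d <= center_fraction * max(d)
  if (!any(ctr_idx)) ctr_idx <- d == min(d)
  reference <- mean(img[px[ctr_idx, , drop = FALSE]])
  outside <- matrix(TRUE, nrow(img), ncol(img))
  outside[px] <- FALSE
  floor_val <- stats::median(img[outside])
  if (reference <= floor_val)
    stop("center reference (", format(reference),
         ") does not exceed the detection floor (", format(floor_val), ")")
  cut <- floor_val + threshold_fraction * (reference - floor_val)
  vals <- img[px]
  in_center <- vals >= cut
  in_border <- !in_center & vals > floor_val
  if (!any(in_center))
    stop("empty center mask: threshold ", format(cut),
         " exceeds the region maximum ", format(max(vals)))
  structure(list(region_id = region$region_id,
                 center_mask = px[in_center, , drop = FALSE],
                 border_mask = px[in_border, , drop = FALSE],
                 threshold_fraction = threshold_fraction,
                 center_reference_intensity = reference,
                 detection_floor = floor_val),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("Zone partition of region %d: %d center px, %d border px (threshold %.2f x %.4g)\n",
              x$region_id, nrow(x$center_mask), nrow(x$border_mask),
              x$threshold_fraction, x$center_reference_intensity))
  invisible(x)
}

#' Quantify marker-channel intensity per plaque zone
#'
#' @param image a [multichannel_image()].
#' @param partition a `zone_partition`.
#' @return An object of class `zone_intensity_record`: `region_id`,
#'   `marker_mean_center`, `marker_mean_border`, `center_border_ratio`
#'   (NA with a warning if the border zone is empty or dark) and
#'   `zone_pixel_counts`.
#' @export
quantify_marker_zones <- function(image, partition) {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(partition, "zone_partition"))
  mc <- mean(image$marker[partition$center_mask])
  mb <- if (nrow(partition$border_mask) > 0)
    mean(image$marker[partition$border_mask]) else NA_real_
  ratio <- if (is.finite(mb) && mb > 0) mc / mb else NA_real_
  if (!is.finite(ratio))
    warning("region ", partition$region_id,
            ": border zone empty or dark, center/border ratio undefined")
  zone_intensity_record(partition$region_id, mc, mb, ratio,
                        c(nrow(partition$center_mask), nrow(partition$border_mask)))
}

#' Construct a zone intensity record
#'
#' @param region_id integer plaque id.
#' @param marker_mean_center,marker_mean_border mean marker intensities (a.u.).
#' @param center_border_ratio their ratio (NA if undefined).
#' @param zone_pixel_counts integer pair (center, border).
#' @return An object of class `zone_intensity_record`.
#' @export
zone_intensity_record <- function(region_id, marker_mean_center,
                                  marker_mean_border, center_border_ratio = NULL,
                                  zone_pixel_counts = c(NA_integer_, NA_integer_)) {
  if (is.null(center_border_ratio))
    center_border_ratio <- if (is.finite(marker_mean_border) && marker_mean_border > 0)
      marker_mean_center / marker_mean_border else NA_real_
  structure(list(region_id = as.integer(region_id),
                 marker_mean_center = marker_mean_center,
                 marker_mean_border = marker_mean_border,
                 center_border_ratio = center_border_ratio,
                 zone_pixel_counts = zone_pixel_counts),
            class = "zone_intensity_record")
}

#' Tabulate zone intensity records
#'
#' @param records a list of `zone_intensity_record` objects.
#' @return A data.frame with one row per plaque.
#' @export
zone_records_table <- function(records) {
  stopifnot(all(vapply(records, inherits, TRUE, "zone_intensity_record")))
  data.frame(
    region_id = vapply(records, `[[`, integer(1), "region_id"),
    marker_mean_center = vapply(records, `[[`, numeric(1), "marker_mean_center"),
    marker_mean_border = vapply(records, `[[`, numeric(1), "marker_mean_border"),
    center_border_ratio = vapply(records, `[[`, numeric(1), "center_border_ratio")
  )
}

#' Test marker enrichment in plaque centers versus borders
#'
#' Two-sided t test of per-plaque mean marker intensity in the center zone
#' against the border zone; paired across plaques by default, matching the
#' plaque-level design of zone quantification.
#'
#' @param records list of `zone_intensity_record` objects (>= 3).
#' @param paired pair center and border within plaque (default TRUE).
#' @return List with `t`, `p`, `mean_difference` (center - border), `df`,
#'   `n`, `paired`.
#' @export
zone_enrichment_test <- function(records, paired = TRUE) {
  stopifnot(length(records) >= 3L,
            all(vapply(records, inherits, TRUE, "zone_intensity_record")))
  ctr <- vapply(records, `[[`, numeric(1), "marker_mean_center")
  brd <- vapply(records, `[[`, numeric(1), "marker_mean_border")
  ok <- is.finite(ctr) & is.finite(brd)
  if (sum(ok) < 3L) stop("fewer than 3 plaques with both zones measurable")
  ctr <- ctr[ok]; brd <- brd[ok]
  if (paired && stats::sd(ctr - brd) == 0)
    stop("zero variance of center-border differences: t statistic undefined")
  if (!paired && stats::sd(ctr) == 0 && stats::sd(brd) == 0)
    stop("zero variance in both groups: t statistic undefined")
  tt <- stats::t.test(ctr, brd, paired = paired)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_difference = mean(ctr) - mean(brd),
       df = unname(tt$parameter), n = length(ctr), paired = paired)
}
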