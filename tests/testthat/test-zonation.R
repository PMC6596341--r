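test_that("detection finds well-separated plaques at their true positions", {
  fld <- simulate_plaque_field(n_plaques = 10, seed = 21)
  regions <- detect_plaques(fld$image, min_diameter_px = 10)
  expect_length(regions, 10)
  truth <- do.call(rbind, lapply(fld$ground_truth$plaques, `[[`, "center"))
  for (rg in regions) {
    d <- sqrt(rowSums((truth - matrix(rg$centroid, nrow(truth), 2,
                                      byrow = TRUE))^2))
    expect_lt(min(d), 2)
  }
})

test_that("constant backgrounds and border-touching plaques yield no regions", {
  flat <- multichannel_image(matrix(7, 64, 64), matrix(1, 64, 64))
  expect_identical(detect_plaques(flat), list())
  # one disk overlapping the image edge
  m <- matrix(0, 64, 64)
  d <- sqrt((row(m) - 2)^2 + (col(m) - 32)^2)
  m[d <= 12] <- 100
  img <- multichannel_image(m, m)
  expect_identical(detect_plaques(img, min_diameter_px = 5), list())
})

test_that("diameter profiles reproduce two-plateau structure and symmetry", {
  disk <- disk_image(size = 101, r_in = 15, r_out = 30,
                     inner = 1000, outer = 600)
  rg <- disk_region(disk)
  pr <- diameter_profile(disk$image, rg, n_diameters = 8)
  n <- length(pr$position)
  expect_equal(pr$intensity, rev(pr$intensity), tolerance = 0.02 * 1000)
  core <- abs(pr$position) <= 10
  expect_equal(mean(pr$intensity[core]), 1000, tolerance = 0.02 * 1000)
  ring <- abs(pr$position) >= 20 & abs(pr$position) <= 27
  expect_equal(mean(pr$intensity[ring]), 600, tolerance = 0.02 * 600)
  # a single diameter agrees with the 8-diameter average for a symmetric disk
  pr1 <- diameter_profile(disk$image, rg, n_diameters = 1)
  expect_equal(pr1$intensity, pr$intensity, tolerance = 0.03 * 1000)
  tiny <- structure(list(region_id = 9L, pixels = cbind(2L, 2L),
                         centroid = c(2, 2), equivalent_diameter = 1),
                    class = "plaque_region")
  expect_error(diameter_profile(disk$image, tiny), "degenerate")
})

test_that("the border/center fraction is recovered from plateau profiles", {
  for (fr in c(0.4, 0.5, 0.6, 0.7)) {
    profs <- replicate(10, plateau_profile(fraction = fr), simplify = FALSE)
    expect_equal(derive_zone_threshold(profs), fr, tolerance = 0.02)
  }
  # averaging over noisy profiles with spread around 0.6
  sim <- simulate_diameter_profiles(50, border_fraction = 0.6,
                                    border_fraction_sd = 0.05,
                                    noise_sd = 10, seed = 31)
  expect_equal(derive_zone_threshold(sim$profiles), 0.6, tolerance = 0.02)
  # profiles without a drop are excluded; all-flat input fails
  flat <- structure(list(position = -20:20, intensity = rep(1000, 41)),
                    class = "diameter_profile")
  expect_warning(
    out <- derive_zone_threshold(list(plateau_profile(fraction = 0.6), flat)),
    "excluded")
  expect_equal(out, 0.6, tolerance = 0.02)
  expect_error(suppressWarnings(derive_zone_threshold(list(flat))),
               "no profile")
})

test_that("partition separates sharp plateaus exactly and degenerates sanely", {
  # uniform disk: everything is center, border empty
  uni <- disk_image(inner = 800, outer = 800)
  pz <- partition_zones(uni$image, disk_region(uni), 0.6)
  expect_equal(nrow(pz$center_mask), nrow(disk_region(uni)$pixels))
  expect_equal(nrow(pz$border_mask), 0L)
  # two sharp plateaus at c and 0.5c, threshold 0.6
  disk <- disk_image(inner = 1000, outer = 500)
  rg <- disk_region(disk)
  pz <- partition_zones(disk$image, rg, 0.6)
  true_center <- which(disk$dist <= disk$r_in, arr.ind = TRUE)
  true_border <- which(disk$dist > disk$r_in & disk$dist <= disk$r_out,
                       arr.ind = TRUE)
  expect_gte(jaccard_index(pz$center_mask, true_center), 0.95)
  expect_gte(jaccard_index(pz$border_mask, true_border), 0.95)
  # near-unity threshold on a peaked plaque: tiny but valid center
  peak <- disk
  peaked <- disk$image$plaque * exp(-disk$dist^2 / (2 * 15^2))
  img <- multichannel_image(peaked, disk$image$marker)
  pz2 <- partition_zones(img, rg, 0.999)
  expect_gt(nrow(pz2$center_mask), 0)
  expect_lt(nrow(pz2$center_mask), nrow(rg$pixels) / 4)
  expect_error(partition_zones(disk$image, rg, 1.2), "threshold_fraction")
})

test_that("partition masks are disjoint, contained, and offset/gain invariant", {
  fld <- simulate_plaque_field(n_plaques = 6, seed = 33)
  regions <- detect_plaques(fld$image, min_diameter_px = 10)
  expect_gt(length(regions), 0)
  for (rg in regions) {
    pz <- partition_zones(fld$image, rg, 0.6)
    keys <- function(m) paste(m[, 1], m[, 2])
    expect_length(intersect(keys(pz$center_mask), keys(pz$border_mask)), 0)
    expect_true(all(c(keys(pz$center_mask), keys(pz$border_mask)) %in%
                      keys(rg$pixels)))
    expect_gt(nrow(pz$center_mask), 0)
    # gain and offset on the plaque channel leave the masks unchanged
    img2 <- multichannel_image(3 * fld$image$plaque + 40, fld$image$marker)
    pz2 <- partition_zones(img2, rg, 0.6)
    expect_identical(pz$center_mask, pz2$center_mask)
    expect_identical(pz$border_mask, pz2$border_mask)
  }
})

test_that("marker quantification is exact on known zones and scale invariant", {
  # uniform marker over the plaque: ratio 1
  disk <- disk_image(inner = 1000, outer = 500, marker_value = 100)
  rg <- disk_region(disk)
  pz <- partition_zones(disk$image, rg, 0.6)
  rec <- quantify_marker_zones(disk$image, pz)
  expect_equal(rec$center_border_ratio, 1.0)
  # noiseless generator: ratio on true masks is exactly the generating 1.5
  fld <- simulate_plaque_field(n_plaques = 4, noise_sd = 0,
                               marker_center_border_ratio = 1.5, seed = 8)
  g <- fld$ground_truth$plaques[[1]]
  part <- structure(list(region_id = 1L, center_mask = g$center_mask,
                         border_mask = g$border_mask, threshold_fraction = 0.6,
                         center_reference_intensity = NA_real_,
                         detection_floor = 0), class = "zone_partition")
  rec2 <- quantify_marker_zones(fld$image, part)
  expect_equal(rec2$center_border_ratio, 1.5)
  # multiplying the marker channel by a constant leaves the ratio unchanged
  img3 <- multichannel_image(fld$image$plaque, fld$image$marker * 37)
  rec3 <- quantify_marker_zones(img3, part)
  expect_equal(rec3$center_border_ratio, rec2$center_border_ratio,
               tolerance = 1e-12)
})

test_that("full zonation pipeline recovers masks and marker ratio from noisy fields", {
  fld <- simulate_plaque_field(n_plaques = 10, border_intensity_fraction = 0.5,
                               seed = 13)
  z <- zonate_field(fld$image, threshold_fraction = 0.6)
  expect_length(z$regions, 10)
  truth <- fld$ground_truth$plaques
  for (i in seq_along(z$regions)) {
    rg <- z$regions[[i]]
    dd <- vapply(truth, function(g) sum((g$center - rg$centroid)^2), numeric(1))
    g <- truth[[which.min(dd)]]
    expect_gte(jaccard_index(z$partitions[[i]]$center_mask, g$center_mask), 0.9)
    expect_gte(jaccard_index(z$partitions[[i]]$border_mask, g$border_mask), 0.9)
  }
  expect_true(all(abs(z$table$center_border_ratio /
                        fld$ground_truth$marker_ratio - 1) < 0.1))
})

test_that("the enrichment test behaves at its degenerate and informative extremes", {
  recs <- lapply(1:5, function(i) zone_intensity_record(i, 10, 10))
  expect_error(zone_enrichment_test(recs), "zero variance")
  sim <- simulate_zone_records(25, ratio = 1.5, seed = 3)
  out <- zone_enrichment_test(sim$records)
  expect_lt(out$p, 0.01)
  expect_gt(out$mean_difference, 0)
  out_unpaired <- zone_enrichment_test(sim$records, paired = FALSE)
  expect_false(out_unpaired$paired)
  expect_error(zone_enrichment_test(sim$records[1:2]), "3")
})
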