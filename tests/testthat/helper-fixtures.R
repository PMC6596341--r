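# Shared fixtures built in code.

# Reference parameter set: t1/2 = 1 h at 5 uM monomer, secondary-dominated.
ref_params <- function(t_half_h = 1) params_for_half_time(t_half_h)

# A circular disk image on zero background: inner plateau `inner` within
# `r_in`, outer plateau `outer` to `r_out`, sharp transitions.
disk_image <- function(size = 101L, r_in = 15, r_out = 30,
                       inner = 1000, outer = 500, marker_value = 100) {
  ctr <- (size + 1) / 2
  d <- sqrt((matrix(seq_len(size), size, size) - ctr)^2 +
            (matrix(seq_len(size), size, size, byrow = TRUE) - ctr)^2)
  plaque <- matrix(0, size, size)
  plaque[d <= r_out] <- outer
  plaque[d <= r_in] <- inner
  marker <- matrix(0, size, size)
  marker[d <= r_out] <- marker_value
  list(image = multichannel_image(plaque, marker), center = c(ctr, ctr),
       dist = d, r_in = r_in, r_out = r_out)
}

# Region covering a disk, as detect_plaques would return it.
disk_region <- function(disk, id = 1L) {
  px <- which(disk$dist <= disk$r_out, arr.ind = TRUE)
  w <- disk$image$plaque[px]
  structure(list(region_id = id, pixels = unname(px),
                 centroid = c(sum(px[, 1] * w), sum(px[, 2] * w)) / sum(w),
                 equivalent_diameter = 2 * sqrt(nrow(px) / pi)),
            class = "plaque_region")
}

# Two-plateau diameter profile object with exact plateaus.
plateau_profile <- function(center = 1000, fraction = 0.6, r_in = 8,
                            r_out = 20, ramp = 2, noise_sd = 0) {
  pos <- seq(-r_out, r_out, by = 1)
  d <- abs(pos)
  y <- ifelse(d <= r_in, 1,
       ifelse(d <= r_in + ramp, 1 - (1 - fraction) * (d - r_in) / ramp, fraction))
  structure(list(position = pos,
                 intensity = center * y + stats::rnorm(length(pos), 0, noise_sd)),
            class = "diameter_profile")
}

# Brute-force one-way ANOVA from sums of squares, as an independent oracle.
anova_oracle <- function(values) {
  y <- unlist(values)
  n <- lengths(values)
  grand <- mean(y)
  ss_between <- sum(n * (vapply(values, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(values) - 1L
  df2 <- length(y) - length(values)
  Fv <- (ss_between / df1) / (ss_within / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}
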