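#' Raw Thioflavin-T plate-reader trace
#'
#' @param times time points in seconds, strictly increasing, length >= 4.
#' @param intensities fluorescence values (a.u.), same length as `times`.
#' @param condition condition label.
#' @param replicate replicate index (integer).
#' @return An object of class `tht_trace`.
#' @export
tht_trace <- function(times, intensities, condition = "sample", replicate = 1L) {
  stopifnot(is.numeric(times), is.numeric(intensities))
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (length(times) < 4L) stop("a trace needs at least 4 points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(!is.finite(times)) || any(!is.finite(intensities)))
    stop("times and intensities must be finite")
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 condition = as.character(condition),
                 replicate = as.integer(replicate)),
            class = "tht_trace")
}

#' @export
print.tht_trace <- function(x, ...) {
  cat(sprintf("ThT trace '%s' replicate %d: %d points, t = %g..%g s, I = %g..%g a.u.\n",
              x$condition, x$replicate, length(x$times),
              min(x$times), max(x$times), min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Normalized fibrillar mass-fraction trace
#'
#' @param times time points in seconds, strictly increasing.
#' @param mass_fraction normalized fibril mass, nominally in \[0, 1\].
#' @param condition,replicate optional provenance labels.
#' @return An object of class `normalized_trace`.
#' @export
normalized_trace <- function(times, mass_fraction, condition = NULL, replicate = NULL) {
  stopifnot(is.numeric(times), is.numeric(mass_fraction),
            length(times) == length(mass_fraction))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times),
                 mass_fraction = as.numeric(mass_fraction),
                 condition = condition, replicate = replicate),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("Normalized trace: %d points, t = %g..%g s, mass fraction %0.3f..%0.3f\n",
              length(x$times), min(x$times), max(x$times),
              min(x$mass_fraction), max(x$mass_fraction)))
  invisible(x)
}

#' Subtract a blank (dye-only) control trace
#'
#' Optional correction for conditions in which an additive alone might
#' shift ThT fluorescence: subtracts a blank well's intensities point by
#' point. Off by default throughout the package, since dye-only controls
#' typically show no systematic variation.
#'
#' @param trace,blank two [tht_trace()] objects on the same time grid.
#' @return A [tht_trace()] with the blank removed and the baseline shifted
#'   so the corrected trace stays non-negative.
#' @export
subtract_blank <- function(trace, blank) {
  stopifnot(inherits(trace, "tht_trace"), inherits(blank, "tht_trace"))
  if (!isTRUE(all.equal(trace$times, blank$times)))
    stop("trace and blank must share one time grid")
  corrected <- trace$intensities - blank$intensities
  tht_trace(trace$times, corrected - min(corrected, 0),
            condition = trace$condition, replicate = trace$replicate)
}

#' Normalize a raw ThT trace to fibrillar mass fraction
#'
#' Maps raw fluorescence onto \[0, 1\] by the two-point rule
#' `(I - baseline) / (plateau - baseline)`, where the baseline is the mean
#' of the first `baseline_points` readings and the plateau the mean of the
#' last `plateau_points`. For a completed sigmoidal reaction the result is
#' the fibrillar mass fraction reported by the dye.
#'
#' @param trace a [tht_trace()].
#' @param baseline_points,plateau_points window sizes (default 5 and 5).
#' @return A [normalized_trace()] carrying the trace's condition/replicate.
#' @export
normalize_trace <- function(trace, baseline_points = 5L, plateau_points = 5L) {
  stopifnot(inherits(trace, "tht_trace"),
            baseline_points >= 1L, plateau_points >= 1L)
  n <- length(trace$times)
  if (baseline_points + plateau_points >= n)
    stop("baseline_points + plateau_points must be smaller than the trace length")
  base <- mean(trace$intensities[seq_len(baseline_points)])
  plat <- mean(trace$intensities[seq.int(n - plateau_points + 1L, n)])
  if (plat <= base)
    stop("plateau mean (", format(plat), ") does not exceed baseline mean (",
         format(base), "): trace is flat or decreasing, cannot normalize")
  normalized_trace(trace$times, (trace$intensities - base) / (plat - base),
                   condition = trace$condition, replicate = trace$replicate)
}

#' Reaction half-time of a normalized trace
#'
#' Time of the first upward crossing of mass fraction 0.5, linearly
#' interpolated between the bracketing samples.
#'
#' @param trace a [normalized_trace()].
#' @return Half-time in hours.
#' @export
half_time <- function(trace) {
  stopifnot(inherits(trace, "normalized_trace"))
  y <- trace$mass_fraction
  t <- trace$times
  hit <- which(y >= 0.5)
  if (length(hit) == 0L)
    stop("trace never reaches mass fraction 0.5: reaction incomplete")
  i <- hit[1L]
  if (i == 1L || y[i] == 0.5) return(t[i] / 3600)
  t_cross <- t[i - 1L] + (0.5 - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
  t_cross / 3600
}

#' Compare fitted half-times against a reference condition
#'
#' @param fits a named list of [fit_secondary_nucleation()] results (class
#'   `secnuc_fit`), or a named numeric vector of half-times in hours.
#' @param reference_label name of the reference condition.
#' @return A data.frame with columns `label`, `t_half` (hours) and
#'   `fold_change` (t_half / reference t_half), sorted by fold change.
#' @export
compare_half_times <- function(fits, reference_label) {
  if (length(fits) == 0L) stop("empty collection of fits")
  if (is.numeric(fits)) {
    th <- fits
  } else {
    stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "secnuc_fit")))
    th <- vapply(fits, function(f) f$t_half, numeric(1))
  }
  if (is.null(names(th)) || any(names(th) == ""))
    stop("fits must be named by condition label")
  if (!reference_label %in% names(th))
    stop("reference label '", reference_label, "' not found; available: ",
         paste(names(th), collapse = ", "))
  out <- data.frame(label = names(th), t_half = unname(th),
                    fold_change = unname(th / th[[reference_label]]),
                    stringsAsFactors = FALSE)
  out[order(out$fold_change), , drop = FALSE]
}
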