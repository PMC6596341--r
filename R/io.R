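#' Read a plate-reader CSV into ThT traces
#'
#' Expects a header row, a first column `time_s` and one column per well.
#' Well-to-condition mapping comes from an optional sidecar JSON (see
#' [read_wells_json()]); without it, each well's name is used as its
#' condition with replicate 1.
#'
#' @param path CSV path.
#' @param wells optional wells mapping: named list `well -> list(condition,
#'   replicate)`, or a path to the sidecar JSON.
#' @return Named list of [tht_trace()] objects, one per well column.
#' @export
read_plate_csv <- function(path, wells = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "time_s")
    stop("plate CSV must have a 'time_s' first column followed by well columns")
  for (j in seq_along(df)) if (!is.numeric(df[[j]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
    stop("non-numeric value in column '", names(df)[j], "' near line ", bad + 1L)
  }
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  if (is.character(wells)) wells <- read_wells_json(wells)
  out <- lapply(names(df)[-1], function(w) {
    cond <- w; repl <- 1L
    if (!is.null(wells) && w %in% names(wells)) {
      cond <- wells[[w]]$condition
      repl <- as.integer(wells[[w]]$replicate)
    }
    tht_trace(df$time_s, df[[w]], condition = cond, replicate = repl)
  })
  names(out) <- names(df)[-1]
  out
}

#' Write ThT traces as a plate-reader CSV
#'
#' @param traces named list of [tht_trace()] objects sharing one time grid;
#'   names become well columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(traces, path) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "tht_trace")),
            !is.null(names(traces)))
  t0 <- traces[[1]]$times
  if (!all(vapply(traces, function(tr) identical(tr$times, t0), TRUE)))
    stop("all traces must share one time grid to form a plate")
  df <- data.frame(time_s = t0)
  for (w in names(traces)) df[[w]] <- traces[[w]]$intensities
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the wells sidecar JSON
#'
#' @param traces named list of [tht_trace()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_wells_json <- function(traces, path) {
  m <- lapply(traces, function(tr)
    list(condition = tr$condition, replicate = tr$replicate))
  jsonlite::write_json(m, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read the wells sidecar JSON
#'
#' @param path JSON path mapping well names to `condition` and `replicate`.
#' @return Named list.
#' @export
read_wells_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path)
}

#' Read a two-channel image from TIFF
#'
#' Accepts either two single-channel files (plaque, marker) or one file
#' holding both channels (as two samples per pixel or two directories).
#' Integer TIFFs are read at their native integer values; float TIFFs are
#' read as-is. No rescaling is applied; the source bit depth is recorded
#' as attribute `bits_per_sample` on each channel.
#'
#' @param paths character vector of length 1 or 2.
#' @param pixel_size optional micrometers per pixel.
#' @return A [multichannel_image()].
#' @export
read_multichannel_tiff <- function(paths, pixel_size = NULL) {
  stopifnot(length(paths) %in% 1:2, all(file.exists(paths)))
  read1 <- function(p) tiff::readTIFF(p, as.is = TRUE, all = TRUE, info = TRUE)
  to_mat <- function(fr, k = 1L) {
    bits <- attr(fr, "bits.per.sample")
    m <- if (length(dim(fr)) == 3L) fr[, , k] else fr
    attributes(m) <- list(dim = dim(m))
    attr(m, "bits_per_sample") <- bits
    m
  }
  if (length(paths) == 2L) {
    chans <- lapply(paths, function(p) to_mat(read1(p)[[1]]))
  } else {
    frames <- read1(paths)
    if (length(frames) >= 2L) {
      chans <- lapply(frames[1:2], to_mat)
    } else if (length(dim(frames[[1]])) == 3L && dim(frames[[1]])[3] >= 2L) {
      chans <- lapply(1:2, function(k) to_mat(frames[[1]], k))
    } else {
      stop("single TIFF must contain two channels (frames or samples)")
    }
  }
  if (!all(dim(chans[[1]]) == dim(chans[[2]])))
    stop("channel shape mismatch: ", paste(dim(chans[[1]]), collapse = "x"),
         " vs ", paste(dim(chans[[2]]), collapse = "x"))
  storage.mode(chans[[1]]) <- "double"
  storage.mode(chans[[2]]) <- "double"
  multichannel_image(chans[[1]], chans[[2]], pixel_size = pixel_size)
}

#' Write a two-channel image as single-channel TIFFs
#'
#' Intensities are rounded to integers and stored as 16-bit grayscale
#' (values above 65535 a.u. are an error); reading the files back with
#' [read_multichannel_tiff()] recovers the rounded values exactly.
#'
#' @param image a [multichannel_image()].
#' @param plaque_path,marker_path output paths.
#' @return Character vector of the two paths, invisibly.
#' @export
write_multichannel_tiff <- function(image, plaque_path, marker_path) {
  stopifnot(inherits(image, "multichannel_image"))
  w1 <- function(m, p) {
    if (max(m) > 65535)
      stop("intensities exceed the 16-bit range; rescale before writing")
    tiff::writeTIFF(round(m) / 65535, p, bits.per.sample = 16L,
                    compression = "none")
  }
  w1(image$plaque, plaque_path)
  w1(image$marker, marker_path)
  invisible(c(plaque_path, marker_path))
}

#' Read a qPCR table CSV
#'
#' Dialect: `sample_id, gene, ct_rep1[, ct_rep2, ...], standard_gene,
#' ct_standard, slope`.
#'
#' @param path CSV path.
#' @return A data.frame with an added `ct_target` column (mean of the
#'   technical replicate columns).
#' @export
read_qpcr_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("sample_id", "gene", "standard_gene", "ct_standard", "slope")
  if (!all(need %in% names(df)))
    stop("qPCR CSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  reps <- grep("^ct_rep", names(df), value = TRUE)
  if (length(reps) == 0L) stop("qPCR CSV needs at least one ct_rep column")
  df$ct_target <- rowMeans(df[, reps, drop = FALSE])
  df
}
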