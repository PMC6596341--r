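# Run code with a local, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Jaccard index of two pixel coordinate sets (n x 2 integer matrices).
#' Jaccard index of two pixel masks
#'
#' @param a,b two-column integer matrices of (row, col) pixel coordinates.
#' @return Intersection over union in \[0, 1\]; 1 for two empty masks.
#' @export
jaccard_index <- function(a, b) {
  ka <- unique(paste(a[, 1], a[, 2]))
  kb <- unique(paste(b[, 1], b[, 2]))
  if (length(ka) == 0L && length(kb) == 0L) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}
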