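#' Virtual mRNA level from qPCR cycle thresholds
#'
#' Converts a target/internal-standard cycle-threshold pair and a
#' standard-curve slope into a relative expression level. Two readings of
#' the published formula are provided: `"literal"` computes
#' `10 * (ct_target - ct_standard) / slope` exactly as printed, and
#' `"exponential"` computes the conventional standard-curve back-calculation
#' `10^((ct_target - ct_standard) / slope)`. The literal form is the
#' default; the exponential form is the one inverted by the qPCR simulator.
#'
#' @param ct_target mean target-gene cycle threshold(s).
#' @param ct_standard internal-standard cycle threshold(s).
#' @param slope standard-curve slope in cycles per log10 dilution
#'   (typically near -3.32 for 100% efficiency); must be nonzero.
#' @param mode `"literal"` or `"exponential"`.
#' @return Numeric level(s) (a.u.), with the mode recorded as attribute
#'   `mode`.
#' @export
#' @examples
#' virtual_mrna_level(23.32, 20, -3.32, mode = "exponential")  # 0.1
virtual_mrna_level <- function(ct_target, ct_standard, slope,
                               mode = c("literal", "exponential")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(ct_target), is.numeric(ct_standard), is.numeric(slope))
  if (any(slope == 0)) stop("standard-curve slope must be nonzero")
  dct <- ct_target - ct_standard
  out <- switch(mode,
                literal = 10 * dct / slope,
                exponential = 10^(dct / slope))
  attr(out, "mode") <- mode
  out
}

#' Mean of technical-replicate ct values
#'
#' @param replicates numeric vector of technical-replicate cycle thresholds.
#' @return Their mean, the ct value entering [virtual_mrna_level()].
#' @export
mean_ct <- function(replicates) {
  stopifnot(is.numeric(replicates), length(replicates) >= 1L,
            all(is.finite(replicates)))
  mean(replicates)
}

#' Normalize densitometry bands to a reference band
#'
#' Western-blot style normalization: each band's integrated density divided
#' by the matched reference band (e.g. beta-III-tubulin) of the same lane.
#'
#' @param records a data.frame with columns `sample_id`, `band`,
#'   `reference` (integrated densities, a.u.).
#' @return A data.frame with columns `sample_id` and `ratio`; empty input
#'   gives an empty data.frame.
#' @export
normalize_densitometry <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "band", "reference") %in% names(records)))
  if (nrow(records) == 0L)
    return(data.frame(sample_id = character(), ratio = numeric()))
  bad <- !is.finite(records$reference) | records$reference <= 0
  if (any(bad))
    stop("non-positive reference intensity for sample(s): ",
         paste(records$sample_id[bad], collapse = ", "))
  data.frame(sample_id = records$sample_id,
             ratio = records$band / records$reference)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise post hoc tests
#'
#' @param values a named list of numeric vectors, one per group, each of
#'   length >= 2.
#' @param alpha significance level recorded in the output (default 0.05).
#' @param var_equal use pooled-variance pairwise t tests (default TRUE,
#'   matching classic post hoc practice); FALSE gives Welch tests.
#' @return An object of class `group_comparison`: `factor_labels`, `F`,
#'   `p`, `df`, and `posthoc`, a data.frame of pairwise comparisons with
#'   raw and Bonferroni-adjusted p values (raw p times the number of
#'   pairs, capped at 1).
#' @export
group_anova_bonferroni <- function(values, alpha = 0.05, var_equal = TRUE) {
  stopifnot(is.list(values), length(values) >= 2L)
  if (is.null(names(values)) || any(names(values) == ""))
    names(values) <- paste0("group", seq_along(values))
  sizes <- lengths(values)
  if (any(sizes < 2L))
    stop("every group needs >= 2 values; offending group(s): ",
         paste(names(values)[sizes < 2L], collapse = ", "))
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), sizes), levels = names(values))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  Fval <- tab[1, "F value"]
  pval <- tab[1, "Pr(>F)"]
  if (!is.finite(Fval)) { Fval <- 0; pval <- 1 }  # zero between-group variance
  pairs <- utils::combn(names(values), 2)
  n_pairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    a <- values[[pairs[1, i]]]; b <- values[[pairs[2, i]]]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(pair = paste(pairs[1, i], pairs[2, i], sep = " vs "),
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_adj = min(1, tt$p.value * n_pairs))
  }))
  structure(list(factor_labels = names(values), F = Fval, p = pval,
                 df = c(tab[1, "Df"], tab[2, "Df"]),
                 posthoc = posthoc, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA over %d groups: F(%d, %d) = %.4g, p = %.4g\n",
              length(x$factor_labels), x$df[1], x$df[2], x$F, x$p))
  cat("Bonferroni post hoc:\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Two-group t test
#'
#' @param a,b numeric vectors, each of length >= 2 (equal lengths if
#'   paired).
#' @param paired paired test (default FALSE).
#' @param var_equal pooled-variance test when unpaired (default TRUE).
#' @return List with `t`, `p`, `df`, `paired`.
#' @export
two_group_ttest <- function(a, b, paired = FALSE, var_equal = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal lengths")
    if (stats::sd(a - b) == 0)
      stop("zero variance of paired differences: t statistic undefined")
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("zero variance in both groups: t statistic undefined")
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), paired = paired)
}
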