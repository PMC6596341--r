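#' Global fit of the secondary-nucleation model to normalized ThT traces
#'
#' Fits the closed-form unseeded primary + secondary nucleation solution
#' jointly to one or more normalized replicate traces by deterministic
#' multi-start least squares. The reaction orders `n_c`, `n_2` and the
#' monomer concentration `m0` are held fixed; the free parameters are the
#' two combined rates \eqn{\lambda} and \eqn{\kappa} (see [lambda_kappa()]),
#' which are the only quantities identifiable from unseeded data. Starting
#' points are drawn log-uniformly over `bounds` from a seeded stream and
#' each is refined with bounded quasi-Newton least squares on the log10
#' scale, so the fit is bit-reproducible given the seed.
#'
#' @param traces a [normalized_trace()] or list of them (replicates and/or
#'   averaged curves), all to be fit by one parameter set.
#' @param m0 initial monomer concentration (M).
#' @param n_c,n_2 fixed reaction orders (default 2 and 2, the conventional
#'   choice for amyloid-beta 42).
#' @param n_starts number of multi-start draws (default 25).
#' @param bounds length-2 search range for both \eqn{\lambda} and
#'   \eqn{\kappa} in s^-1 (default `c(1e-8, 1e-1)`).
#' @param seed integer seed for the start draws.
#' @return An object of class `secnuc_fit` with components `lambda`,
#'   `kappa` (s^-1), `t_half` (hours, from the fitted curve),
#'   `residual_rms`, `converged`, `n_restarts_used`, `seed`, the fixed
#'   settings, identifiable rate products `k_n_k_plus` and `k_2_k_plus`,
#'   and the data. Methods: [print()], [summary()], [coef()], [predict()],
#'   [fitted()], [residuals()], [plot()], [simulate()].
#' @export
#' @examples
#' p <- params_for_half_time(0.8)
#' tg <- seq(0, 4 * 3600, by = 400)
#' tr <- normalized_trace(tg, closed_form_mass_fraction(p, tg))
#' fit <- fit_secondary_nucleation(tr, seed = 1)
#' fit
fit_secondary_nucleation <- function(traces, m0 = 5e-6, n_c = 2, n_2 = 2,
                                     n_starts = 25L, bounds = c(1e-8, 1e-1),
                                     seed = 1L) {
  if (inherits(traces, "normalized_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "normalized_trace")),
            length(bounds) == 2L, bounds[1] > 0, bounds[2] > bounds[1],
            n_starts >= 1L)
  t_all <- unlist(lapply(traces, `[[`, "times"))
  y_all <- unlist(lapply(traces, `[[`, "mass_fraction"))
  lb <- log10(bounds)

  obj <- function(par) {
    mf <- .mass_fraction_lk(10^par[1], 10^par[2], n_c, n_2, t_all)
    sum((mf - y_all)^2)
  }

  starts <- with_seed(seed,
    matrix(stats::runif(2L * n_starts, lb[1], lb[2]), ncol = 2L))
  best <- NULL
  conv_any <- FALSE
  for (i in seq_len(n_starts)) {
    res <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                            lower = lb[1], upper = lb[2],
                            control = list(maxit = 500L)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (res$convergence == 0L) conv_any <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("no start converged: all ", n_starts, " optimizations failed; ",
         "check that traces are normalized and span the transition")

  lambda <- 10^best$par[1]
  kappa  <- 10^best$par[2]
  rms <- sqrt(best$value / length(y_all))
  t_half <- .half_time_lk(lambda, kappa, n_c, n_2) / 3600

  structure(list(
    lambda = lambda, kappa = kappa,
    n_c = n_c, n_2 = n_2, m0 = m0,
    k_n_k_plus = lambda^2 / (2 * m0^n_c),
    k_2_k_plus = kappa^2 / (2 * m0^(n_2 + 1)),
    t_half = t_half,
    residual_rms = rms,
    converged = conv_any,
    n_restarts_used = as.integer(n_starts),
    seed = seed, bounds = bounds,
    traces = traces,
    call = match.call()
  ), class = "secnuc_fit")
}

#' @export
print.secnuc_fit <- function(x, ...) {
  cat("Secondary-nucleation global fit\n")
  cat(sprintf("  lambda = %.4g /s, kappa = %.4g /s (n_c = %g, n_2 = %g, m0 = %.3g M)\n",
              x$lambda, x$kappa, x$n_c, x$n_2, x$m0))
  cat(sprintf("  t1/2 = %.3f h, residual RMS = %.4g, %d traces, converged: %s\n",
              x$t_half, x$residual_rms, length(x$traces), x$converged))
  invisible(x)
}

#' @export
summary.secnuc_fit <- function(object, ...) {
  per_trace <- vapply(object$traces, function(tr) {
    sqrt(mean((stats::predict(object, tr$times) - tr$mass_fraction)^2))
  }, numeric(1))
  out <- list(fit = object, per_trace_rms = per_trace)
  class(out) <- "summary.secnuc_fit"
  out
}

#' @export
print.summary.secnuc_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  identifiable products: k_n*k_plus = %.4g, k_2*k_plus = %.4g\n",
              x$fit$k_n_k_plus, x$fit$k_2_k_plus))
  cat(sprintf("  multi-start: %d log-uniform starts over [%g, %g] /s, seed %d\n",
              x$fit$n_restarts_used, x$fit$bounds[1], x$fit$bounds[2], x$fit$seed))
  cat("  per-trace RMS:", paste(sprintf("%.4g", x$per_trace_rms), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.secnuc_fit <- function(object, ...) {
  c(lambda = object$lambda, kappa = object$kappa)
}

#' Predicted mass fraction from a fitted secondary-nucleation model
#'
#' @param object a `secnuc_fit`.
#' @param times time points in seconds; defaults to the pooled data times.
#' @param ... unused.
#' @return Numeric vector of fitted mass fractions.
#' @export
predict.secnuc_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- sort(unique(unlist(lapply(object$traces, `[[`, "times"))))
  .mass_fraction_lk(object$lambda, object$kappa, object$n_c, object$n_2, times)
}

#' @export
fitted.secnuc_fit <- function(object, ...) {
  lapply(object$traces, function(tr) stats::predict(object, tr$times))
}

#' @export
residuals.secnuc_fit <- function(object, ...) {
  lapply(object$traces, function(tr)
    tr$mass_fraction - stats::predict(object, tr$times))
}

#' Plot data and fitted aggregation curve
#'
#' @param x a `secnuc_fit`.
#' @param ... further arguments passed to [plot.default()].
#' @export
plot.secnuc_fit <- function(x, ...) {
  t_all <- unlist(lapply(x$traces, `[[`, "times"))
  y_all <- unlist(lapply(x$traces, `[[`, "mass_fraction"))
  th <- range(t_all) / 3600
  plot(NA, xlim = th, ylim = range(c(y_all, 0, 1)),
       xlab = "time (h)", ylab = "fibrillar mass fraction", ...)
  for (i in seq_along(x$traces))
    graphics::points(x$traces[[i]]$times / 3600, x$traces[[i]]$mass_fraction,
                     col = "grey40", pch = 16, cex = 0.5)
  tg <- seq(min(t_all), max(t_all), length.out = 400)
  graphics::lines(tg / 3600, stats::predict(x, tg), col = "firebrick", lwd = 2)
  graphics::abline(h = 0.5, v = x$t_half, lty = 3, col = "grey60")
  invisible(x)
}

#' Simulate new noisy plate-reader traces from a fitted model
#'
#' @param object a `secnuc_fit`.
#' @param nsim number of replicate traces.
#' @param seed integer seed.
#' @param read_interval sampling interval in seconds.
#' @param duration total duration in seconds; default spans 4 half-times.
#' @param baseline,amplitude,noise_sd_fraction raw-signal parameters as in
#'   [simulate_tht_plate()].
#' @param ... unused.
#' @return A list of [tht_trace()] objects.
#' @export
simulate.secnuc_fit <- function(object, nsim = 1, seed = 1L,
                                read_interval = 400, duration = NULL,
                                baseline = 100, amplitude = 900,
                                noise_sd_fraction = 0.01, ...) {
  if (is.null(duration)) duration <- 4 * object$t_half * 3600
  tg <- seq(0, duration, by = read_interval)
  mf <- .mass_fraction_lk(object$lambda, object$kappa, object$n_c, object$n_2, tg)
  with_seed(seed, lapply(seq_len(nsim), function(r) {
    tht_trace(tg, baseline + amplitude * mf +
                stats::rnorm(length(tg), 0, noise_sd_fraction * amplitude),
              condition = "simulated", replicate = r)
  }))
}
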