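#' Transcriptional shutdown time course
#'
#' Normalised transcript abundance measured at increasing times after
#' transcription is shut off (for GAL genes, after transfer from galactose to
#' glucose). Abundances are expressed as a fraction of the level at time zero;
#' the constructor renormalises to the first point.
#'
#' @param times minutes, strictly increasing, first element 0.
#' @param abundance positive abundances, same length as \code{times}.
#' @return An object of class \code{"decay_timecourse"}.
#' @export
decay_timecourse <- function(times, abundance) {
  if (length(times) != length(abundance))
    stop("'times' and 'abundance' must have the same length")
  if (length(times) < 2L) stop("need at least two timepoints")
  if (times[1L] != 0) stop("first timepoint must be 0")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(abundance <= 0)) stop("abundances must be positive")
  structure(list(times = as.double(times),
                 abundance = as.double(abundance / abundance[1L])),
            class = "decay_timecourse")
}

#' @export
print.decay_timecourse <- function(x, ...) {
  cat(sprintf("Decay time course: %d timepoints over %g min\n",
              length(x$times), max(x$times)))
  print(data.frame(time = x$times, abundance = signif(x$abundance, 4)))
  invisible(x)
}

#' Fit an exponential decay to a shutdown time course
#'
#' Least-squares fit of \code{A * exp(-delta * t)} (amplitude free, expected
#' close to 1) to a normalised shutdown time course. The default fits by
#' nonlinear least squares on the measured (linear) scale, since the
#' goodness-of-fit metric - the root-mean-square error of the residuals - is
#' quoted on that scale; \code{fit_space = "log"} instead regresses
#' \code{log(abundance)} on time. The 95\% confidence interval for the decay
#' rate comes from the estimator's standard error (t quantile on the residual
#' degrees of freedom).
#'
#' @param tc a [decay_timecourse()] (or a list with \code{times} and
#'   \code{abundance}), at least 3 timepoints.
#' @param fit_space \code{"linear"} (default) or \code{"log"}.
#' @return An object of class \code{"decay_fit"}: a list with
#'   \code{delta_hat} (1/min), \code{se}, \code{rmse}, \code{ci_low},
#'   \code{ci_high}, \code{half_life} (min), \code{amplitude}, and the data.
#' @examples
#' tc <- decay_timecourse(c(0, 5, 10, 20, 30, 60),
#'                        exp(-log(2) / 20.26 * c(0, 5, 10, 20, 30, 60)))
#' fit <- fit_exponential(tc)
#' fit$half_life
#' @export
fit_exponential <- function(tc, fit_space = c("linear", "log")) {
  if (!inherits(tc, "decay_timecourse"))
    tc <- decay_timecourse(tc$times, tc$abundance)
  fit_space <- match.arg(fit_space)
  t <- tc$times
  y <- tc$abundance
  if (length(t) < 3L) stop("need at least 3 timepoints to fit a decay rate")

  # log-linear regression supplies the fit (log space) or the start values (linear)
  lf <- stats::lm(log(y) ~ t)
  slope <- unname(stats::coef(lf)[2L])
  if (slope >= -1e-10)
    stop("no decay: abundance does not decrease with time")

  if (fit_space == "log") {
    delta_hat <- -slope
    se <- summary(lf)$coefficients[2L, 2L]
    amp <- exp(unname(stats::coef(lf)[1L]))
    resid <- y - amp * exp(-delta_hat * t)
    df <- length(t) - 2L
  } else {
    nl <- minpack.lm::nlsLM(
      y ~ A * exp(-d * t),
      start = list(A = exp(unname(stats::coef(lf)[1L])), d = -slope),
      lower = c(A = 0, d = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    co <- stats::coef(nl)
    delta_hat <- unname(co["d"])
    amp <- unname(co["A"])
    se <- summary(nl)$coefficients["d", "Std. Error"]
    resid <- stats::residuals(nl)
    df <- length(t) - 2L
  }
  if (delta_hat <= 1e-10)
    stop("no decay: fitted degradation rate is zero")
  rmse <- sqrt(mean(resid^2))
  qt975 <- stats::qt(0.975, df)
  structure(
    list(delta_hat = delta_hat,
         se = se,
         rmse = rmse,
         ci_low = max(0, delta_hat - qt975 * se),
         ci_high = delta_hat + qt975 * se,
         half_life = log(2) / delta_hat,
         amplitude = amp,
         fit_space = fit_space,
         times = t, abundance = y),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit\n")
  cat(sprintf("  degradation rate: %.5g 1/min  (95%% CI %.5g - %.5g)\n",
              x$delta_hat, x$ci_low, x$ci_high))
  cat(sprintf("  half-life: %.4g min\n", x$half_life))
  cat(sprintf("  amplitude: %.4g, RMSE: %.4g  (%s-scale fit)\n",
              x$amplitude, x$rmse, x$fit_space))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(amplitude = object$amplitude, delta = object$delta_hat)
}

#' @export
predict.decay_fit <- function(object, times = object$times, ...) {
  object$amplitude * exp(-object$delta_hat * times)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$times, x$abundance, xlab = "time (min)",
                 ylab = "normalised abundance",
                 main = sprintf("half-life %.3g min", x$half_life), ...)
  tt <- seq(0, max(x$times), length.out = 200L)
  graphics::lines(tt, predict(x, tt), col = "red")
  invisible(x)
}

#' Resample degradation rates from a fitted decay
#'
#' Draws degradation-rate values from a Beta distribution rescaled to the 95\%
#' confidence interval of the fit, with mean equal to the point estimate. The
#' requested standard deviation is the fit RMSE (the convention adopted for
#' propagating decay-fit uncertainty into the rate inference, which takes the
#' RMSE as the standard deviation of the decay-rate estimator even though the
#' RMSE is measured in abundance units); when that is infeasible on the
#' interval the estimator's standard error is used instead, and if even that
#' exceeds the maximum standard deviation a Beta distribution can attain on
#' the interval, the value is clamped just below the feasible maximum with a
#' warning. A degenerate interval returns the point estimate for every draw.
#'
#' @param fit a [fit_exponential()] result.
#' @param n number of samples, >= 1.
#' @param seed integer seed.
#' @return Numeric vector of length \code{n}, all within
#'   \code{[ci_low, ci_high]}.
#' @export
sample_degradation_rates <- function(fit, n, seed) {
  stopifnot(inherits(fit, "decay_fit"))
  stopifnot_scalar(n, "n")
  if (n < 1) stop("'n' must be >= 1")
  lo <- fit$ci_low
  hi <- fit$ci_high
  if (hi < lo) stop("invalid fit: ci_high < ci_low")
  width <- hi - lo
  if (width <= .Machine$double.eps * max(1, hi))
    return(rep(fit$delta_hat, n))
  if (fit$delta_hat < lo || fit$delta_hat > hi)
    stop("delta_hat must lie inside [ci_low, ci_high]")
  m <- (fit$delta_hat - lo) / width
  m <- min(max(m, 1e-9), 1 - 1e-9)
  sd_max <- sqrt(m * (1 - m))
  s <- fit$rmse / width
  if (s >= sd_max) s <- fit$se / width
  if (s >= sd_max) {
    warning("requested standard deviation infeasible on the confidence ",
            "interval; clamping to the feasible maximum")
    s <- 0.99 * sd_max
  }
  if (s <= 0) return(rep(fit$delta_hat, n))
  nu <- m * (1 - m) / s^2 - 1
  shape1 <- m * nu
  shape2 <- (1 - m) * nu
  with_seed(seed, lo + width * stats::rbeta(n, shape1, shape2))
}
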