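#' Kinetic parameters of the transcription model
#'
#' Bundles the six quantities that drive the stochastic transcription model: a
#' two-state promoter that switches on with rate \code{alpha} and off with rate
#' \code{beta}, initiation at rate \code{gamma} while on, nuclear processing as
#' \code{n_steps} sequential exponential sub-steps each with rate \code{k} (so
#' the initiation-to-export time is Gamma(\code{n_steps}, \code{k}) distributed
#' with mean \code{n_steps / k}), and first-order cytoplasmic degradation at
#' rate \code{delta}. All rates are per minute.
#'
#' \code{n_steps} plays the role of gene length in elongation sub-steps; the
#' default of 30 corresponds to roughly 50 bp per step for a GAL1-scale gene.
#' Note that \code{k} is the per-sub-step rate, and it is \code{k} itself that
#' is reported as the "nuclear processing rate".
#'
#' @param alpha promoter activation rate (1/min), >= 0.
#' @param beta promoter inactivation rate (1/min), >= 0.
#' @param gamma initiation rate while active (1/min), >= 0.
#' @param n_steps integer number of nuclear-processing sub-steps, >= 1.
#' @param k per-sub-step nuclear processing rate (1/min), >= 0.
#' @param delta cytoplasmic degradation rate (1/min), >= 0.
#' @return An object of class \code{"model_params"}.
#' @examples
#' p <- model_params(alpha = 0.1, beta = 0.1, gamma = 0.85, k = 2.33,
#'                   delta = log(2) / 13.53)
#' mean_production_rate(p)
#' @seealso [simulate_population()], [steady_state_means()]
#' @export
model_params <- function(alpha, beta, gamma, n_steps = 30L, k, delta) {
  for (nm in c("alpha", "beta", "gamma", "n_steps", "k", "delta"))
    stopifnot_scalar(get(nm), nm)
  if (alpha < 0 || beta < 0 || gamma < 0 || k < 0 || delta < 0)
    stop("all rates must be non-negative")
  if (n_steps < 1 || n_steps != round(n_steps))
    stop("'n_steps' must be an integer >= 1")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         n_steps = as.integer(n_steps), k = k, delta = delta),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Transcription model parameters (rates in 1/min):\n")
  cat(sprintf("  promoter: activation %.4g, inactivation %.4g\n", x$alpha, x$beta))
  cat(sprintf("  initiation while active: %.4g\n", x$gamma))
  cat(sprintf("  nuclear processing: %d sub-steps at rate %.4g (mean residence %.4g min)\n",
              x$n_steps, x$k, if (x$k > 0) x$n_steps / x$k else Inf))
  cat(sprintf("  cytoplasmic degradation: %.4g", x$delta))
  if (x$delta > 0) cat(sprintf("  (half-life %.4g min)", half_life(x$delta)))
  cat("\n")
  cat(sprintf("  mean production rate: %.4g\n",
              tryCatch(mean_production_rate(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Time-averaged transcription initiation rate
#'
#' The promoter is active a fraction \code{alpha / (alpha + beta)} of the time,
#' so the mean production rate is \code{alpha * gamma / (alpha + beta)}.
#'
#' @param params a [model_params()] object.
#' @return Mean initiation rate in 1/min.
#' @export
mean_production_rate <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$alpha + params$beta <= 0)
    stop("mean production rate undefined when alpha + beta = 0")
  params$alpha * params$gamma / (params$alpha + params$beta)
}

#' Closed-form steady-state mean transcript counts
#'
#' By Little's law the steady-state nuclear mean is the mean production rate
#' times the mean nuclear residence time \code{n_steps / k}, and the
#' cytoplasmic mean is the production rate over the degradation rate. Used as
#' the analytic oracle against which the stochastic simulator is validated.
#'
#' @param params a [model_params()] object with \code{k > 0} and \code{delta > 0}.
#' @return Named numeric vector with elements \code{nuclear} and \code{cytoplasmic}.
#' @export
steady_state_means <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$k <= 0 || params$delta <= 0)
    stop("steady-state means require k > 0 and delta > 0")
  r <- mean_production_rate(params)
  c(nuclear = r * params$n_steps / params$k, cytoplasmic = r / params$delta)
}

#' Half-life of an exponentially decaying transcript
#'
#' @param delta degradation rate in 1/min, > 0.
#' @return Half-life \code{log(2) / delta} in minutes.
#' @export
half_life <- function(delta) {
  stopifnot_scalar(delta, "delta")
  if (delta <= 0) stop("half-life requires delta > 0")
  log(2) / delta
}
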