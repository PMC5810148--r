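#' Default Latin hypercube bounds for rate inference
#'
#' Promoter switching and initiation rates in \code{[0.01, 10]} per minute and
#' per-sub-step processing rates in \code{[0.1, 10]} per minute, stratified on
#' the log scale. These spans bracket the kinetic scales reported for budding
#' yeast genes (switching and initiation on the 0.1-10 per minute scale,
#' nuclear residence times of minutes).
#'
#' @return A 2 x 4 matrix with columns \code{alpha}, \code{beta},
#'   \code{gamma}, \code{k}.
#' @export
default_bounds <- function() {
  rbind(low  = c(alpha = 0.01, beta = 0.01, gamma = 0.01, k = 0.1),
        high = c(alpha = 10,   beta = 10,   gamma = 10,   k = 10))
}

#' Score candidate parameter sets against observed counts
#'
#' For each candidate (a row of \code{candidates}, paired with one degradation
#' rate draw), a population of \code{sim_cells} cells is simulated to
#' \code{t_end} and compared to the observed nuclear and cytoplasmic count
#' distributions by the two-sample Kolmogorov-Smirnov statistic. The combined
#' score is the maximum of the two D statistics by default (conservative: a
#' set must fit both compartments), or their sum.
#'
#' Candidate \code{i} simulates with master seed
#' \code{\link{candidate_seed}(seed, i)}, so scores are reproducible and
#' independent of candidate order.
#'
#' @param candidates matrix/data frame with columns \code{alpha}, \code{beta},
#'   \code{gamma}, \code{k}.
#' @param observed a [count_distribution()].
#' @param delta_samples degradation-rate draws, recycled over candidates.
#' @param sim_cells cells simulated per candidate (a warning is issued below
#'   100, where the empirical CDF is unstable).
#' @param t_end simulation time in minutes.
#' @param n_steps nuclear-processing sub-steps used for all candidates.
#' @param seed integer master seed.
#' @param score \code{"max"} or \code{"sum"}.
#' @return A data frame sorted by ascending combined score, with the candidate
#'   parameters, \code{delta}, \code{ks_nuclear}, \code{ks_cytoplasmic},
#'   \code{score} and the original candidate index.
#' @export
score_parameter_sets <- function(candidates, observed, delta_samples,
                                 sim_cells = 1000L, t_end = 500, n_steps = 30L,
                                 seed = 1L, score = c("max", "sum")) {
  score <- match.arg(score)
  candidates <- as.matrix(candidates)
  if (!nrow(candidates)) stop("'candidates' must be non-empty")
  need <- c("alpha", "beta", "gamma", "k")
  if (!all(need %in% colnames(candidates)))
    stop("candidates need columns alpha, beta, gamma, k")
  stopifnot(inherits(observed, "count_distribution"))
  if (!nrow(observed)) stop("'observed' must be non-empty")
  if (sim_cells < 100)
    warning("sim_cells < 100: empirical CDFs will be unstable")
  nc <- nrow(candidates)
  delta_samples <- rep_len(as.double(delta_samples), nc)

  obs_nuc <- .ecdf_table(observed$nuclear)
  obs_cyt <- .ecdf_table(observed$cytoplasmic)

  d_nuc <- d_cyt <- numeric(nc)
  for (i in seq_len(nc)) {
    m <- .simulate_population_cpp(candidates[i, "alpha"], candidates[i, "beta"],
                                  candidates[i, "gamma"], n_steps,
                                  candidates[i, "k"], delta_samples[i],
                                  as.integer(sim_cells), t_end,
                                  candidate_seed(seed, i))
    d_nuc[i] <- .ks_counts(m[, 1L], obs_nuc)
    d_cyt[i] <- .ks_counts(m[, 2L], obs_cyt)
  }
  comb <- if (score == "max") pmax(d_nuc, d_cyt) else d_nuc + d_cyt
  out <- data.frame(candidates[, need, drop = FALSE],
                    delta = delta_samples,
                    ks_nuclear = d_nuc,
                    ks_cytoplasmic = d_cyt,
                    score = comb,
                    candidate = seq_len(nc))
  out[order(out$score), , drop = FALSE]
}

# histogram mode with Freedman-Diaconis binning (fixed width optional)
.histogram_mode <- function(x, binwidth = NULL) {
  if (!length(x)) stop("no values to take a mode over")
  if (is.null(binwidth)) {
    iqr <- stats::IQR(x)
    binwidth <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else 0
  }
  if (binwidth <= 0 || diff(range(x)) <= 0)
    return(list(mode = stats::median(x), hist = NULL))
  brk <- seq(min(x), max(x) + binwidth, by = binwidth)
  h <- graphics::hist(x, breaks = brk, plot = FALSE)
  top <- which(h$density == max(h$density))
  if (length(top) > 1L)
    warning("multimodal histogram: reporting the leftmost global mode")
  list(mode = h$mids[top[1L]], hist = h)
}

#' Infer transcription rates from nuclear/cytoplasmic count distributions
#'
#' Two-stage distribution-matching inference of the transcription model's
#' rates from per-cell smFISH counts, with the degradation rate supplied by an
#' independent decay fit. Candidate rate sets (\code{alpha}, \code{beta},
#' \code{gamma}, \code{k}) are drawn by Latin hypercube over \code{bounds},
#' paired with Beta-resampled degradation rates, and scored against the
#' observed counts with the Kolmogorov-Smirnov statistic
#' ([score_parameter_sets()]).
#'
#' The fit to the cytoplasmic distribution constrains the mean production rate
#' \code{alpha * gamma / (alpha + beta)} relative to degradation: the
#' \code{retain_k} candidates with the best cytoplasmic fit yield a histogram
#' of mean production rates whose mode is reported. The fit to the nuclear
#' distribution constrains the ratio of mean production rate to nuclear
#' processing rate: from the \code{retain_k} best nuclear fits, ratio samples
#' \code{r / k} are taken, and the cytoplasmic production-rate density is
#' projected through them (production draw divided by ratio draw,
#' \code{n_project} times) to obtain the processing-rate density, whose mode
#' is reported.
#'
#' @param observed a [count_distribution()] with both compartments.
#' @param decay a [fit_exponential()] result supplying the degradation rate.
#' @param n_lhs number of Latin hypercube candidates.
#' @param sim_cells cells simulated per candidate.
#' @param retain_k candidates retained per compartment (the study convention
#'   is the best 1,000 of 1,000,000; scaled-down runs keep the same fraction
#'   or simply the best 1,000).
#' @param t_end simulation time per candidate, minutes.
#' @param n_steps processing sub-steps assumed for all candidates.
#' @param bounds sampling bounds as in [latin_hypercube()].
#' @param score combined-score rule, \code{"max"} (default) or \code{"sum"}.
#' @param n_project draws used to project the production-rate density through
#'   the nuclear ratio samples.
#' @param seed integer master seed for sampling, pairing and scoring.
#' @return An object of class \code{"telegraph_fit"}: a list with
#'   \code{production_rate_mode} and \code{processing_rate_mode} (1/min),
#'   \code{delta_used}, normalised histograms
#'   \code{production_rate_density} / \code{processing_rate_density},
#'   \code{best_samples} (top \code{retain_k} by combined score) and the run
#'   configuration.
#' @examples
#' \donttest{
#' truth <- model_params(alpha = 0.1, beta = 0.1, gamma = 0.85, k = 2.33,
#'                       delta = log(2) / 13.53)
#' obs <- simulate_population(truth, 2000, 500, seed = 7)
#' tc <- gen_decay(truth$delta, noise_sd = 0, n_reps = 1, seed = 1)$timecourses[[1]]
#' fit <- infer_rates(obs, fit_exponential(tc),
#'                    n_lhs = 500, sim_cells = 300, retain_k = 100, seed = 2)
#' fit
#' }
#' @export
infer_rates <- function(observed, decay,
                        n_lhs = 5000L, sim_cells = 1000L, retain_k = 1000L,
                        t_end = 500, n_steps = 30L,
                        bounds = default_bounds(),
                        score = c("max", "sum"),
                        n_project = 10000L, seed = 1L) {
  stopifnot(inherits(observed, "count_distribution"))
  if (!nrow(observed)) stop("'observed' must be non-empty")
  stopifnot(inherits(decay, "decay_fit"))
  score <- match.arg(score)
  retain_k <- min(as.integer(retain_k), as.integer(n_lhs))

  candidates <- latin_hypercube(bounds, n_lhs, seed = seed, log_scale = TRUE)
  deltas <- sample_degradation_rates(decay, n_lhs, seed = candidate_seed(seed, 0))
  scored <- score_parameter_sets(candidates, observed, deltas,
                                 sim_cells = sim_cells, t_end = t_end,
                                 n_steps = n_steps, seed = seed, score = score)
  if (!nrow(scored)) stop("no scored parameter sets retained")

  r_all <- scored$alpha * scored$gamma / (scored$alpha + scored$beta)

  idx_cyt <- order(scored$ks_cytoplasmic)[seq_len(retain_k)]
  idx_nuc <- order(scored$ks_nuclear)[seq_len(retain_k)]
  prod_vals <- r_all[idx_cyt]
  ratio_vals <- r_all[idx_nuc] / scored$k[idx_nuc]

  prod_mode <- .histogram_mode(prod_vals)
  k_proj <- with_seed(candidate_seed(seed, n_lhs + 1), {
    sample(prod_vals, n_project, replace = TRUE) /
      sample(ratio_vals, n_project, replace = TRUE)
  })
  k_mode <- .histogram_mode(k_proj)

  structure(
    list(production_rate_mode = prod_mode$mode,
         processing_rate_mode = k_mode$mode,
         delta_used = decay$delta_hat,
         production_rate_density = prod_mode$hist,
         processing_rate_density = k_mode$hist,
         production_samples = prod_vals,
         ratio_samples = ratio_vals,
         best_samples = utils::head(scored, retain_k),
         n_steps = n_steps,
         config = list(n_lhs = n_lhs, sim_cells = sim_cells,
                       retain_k = retain_k, t_end = t_end,
                       bounds = bounds, score = score,
                       n_project = n_project, seed = seed),
         n_cells_observed = nrow(observed)),
    class = "telegraph_fit"
  )
}

#' @export
print.telegraph_fit <- function(x, ...) {
  cat("Transcription-rate inference (LHS + Kolmogorov-Smirnov)\n")
  cat(sprintf("  observed cells: %d;  candidates: %d;  retained: %d\n",
              x$n_cells_observed, x$config$n_lhs, x$config$retain_k))
  cat(sprintf("  mean production rate (mode): %.4g 1/min\n",
              x$production_rate_mode))
  cat(sprintf("  nuclear processing rate (mode): %.4g 1/min  (%d sub-steps)\n",
              x$processing_rate_mode, x$n_steps))
  cat(sprintf("  degradation rate used: %.4g 1/min (half-life %.4g min)\n",
              x$delta_used, log(2) / x$delta_used))
  invisible(x)
}

#' @export
summary.telegraph_fit <- function(object, ...) {
  cat("Best retained parameter sets (combined score):\n")
  print(utils::head(object$best_samples, 5L))
  cat("\nProduction-rate samples (cytoplasmic fits):\n")
  print(summary(object$production_samples))
  cat("\nProduction/processing ratio samples (nuclear fits):\n")
  print(summary(object$ratio_samples))
  invisible(object)
}

#' @export
coef.telegraph_fit <- function(object, ...) {
  c(production_rate = object$production_rate_mode,
    processing_rate = object$processing_rate_mode,
    degradation_rate = object$delta_used)
}

#' @export
plot.telegraph_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (!is.null(x$production_rate_density))
    graphics::plot(x$production_rate_density, freq = FALSE,
                   main = "mean production rate", xlab = "rate (1/min)")
  if (!is.null(x$processing_rate_density))
    graphics::plot(x$processing_rate_density, freq = FALSE,
                   main = "nuclear processing rate", xlab = "rate (1/min)")
  invisible(x)
}

#' Simulate from a fitted model
#'
#' Simulates a population from the best-scoring retained parameter set of a
#' [infer_rates()] fit (with its paired degradation-rate draw).
#'
#' @param object a \code{telegraph_fit}.
#' @param nsim number of cells.
#' @param seed integer seed.
#' @param t_end simulation time, minutes.
#' @param ... unused.
#' @return A [count_distribution()].
#' @export
simulate.telegraph_fit <- function(object, nsim = 1000L, seed = 1L,
                                   t_end = object$config$t_end, ...) {
  b <- object$best_samples[1L, ]
  p <- model_params(alpha = b$alpha, beta = b$beta, gamma = b$gamma,
                    n_steps = object$n_steps, k = b$k, delta = b$delta)
  simulate_population(p, nsim, t_end, seed = seed)
}
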