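# Independent oracles and shared fixtures for the suite.

# Brute-force two-sample KS: double loop over the pooled values, ECDFs
# evaluated by explicit counting. Deliberately naive and independent of the
# package implementation.
ks_brute_force <- function(a, b) {
  vals <- sort(unique(c(a, b)))
  dmax <- 0
  for (v in vals) {
    fa <- sum(a <= v) / length(a)
    fb <- sum(b <= v) / length(b)
    dmax <- max(dmax, abs(fa - fb))
  }
  dmax
}

# Brute-force single-threshold Otsu: exhaustive search over histogram bins
# maximising between-class variance.
otsu_brute_force <- function(x, nbins = 256L) {
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  m <- h$mids
  best <- -Inf
  best_t <- NA
  for (t in 1:(nbins - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * m[1:t]) / w0
    mu1 <- sum(p[(t + 1):nbins] * m[(t + 1):nbins]) / w1
    v <- w0 * mu0^2 + w1 * mu1^2
    if (v > best) { best <- v; best_t <- h$breaks[t + 1L] }
  }
  best_t
}

# Brute-force two-threshold Otsu: exhaustive search over all bin pairs.
otsu2_brute_force <- function(x, nbins = 256L) {
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  m <- h$mids
  score <- function(idx) {
    w <- sum(p[idx])
    if (w == 0) return(0)
    mu <- sum(p[idx] * m[idx]) / w
    w * mu^2
  }
  best <- -Inf
  best_t <- c(NA, NA)
  for (t1 in 1:(nbins - 2L)) for (t2 in (t1 + 1L):(nbins - 1L)) {
    v <- score(1:t1) + score((t1 + 1L):t2) + score((t2 + 1L):nbins)
    if (v > best) {
      best <- v
      best_t <- h$breaks[c(t1, t2) + 1L]
    }
  }
  best_t
}

# Match segmented cells to planted truth cells by nucleus centre position;
# returns recovered (nuclear, cytoplasmic) in truth order, or NA for cells
# the segmentation did not retain.
match_cells_to_truth <- function(quant, truth_cells) {
  seg <- quant$segmentation
  ids_present <- sort(setdiff(unique(as.vector(seg$cells_2d)), 0L))
  out <- matrix(NA_integer_, nrow(truth_cells), 2L)
  for (i in seq_len(nrow(truth_cells))) {
    cid <- seg$cells_2d[round(truth_cells$y[i]), round(truth_cells$x[i])]
    if (cid > 0) {
      j <- match(cid, ids_present)
      out[i, ] <- c(quant$counts$nuclear[j], quant$counts$cytoplasmic[j])
    }
  }
  colnames(out) <- c("nuclear", "cytoplasmic")
  out
}

# Monte-Carlo standard error of a sample mean
mc_se <- function(x) stats::sd(x) / sqrt(length(x))

# The two engineered-construct operating points: mean production rate,
# per-sub-step processing rate, and cytoplasmic half-life (minutes).
operating_points <- list(
  low_as  = list(production = 0.425, k = 2.33, half_life = 13.53),
  high_as = list(production = 0.256, k = 1.54, half_life = 20.26)
)

op_params <- function(op, n_steps = 30L) {
  # alpha = beta realises the production rate with gamma = 2 * production
  model_params(alpha = 0.1, beta = 0.1, gamma = 2 * op$production,
               n_steps = n_steps, k = op$k, delta = log(2) / op$half_life)
}

# Shared cache for the expensive criterion-scale inference runs so the
# production-rate and processing-rate acceptance blocks (and the recovery
# sweep) reuse a single computation per operating point.
.heavy_cache <- new.env(parent = emptyenv())

heavy_inference <- function(which = c("low_as", "high_as")) {
  which <- match.arg(which)
  if (!is.null(.heavy_cache[[which]])) return(.heavy_cache[[which]])
  op <- operating_points[[which]]
  base_seed <- if (which == "low_as") 101L else 201L
  truth <- op_params(op)
  obs <- gen_fish_counts(truth, n_cells = 2000L, t_end = 500, seed = base_seed)$counts
  dec <- gen_decay(truth$delta, seed = base_seed + 1L)
  dfit <- fit_exponential(dec$mean_timecourse)
  fit <- infer_rates(obs, dfit, n_lhs = 40000L, sim_cells = 1000L,
                     retain_k = 1000L, t_end = 500, seed = base_seed + 2L)
  .heavy_cache[[which]] <- list(truth = op, fit = fit)
  .heavy_cache[[which]]
}
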