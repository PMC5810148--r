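# internal helpers

# Run code with a temporary RNG seed, restoring the caller's .Random.seed so that
# functions taking an explicit `seed` argument do not disturb the global stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# lower-of-the-two-middle-values median: makes the "voxels <= median" set used by
# the background estimator well defined for even counts
median_low <- function(x) {
  x <- sort(x)
  x[[ceiling(length(x) / 2)]]
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive the master seed for candidate i in a scoring run
#'
#' Candidate \code{i} of \code{\link{score_parameter_sets}} simulates its
#' population with master seed \code{candidate_seed(seed, i)}; per-cell
#' substreams are then derived from that master. The mapping is exposed so that
#' callers can reproduce a single candidate's simulation exactly.
#'
#' @param seed integer master seed of the scoring run.
#' @param i candidate index (1-based).
#' @return An integer scalar below \code{2^31}.
#' @export
candidate_seed <- function(seed, i) {
  (as.double(seed) + 1000003 * as.double(i)) %% 2147483647
}
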