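#' Latin hypercube sample over parameter bounds
#'
#' Stratified sampling with exactly one point per equal-width stratum per
#' dimension (on the sampling scale). Dimensions flagged in \code{log_scale}
#' are stratified on the logarithmic scale, which is the natural choice for
#' kinetic rates spanning orders of magnitude.
#'
#' @param bounds a 2 x d matrix (rows: low, high) or a list of length-2
#'   vectors; column/list names become the output column names.
#' @param n number of points, >= 1.
#' @param seed integer seed.
#' @param log_scale logical vector of length d (recycled): stratify this
#'   dimension on the log scale (requires positive bounds).
#' @return An \code{n x d} numeric matrix; the underlying unit-cube sample is
#'   attached as attribute \code{"unit"}.
#' @examples
#' latin_hypercube(rbind(low = c(a = 0, b = 1), high = c(a = 1, b = 10)),
#'                 n = 4, seed = 1)
#' @export
latin_hypercube <- function(bounds, n, seed, log_scale = FALSE) {
  if (is.list(bounds)) bounds <- vapply(bounds, as.double, double(2L))
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L) stop("'bounds' must have two rows (low, high)")
  d <- ncol(bounds)
  if (any(bounds[1L, ] >= bounds[2L, ]))
    stop("each dimension needs low < high")
  stopifnot_scalar(n, "n")
  if (n < 1) stop("'n' must be >= 1")
  log_scale <- rep_len(as.logical(log_scale), d)
  if (any(log_scale & bounds[1L, ] <= 0))
    stop("log-scale dimensions require positive bounds")
  u <- with_seed(seed, lhs::randomLHS(as.integer(n), d))
  out <- matrix(NA_real_, n, d)
  for (j in seq_len(d)) {
    if (log_scale[j]) {
      lo <- log(bounds[1L, j]); hi <- log(bounds[2L, j])
      out[, j] <- exp(lo + u[, j] * (hi - lo))
    } else {
      out[, j] <- bounds[1L, j] + u[, j] * (bounds[2L, j] - bounds[1L, j])
    }
  }
  colnames(out) <- colnames(bounds)
  attr(out, "unit") <- u
  out
}
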