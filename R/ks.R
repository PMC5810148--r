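#' Two-sample Kolmogorov-Smirnov statistic for integer counts
#'
#' The maximum absolute difference between the two right-continuous empirical
#' distribution functions, evaluated over the pooled support. Ties (which are
#' the norm for integer count data) are handled exactly; this is the
#' goodness-of-fit metric used to score simulated count distributions against
#' observed ones.
#'
#' @param a,b non-empty numeric vectors (typically integer counts).
#' @return The KS statistic D in \code{[0, 1]}.
#' @examples
#' ks_statistic(c(0, 0, 1), c(0, 1, 1))  # 1/3
#' @export
ks_statistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  vals <- sort(unique(c(a, b)))
  ca <- cumsum(tabulate(match(a, vals), length(vals))) / length(a)
  cb <- cumsum(tabulate(match(b, vals), length(vals))) / length(b)
  max(abs(ca - cb))
}

# fast path used in candidate scoring: `b_sorted` is reused across candidates.
# ECDFs compared over the pooled support of non-negative integers.
.ks_counts <- function(a, b_ecdf_env) {
  nmax <- max(max(a), b_ecdf_env$max_val)
  ca <- cumsum(tabulate(a + 1L, nmax + 1L)) / length(a)
  cb <- b_ecdf_env$cum(nmax)
  max(abs(ca - cb))
}

# precompute the observed ECDF on 0..max once per inference run
.ecdf_table <- function(b) {
  mv <- max(b)
  cum <- cumsum(tabulate(b + 1L, mv + 1L)) / length(b)
  env <- new.env(parent = emptyenv())
  env$max_val <- mv
  env$cum <- function(nmax) {
    if (nmax <= mv) cum[seq_len(nmax + 1L)]
    else c(cum, rep(1, nmax - mv))
  }
  env
}
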