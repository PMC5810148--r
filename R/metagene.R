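#' Metagene profile around paired sense/antisense TSSs
#'
#' For each gene, three sense-oriented segments are collected: the
#' \code{flank} bases upstream of the sTSS, the inter-TSS region rescaled
#' into \code{n_bins} equal bins (mean per bin), and the \code{flank} bases
#' from the asTSS onwards. Minus-strand genes are mirrored so every profile
#' reads 5' to 3' along the sense transcript. Profiles are averaged across
#' genes. The inter-TSS binning uses boundaries \code{floor(L * j / n_bins)},
#' so bin means times bin widths always sum to the region total.
#'
#' @param track a [signal_track()].
#' @param pairs data frame with \code{stss}, \code{astss}, \code{strand}.
#' @param flank flank length in bp (default 300).
#' @param n_bins inter-TSS bins (30 by default; 100 gives the finer
#'   convention).
#' @param strand_mode \code{"unstranded"}, \code{"sense"} or
#'   \code{"antisense"}: which strand of a stranded track to read per gene.
#' @return A list of class \code{"metagene_profile"} with \code{upstream}
#'   (length \code{flank}), \code{inter} (length \code{n_bins}),
#'   \code{downstream} (length \code{flank}) and \code{n_genes}.
#' @export
metagene_profile <- function(track, pairs, flank = 300L, n_bins = 30L,
                             strand_mode = c("unstranded", "sense", "antisense")) {
  strand_mode <- match.arg(strand_mode)
  if (flank <= 0) stop("'flank' must be positive")
  if (n_bins < 1) stop("'n_bins' must be >= 1")
  ok <- ifelse(pairs$strand == "+",
               pairs$astss > pairs$stss,
               pairs$astss < pairs$stss)
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) with asTSS not downstream of sTSS excluded")
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no valid sTSS/asTSS pairs")

  up <- matrix(NA_real_, nrow(pairs), flank)
  inter <- matrix(NA_real_, nrow(pairs), n_bins)
  down <- matrix(NA_real_, nrow(pairs), flank)
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$stss[i]; a <- pairs$astss[i]; st <- pairs$strand[i]
    tr_strand <- switch(strand_mode,
                        unstranded = NA,
                        sense = st,
                        antisense = if (st == "+") "-" else "+")
    if (st == "+") {
      up[i, ] <- track_values(track, s - flank, s, tr_strand)
      body <- track_values(track, s, a, tr_strand)
      down[i, ] <- track_values(track, a, a + flank, tr_strand)
    } else {
      up[i, ] <- rev(track_values(track, s + 1L, s + 1L + flank, tr_strand))
      body <- rev(track_values(track, a + 1L, s + 1L, tr_strand))
      down[i, ] <- rev(track_values(track, a - flank + 1L, a + 1L, tr_strand))
    }
    L <- length(body)
    bnd <- floor(L * (0:n_bins) / n_bins)
    for (j in seq_len(n_bins)) {
      if (bnd[j + 1L] > bnd[j])
        inter[i, j] <- mean(body[(bnd[j] + 1L):bnd[j + 1L]])
    }
  }
  structure(list(upstream = colMeans(up, na.rm = TRUE),
                 inter = colMeans(inter, na.rm = TRUE),
                 downstream = colMeans(down, na.rm = TRUE),
                 n_genes = nrow(pairs), flank = flank, n_bins = n_bins),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile over %d genes: %d bp flanks, %d inter-TSS bins\n",
              x$n_genes, x$flank, x$n_bins))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  n <- x$flank + x$n_bins + x$flank
  vals <- c(x$upstream, x$inter, x$downstream)
  graphics::plot(seq_len(n), vals, type = "l", xlab = "position (sTSS | binned | asTSS)",
                 ylab = "mean signal", ...)
  graphics::abline(v = c(x$flank + 0.5, x$flank + x$n_bins + 0.5), lty = 2)
  invisible(x)
}

#' Gene compaction score
#'
#' Intragenic chromosomal contact counts normalised by gene length, making
#' compaction comparable across genes of different sizes.
#'
#' @param contacts per-gene intragenic contact sums.
#' @param genes a [gene_table()] (or any data frame with \code{start},
#'   \code{end}).
#' @return Numeric vector of contact density per bp.
#' @export
gene_compaction <- function(contacts, genes) {
  len <- genes$end - genes$start
  if (any(len <= 0)) stop("zero-length gene")
  contacts / len
}

#' Upper and lower quintiles of genes by antisense level
#'
#' Sorts genes by the supplied antisense-transcription level (conventionally
#' the nascent signal in a 300-bp window immediately downstream of the sTSS)
#' and returns the highest and lowest \code{ceiling(n/5)} genes. Ties are
#' broken by stable original order; if all levels are equal the grouping is
#' flagged degenerate.
#'
#' @param levels per-gene antisense levels.
#' @param ids optional gene identifiers (defaults to indices).
#' @return List with \code{high}, \code{low} (ids), \code{size} and
#'   \code{degenerate}.
#' @export
quintile_groups <- function(levels, ids = seq_along(levels)) {
  n <- length(levels)
  if (n < 5L) stop("need at least 5 genes for quintiles")
  if (length(ids) != n) stop("'ids' must match 'levels'")
  q <- ceiling(n / 5)
  ord <- order(levels)  # stable: ties keep original order
  degenerate <- length(unique(levels)) == 1L
  if (degenerate)
    warning("all levels equal: quintile grouping is degenerate")
  list(high = ids[ord[(n - q + 1L):n]],
       low = ids[ord[seq_len(q)]],
       size = q, degenerate = degenerate)
}
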