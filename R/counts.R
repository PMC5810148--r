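#' Per-cell nuclear and cytoplasmic transcript counts
#'
#' The empirical object shared by the simulator, the inference machinery and
#' the smFISH quantification pipeline: one row per cell, with integer counts of
#' transcripts still in the nucleus (nascent transcripts are pooled with
#' nuclear ones) and of mature cytoplasmic transcripts.
#'
#' @param nuclear,cytoplasmic non-negative integer vectors of equal length.
#' @return A data frame of class \code{"count_distribution"} with columns
#'   \code{nuclear} and \code{cytoplasmic}.
#' @export
count_distribution <- function(nuclear, cytoplasmic) {
  if (length(nuclear) != length(cytoplasmic))
    stop("'nuclear' and 'cytoplasmic' must have the same length")
  if (length(nuclear) &&
      (any(nuclear < 0) || any(cytoplasmic < 0) ||
       any(nuclear != round(nuclear)) || any(cytoplasmic != round(cytoplasmic))))
    stop("counts must be non-negative integers")
  structure(
    data.frame(nuclear = as.integer(nuclear),
               cytoplasmic = as.integer(cytoplasmic)),
    class = c("count_distribution", "data.frame")
  )
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("Transcript counts for %d cells\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  nuclear:     mean %.3f, var %.3f, max %d\n",
                mean(x$nuclear), stats::var(x$nuclear), max(x$nuclear)))
    cat(sprintf("  cytoplasmic: mean %.3f, var %.3f, max %d\n",
                mean(x$cytoplasmic), stats::var(x$cytoplasmic), max(x$cytoplasmic)))
  }
  invisible(x)
}

#' Read or write count distributions as tab-separated text
#'
#' Two tab-separated columns (nuclear, cytoplasmic), one row per cell, with
#' \code{#}-prefixed header lines.
#'
#' @param x a [count_distribution()].
#' @param path file path.
#' @return \code{write_counts} returns \code{path} invisibly; \code{read_counts}
#'   returns a [count_distribution()].
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# per-cell transcript counts",
               "# columns: nuclear<TAB>cytoplasmic"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("nuclear", "cytoplasmic"))
  count_distribution(d$nuclear, d$cytoplasmic)
}
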