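# plain-text interchange for the genomics and imaging objects

#' Read and write signal tracks as bedGraph text
#'
#' Standard 4-column bedGraph (chrom, 0-based start, end, value). Stranded
#' tracks use one file per strand.
#'
#' @param track a [signal_track()].
#' @param path file path.
#' @param strand \code{"+"}, \code{"-"} or \code{NA} for unstranded.
#' @return \code{write_bedgraph} returns \code{path} invisibly.
#' @export
write_bedgraph <- function(track, path, strand = NA) {
  stopifnot(inherits(track, "signal_track"))
  v <- if (!track$stranded) track$value
       else if (identical(strand, "+")) track$plus
       else if (identical(strand, "-")) track$minus
       else stop("stranded track: choose strand '+' or '-'")
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  d <- data.frame(chrom = track$chrom, start = starts[keep],
                  end = ends[keep], value = r$values[keep])
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param length chromosome length for the reconstructed track.
#' @export
read_bedgraph <- function(path, length) {
  d <- utils::read.table(path, sep = "\t",
                         col.names = c("chrom", "start", "end", "value"))
  tr <- signal_track(length, stranded = FALSE,
                     chrom = if (nrow(d)) d$chrom[1L] else "chrS")
  for (i in seq_len(nrow(d)))
    tr <- track_add(tr, d$start[i], d$end[i], d$value[i])
  tr
}

#' Read and write gene tables as BED-like TSV
#'
#' Tab-separated with a header line; coordinates 0-based half-open.
#'
#' @param genes a [gene_table()].
#' @param path file path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  gene_table(utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
}

#' Write or read an image stack as multi-page TIFF
#'
#' One page per z plane, 32-bit float. Requires the \pkg{tiff} package.
#'
#' @param img an [image_stack()].
#' @param path file path.
#' @param channel,z_allowed metadata for the reconstructed stack.
#' @export
write_image_stack <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF i/o")
  stopifnot(inherits(img, "image_stack"))
  scale <- max(img$voxels, 1)
  pages <- lapply(seq_len(dim(img$voxels)[1L]),
                  function(z) img$voxels[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, channel = "fish", z_allowed = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF i/o")
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1L]])
  v <- array(0, c(length(pages), d[1L], d[2L]))
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]]
  if (is.null(z_allowed)) z_allowed <- c(1L, length(pages))
  image_stack(v, channel, z_allowed)
}

#' Read and write decay time courses as two-column TSV
#'
#' Columns: time (min) and normalised abundance; \code{#} comment lines
#' allowed.
#'
#' @param tc a [decay_timecourse()].
#' @param path file path.
#' @export
write_decay_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "decay_timecourse"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# decay time course: time_min<TAB>abundance", con)
  utils::write.table(data.frame(tc$times, tc$abundance), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_timecourse
#' @export
read_decay_timecourse <- function(path) {
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("time", "abundance"))
  decay_timecourse(d$time, d$abundance)
}

#' Write a fixture manifest as JSON
#'
#' @param manifest a \code{fixture_manifest}.
#' @param path file path.
#' @export
write_manifest_json <- function(manifest, path) {
  stopifnot(inherits(manifest, "fixture_manifest"))
  m <- manifest
  m$args <- lapply(m$args, function(a) if (is.function(a)) deparse(a) else a)
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Write detected foci as TSV
#'
#' @param foci a [detect_foci()] (optionally quantified) data frame.
#' @param path file path.
#' @export
write_foci <- function(foci, path) {
  utils::write.table(as.data.frame(foci), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
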