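# All genomic coordinates in this module are 0-based half-open; single-base
# positions (TSSs) are 0-based base indices.

#' Per-base signal track on a single chromosome
#'
#' Stranded or unstranded per-base coverage (nascent transcription, ChIP
#' signal, ...) on one chromosome, stored as plain numeric vectors.
#'
#' @param length chromosome length in bp.
#' @param stranded logical.
#' @param chrom chromosome name.
#' @return An object of class \code{"signal_track"} with per-base vectors
#'   \code{plus}/\code{minus} (stranded) or \code{value}.
#' @export
signal_track <- function(length, stranded = TRUE, chrom = "chrS") {
  length <- as.integer(length)
  if (length < 1L) stop("'length' must be >= 1")
  out <- if (stranded)
    list(chrom = chrom, length = length, stranded = TRUE,
         plus = numeric(length), minus = numeric(length))
  else
    list(chrom = chrom, length = length, stranded = FALSE,
         value = numeric(length))
  structure(out, class = "signal_track")
}

#' Extract per-base values over a 0-based half-open window
#'
#' @param track a [signal_track()].
#' @param start,end 0-based half-open window (clipped to the chromosome).
#' @param strand \code{"+"}, \code{"-"} or \code{NA} (unstranded track).
#' @return Numeric vector of length \code{end - start} (positions outside
#'   the chromosome contribute 0).
#' @export
track_values <- function(track, start, end, strand = NA) {
  stopifnot(inherits(track, "signal_track"))
  if (end <= start) return(numeric(0))
  v <- if (!track$stranded) {
    if (!is.na(strand) && !is.null(strand))
      strand <- NA
    track$value
  } else {
    if (is.na(strand)) stop("stranded track requires a strand")
    if (strand == "+") track$plus else if (strand == "-") track$minus
    else stop("strand must be '+' or '-'")
  }
  out <- numeric(end - start)
  lo <- max(start, 0L)
  hi <- min(end, track$length)
  if (hi > lo)
    out[(lo - start + 1L):(hi - start)] <- v[(lo + 1L):hi]
  out
}

#' Add signal to a track in place-like fashion
#'
#' @inheritParams track_values
#' @param values value(s) recycled over the window.
#' @return The modified track.
#' @export
track_add <- function(track, start, end, values, strand = NA) {
  stopifnot(inherits(track, "signal_track"))
  lo <- max(start, 0L); hi <- min(end, track$length)
  if (hi <= lo) return(track)
  idx <- (lo + 1L):hi
  vals <- rep_len(values, end - start)[(lo - start + 1L):(hi - start)]
  if (!track$stranded) track$value[idx] <- track$value[idx] + vals
  else if (strand == "+") track$plus[idx] <- track$plus[idx] + vals
  else if (strand == "-") track$minus[idx] <- track$minus[idx] + vals
  else stop("stranded track requires a strand")
  track
}

#' A table of annotated genes
#'
#' Validates the gene annotation used throughout the TSS/chromatin module.
#' \code{tss_left}/\code{tss_right} bound the annotated TSS region (left-most
#' and right-most annotated TSS), \code{exon1_end} is the genomic coordinate
#' of the first exon-intron boundary, and \code{transcript_end} the annotated
#' transcript end; all 0-based.
#'
#' @param genes data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{exon1_end},
#'   \code{tss_left}, \code{tss_right}, \code{transcript_end}.
#' @return The validated data frame (class \code{"gene_table"}).
#' @export
gene_table <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand",
            "exon1_end", "tss_left", "tss_right", "transcript_end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("missing gene columns: ", paste(miss, collapse = ", "))
  if (any(genes$start >= genes$end)) stop("genes need start < end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Call a TSS from a tag cluster
#'
#' A cluster of capped-5'-end tags (e.g. CAGE) is promoted to a TSS if it
#' holds at least \code{min_tags} tags (two or more overlapping tags mark a
#' validated TSS). The TSS coordinate is the base with the highest 5'-end
#' density; ties resolve to the 5'-most base on the cluster's strand. The
#' call is then vetoed unless the nascent-transcription track shows at least
#' \code{min_nascent} reads in a \code{window}-bp same-strand window
#' immediately downstream.
#'
#' @param cluster list with \code{start} (0-based), \code{strand} and
#'   \code{counts} (per-base 5'-end counts).
#' @param nascent a stranded [signal_track()].
#' @param min_tags minimum total tags (default 2).
#' @param window downstream veto window in bp (default 200).
#' @param min_nascent minimum nascent reads in the window (default 3).
#' @return A list \code{(position, strand, peak_density)}, or \code{NULL} if
#'   the cluster fails either rule.
#' @export
call_tss_from_cluster <- function(cluster, nascent, min_tags = 2,
                                  window = 200, min_nascent = 3) {
  if (!all(c("start", "strand", "counts") %in% names(cluster)))
    stop("cluster needs start, strand, counts")
  if (!cluster$strand %in% c("+", "-")) stop("cluster strand must be '+' or '-'")
  if (!nascent$stranded)
    stop("strand mismatch: nascent track must be stranded")
  counts <- cluster$counts
  if (any(counts < 0)) stop("cluster counts must be non-negative")
  if (sum(counts) < min_tags) return(NULL)
  peak <- max(counts)
  idx <- which(counts == peak)
  i <- if (cluster$strand == "+") idx[1L] else idx[length(idx)]
  pos <- cluster$start + i - 1L
  win <- if (cluster$strand == "+") c(pos + 1L, pos + 1L + window)
         else c(pos - window, pos)
  support <- sum(track_values(nascent, win[1L], win[2L], cluster$strand))
  if (support < min_nascent) return(NULL)
  list(position = pos, strand = cluster$strand, peak_density = peak)
}

#' Assign the predominant sense and antisense TSS to a gene
#'
#' The sense TSS (sTSS) is the highest-density sense-strand TSS found from
#' 500 bp upstream of the left-most annotated TSS to 500 bp downstream of
#' the right-most annotated TSS. The antisense TSS (asTSS) is the
#' highest-density opposite-strand TSS lying strictly between the sTSS and
#' the annotated transcript end. Genes without a sense TSS are signalled
#' (status \code{"no_sTSS"}), not errored.
#'
#' @param gene one row of a [gene_table()].
#' @param tss_list data frame with columns \code{position}, \code{strand},
#'   \code{peak_density}.
#' @param scan_flank bp added on both sides of the annotated TSS window
#'   (default 500).
#' @return List with \code{sTSS}, \code{asTSS} (positions or \code{NULL})
#'   and \code{status}.
#' @export
assign_gene_tss <- function(gene, tss_list, scan_flank = 500) {
  if (!nrow(tss_list))
    return(list(sTSS = NULL, asTSS = NULL, status = "no_sTSS"))
  sense <- gene$strand
  anti <- if (sense == "+") "-" else "+"
  lo <- gene$tss_left - scan_flank
  hi <- gene$tss_right + scan_flank
  cand <- tss_list[tss_list$strand == sense &
                   tss_list$position >= lo & tss_list$position <= hi, ]
  if (!nrow(cand))
    return(list(sTSS = NULL, asTSS = NULL, status = "no_sTSS"))
  stss <- cand$position[which.max(cand$peak_density)]
  if (sense == "+") {
    acand <- tss_list[tss_list$strand == anti &
                      tss_list$position > stss &
                      tss_list$position < gene$transcript_end, ]
  } else {
    acand <- tss_list[tss_list$strand == anti &
                      tss_list$position < stss &
                      tss_list$position > gene$transcript_end, ]
  }
  astss <- if (nrow(acand)) acand$position[which.max(acand$peak_density)] else NULL
  list(sTSS = stss, asTSS = astss, status = "ok")
}

#' Derive sense/antisense TSSs from transcript isoforms
#'
#' The sense TSS comes from the same-strand isoform with the highest
#' nascent-read support that completely encompasses the open reading frame;
#' the antisense TSS from the opposite-strand isoform with the highest
#' support that overlaps the ORF. Used for organisms where TSSs are defined
#' by transcript-isoform sequencing rather than tag clusters.
#'
#' @param gene one row of a [gene_table()] (start/end taken as the ORF).
#' @param isoforms data frame with \code{start}, \code{end} (0-based
#'   half-open), \code{strand}, \code{read_support}.
#' @return List with \code{sTSS}, \code{asTSS} (or \code{NULL}) and
#'   \code{status}.
#' @export
yeast_tss_from_isoforms <- function(gene, isoforms) {
  five_prime <- function(s, e, strand) if (strand == "+") s else e - 1L
  sense <- isoforms[isoforms$strand == gene$strand &
                    isoforms$start <= gene$start &
                    isoforms$end >= gene$end, ]
  if (!nrow(sense))
    return(list(sTSS = NULL, asTSS = NULL, status = "no_sTSS"))
  sb <- sense[which.max(sense$read_support), ]
  stss <- five_prime(sb$start, sb$end, sb$strand)
  anti <- isoforms[isoforms$strand != gene$strand &
                   isoforms$start < gene$end &
                   isoforms$end > gene$start, ]
  astss <- if (nrow(anti)) {
    ab <- anti[which.max(anti$read_support), ]
    five_prime(ab$start, ab$end, ab$strand)
  } else NULL
  list(sTSS = stss, asTSS = astss, status = "ok")
}

#' Position of the asTSS relative to a reference boundary
#'
#' The sense-strand-oriented distance from the sTSS to the asTSS divided by
#' the distance from the sTSS to a reference boundary (typically the first
#' exon-intron boundary, or the 3' end of the ORF): 0 at the sTSS, 1 at the
#' boundary.
#'
#' @param stss,astss,boundary 0-based positions.
#' @param strand gene strand.
#' @return The signed fraction.
#' @export
relative_position <- function(stss, astss, boundary, strand = "+") {
  sgn <- ifelse(strand == "+", 1, -1)
  denom <- sgn * (boundary - stss)
  if (any(denom == 0)) stop("boundary coincides with the sTSS")
  sgn * (astss - stss) / denom
}

#' Randomisation null for relative asTSS positions
#'
#' Re-draws each gene's asTSS uniformly over a per-gene region and
#' accumulates the histogram of relative positions, averaged over
#' \code{n_iter} iterations. This is the null distribution against which
#' the observed preference of asTSSs for the exon boundary is judged.
#'
#' @param genes data frame with \code{stss}, \code{boundary}, \code{strand}.
#' @param regions data frame with \code{start}, \code{end} (0-based
#'   half-open), one row per gene.
#' @param n_iter iterations (the study convention is 1,000).
#' @param seed integer seed.
#' @param breaks histogram breaks on the relative-position axis.
#' @return List with \code{breaks}, \code{mids}, \code{density} (averaged),
#'   \code{n_iter}.
#' @export
randomized_null <- function(genes, regions, n_iter = 1000L, seed = 1L,
                            breaks = seq(0, 1, by = 0.05)) {
  if (n_iter < 1) stop("'n_iter' must be >= 1")
  ok <- regions$end > regions$start
  if (!any(ok)) stop("all regions are empty")
  g <- genes[ok, , drop = FALSE]
  rg <- regions[ok, , drop = FALSE]
  nb <- length(breaks) - 1L
  acc <- numeric(nb)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      pos <- rg$start + floor(stats::runif(nrow(rg)) * (rg$end - rg$start))
      rel <- relative_position(g$stss, pos, g$boundary, g$strand)
      h <- graphics::hist(pmin(pmax(rel, breaks[1L]), breaks[nb + 1L]),
                          breaks = breaks, plot = FALSE)
      acc <- acc + h$density
    }
  })
  list(breaks = breaks, mids = breaks[-1L] - diff(breaks) / 2,
       density = acc / n_iter, n_iter = n_iter)
}
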