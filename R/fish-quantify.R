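#' Classify foci and convert intensities to RNA counts
#'
#' Foci below the knockout-calibrated intensity cutoff are discarded. The
#' remaining foci are classified by the compartment containing their centre
#' voxel: nuclear if it lies in a 2D nucleus footprint (extruded over the
#' allowed z window), cytoplasmic if it lies in the cell but outside the
#' nucleus, and discarded otherwise (outside any retained cell or outside
#' the allowed z window). Every focus receives exactly one of the three
#' labels. The median 27-voxel neighbourhood mean over all accepted foci
#' defines the intensity of a single RNA; each focus is converted to an RNA
#' count by dividing by this median and rounding to the nearest integer
#' (half away from zero). Foci rounding to zero RNAs are dropped - an
#' additional filtering step beyond the knockout cutoff. Per-cell nuclear
#' and cytoplasmic totals are returned for every retained cell, including
#' cells with no foci.
#'
#' @param foci a [detect_foci()] data frame.
#' @param seg a [segment_stack()] result.
#' @param cutoff intensity cutoff from [determine_cutoff()].
#' @return A list of class \code{"fish_quantification"}: \code{counts} (a
#'   [count_distribution()], one row per retained cell), \code{foci} (the
#'   input annotated with \code{compartment}, \code{cell} and
#'   \code{rna_count}), and \code{single_rna_intensity}.
#' @export
classify_and_quantify <- function(foci, seg, cutoff) {
  stopifnot(inherits(seg, "segmentation_result"))
  foci <- as.data.frame(foci)
  n <- nrow(foci)
  compartment <- rep("discarded", n)
  cell <- integer(n)
  zlo <- seg$z_allowed[1L]; zhi <- seg$z_allowed[2L]
  for (i in seq_len(n)) {
    if (foci$raw_intensity[i] < cutoff) next
    z <- foci$z[i]; y <- foci$y[i]; x <- foci$x[i]
    if (z < zlo || z > zhi) next
    nuc <- seg$nuclei_2d[y, x]
    cl <- seg$cells_2d[y, x]
    if (nuc > 0 && cl > 0) {
      compartment[i] <- "nuclear"
      cell[i] <- cl
    } else if (cl > 0) {
      compartment[i] <- "cytoplasmic"
      cell[i] <- cl
    }
  }
  accepted <- compartment != "discarded"
  if (!any(accepted)) {
    warning("no foci accepted; returning an empty distribution")
    foci$compartment <- compartment
    foci$cell <- cell
    foci$rna_count <- 0L
    return(structure(list(counts = count_distribution(integer(0), integer(0)),
                          foci = foci, single_rna_intensity = NA_real_),
                     class = "fish_quantification"))
  }
  med <- stats::median(foci$neighborhood_mean[accepted])
  rna <- integer(n)
  rna[accepted] <- as.integer(round_half_up(foci$neighborhood_mean[accepted] / med))
  foci$compartment <- compartment
  foci$cell <- cell
  foci$rna_count <- rna

  cells <- sort(setdiff(unique(as.vector(seg$cells_2d)), 0L))
  nuc_tot <- cyt_tot <- integer(length(cells))
  for (j in seq_along(cells)) {
    sel <- cell == cells[j] & rna > 0L
    nuc_tot[j] <- sum(rna[sel & compartment == "nuclear"])
    cyt_tot[j] <- sum(rna[sel & compartment == "cytoplasmic"])
  }
  structure(list(counts = count_distribution(nuc_tot, cyt_tot),
                 foci = foci,
                 single_rna_intensity = med),
            class = "fish_quantification")
}

#' @export
print.fish_quantification <- function(x, ...) {
  cat(sprintf("fish_quantification: %d cells, %d accepted foci, 1 RNA = %.4g a.u.\n",
              nrow(x$counts),
              sum(x$foci$compartment != "discarded"),
              x$single_rna_intensity))
  print(x$counts)
  invisible(x)
}

#' End-to-end quantification of one two-channel stack
#'
#' Convenience wrapper running the full pipeline on raw stacks: background
#' subtraction of both channels, foci detection on the FISH channel,
#' segmentation from the DAPI channel, and focus classification /
#' RNA quantification under a supplied intensity cutoff.
#'
#' @param dapi,fish raw [image_stack()] objects.
#' @param cutoff intensity cutoff (from [determine_cutoff()] across the
#'   experiment's strains and knockout).
#' @param profile a [fish_profile()] or profile name.
#' @return A \code{"fish_quantification"} list (see
#'   [classify_and_quantify()]) with the segmentation attached as
#'   \code{segmentation}.
#' @export
quantify_stack <- function(dapi, fish, cutoff,
                           profile = fish_profile("gal1")) {
  if (is.character(profile)) profile <- fish_profile(profile)
  dapi_bs <- subtract_background(dapi)
  fish_bs <- subtract_background(fish)
  foci <- detect_foci(fish_bs)
  seg <- segment_stack(dapi_bs, fish_bs, profile)
  out <- classify_and_quantify(foci, seg, cutoff)
  out$segmentation <- seg
  out
}
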