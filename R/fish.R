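#' Two-channel 3D image stack
#'
#' A light container for one channel of a 3D microscopy stack. Voxels are
#' indexed \code{(z, y, x)}; \code{z_allowed} is the inclusive window of z
#' planes considered in focus (overly blurred planes above and below are
#' excluded from nuclei detection and foci classification).
#'
#' @param voxels 3D numeric array (z, y, x) of non-negative intensities.
#' @param channel \code{"dapi"} or \code{"fish"}.
#' @param z_allowed inclusive \code{c(z_min, z_max)} window within the stack.
#' @return An object of class \code{"image_stack"}.
#' @export
image_stack <- function(voxels, channel = c("fish", "dapi"),
                        z_allowed = c(1L, dim(voxels)[1L])) {
  channel <- match.arg(channel)
  if (length(dim(voxels)) != 3L) stop("'voxels' must be a 3D array (z, y, x)")
  if (any(voxels < 0)) stop("intensities must be non-negative")
  z_allowed <- as.integer(z_allowed)
  if (length(z_allowed) != 2L || z_allowed[1L] < 1L ||
      z_allowed[2L] > dim(voxels)[1L] || z_allowed[1L] > z_allowed[2L])
    stop("'z_allowed' must be an inclusive window within the stack depth")
  structure(list(voxels = voxels, channel = channel, z_allowed = z_allowed),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack [%s]: %d z-planes x %d x %d, z window %d-%d\n",
              x$channel, d[1L], d[2L], d[3L], x$z_allowed[1L], x$z_allowed[2L]))
  invisible(x)
}

#' Analysis profiles for the two imaging configurations
#'
#' The quantification pipeline was tuned separately for two acquisition
#' set-ups: the engineered GAL1 constructs and the endogenous (GFP-tagged)
#' gene set, which were imaged with slightly different optics. Each profile
#' fixes the Gaussian smoothing width, the number of Otsu threshold levels
#' used for nuclei detection, component size limits (voxels), the
#' neighbourhood used for local mean intensities (radius 1 = 27 voxels,
#' radius 2 = 125 voxels), nucleus volume limits and the intensity-histogram
#' bin width used for the knockout cutoff.
#'
#' @param name \code{"gal1"} or \code{"endogenous"}.
#' @return A named list of parameters.
#' @export
fish_profile <- function(name = c("gal1", "endogenous")) {
  name <- match.arg(name)
  if (name == "gal1") {
    list(name = "gal1",
         sigma = 2,
         n_thresholds = 6L,       # segment into 7 levels, cycle levels 3..7
         first_level = 3L,
         comp_min = 50, comp_max = 6000,
         nbhd_radius = 1L,         # 27-voxel neighbourhood
         grow_frac = 0.65,
         mean_floor = 0.025,
         vol_floor = 50,
         vol_ceiling = 3000,       # removed as "too large" after cell detection
         merge_dist = 6,
         cutoff_bin_width = 250)
  } else {
    list(name = "endogenous",
         sigma = 2.5,
         n_thresholds = 2L,        # segment into 3 levels, keep the top one
         first_level = 3L,
         comp_min = 600, comp_max = 40000,
         nbhd_radius = 2L,         # 125-voxel neighbourhood
         grow_frac = 0.65,
         mean_floor = 0.025,
         vol_floor = 200,
         vol_ceiling = 20000,
         merge_dist = 6,
         cutoff_bin_width = 50)
  }
}

#' Background-subtract an image stack
#'
#' The background is estimated as the median voxel intensity plus a spread
#' term computed, like a standard deviation, over the voxels at or below the
#' median: \code{sqrt(sum((p_i - p_med)^2) / (N_i - 1))}. This one-sided
#' spread avoids inflating the background with signal voxels. The background
#' is subtracted everywhere and negative intensities are clamped to zero. The
#' median convention for even voxel counts is the lower of the two middle
#' values, which keeps the "at or below the median" set well defined.
#'
#' @param img an [image_stack()].
#' @return The background-subtracted [image_stack()].
#' @export
subtract_background <- function(img) {
  stopifnot(inherits(img, "image_stack"))
  v <- img$voxels
  if (!length(v)) stop("empty image stack")
  p_med <- median_low(as.vector(v))
  below <- v[v <= p_med]
  spread <- if (length(below) > 1L)
    sqrt(sum((below - p_med)^2) / (length(below) - 1L)) else 0
  out <- v - (p_med + spread)
  out[out < 0] <- 0
  image_stack(out, img$channel, img$z_allowed)
}

#' Detect candidate fluorescent foci
#'
#' Finds all strict local maxima within a 1-voxel radius (the 26-voxel
#' neighbourhood; border voxels compare against available neighbours) of a
#' background-subtracted FISH stack. Each candidate records its raw peak
#' intensity and the mean of the 27 voxels surrounding and including it
#' (truncated at stack borders), the quantity later converted to RNA counts.
#'
#' @param img a background-subtracted [image_stack()].
#' @return A data frame of class \code{"foci"} with columns \code{z, y, x},
#'   \code{raw_intensity}, \code{neighborhood_mean}.
#' @export
detect_foci <- function(img) {
  stopifnot(inherits(img, "image_stack"))
  v <- img$voxels
  hits <- .local_maxima_cpp(as.double(v), dim(v))
  nm <- numeric(nrow(hits))
  d <- dim(v)
  if (nrow(hits)) for (i in seq_len(nrow(hits))) {
    z <- hits[i, 1L]; y <- hits[i, 2L]; x <- hits[i, 3L]
    zz <- max(1L, z - 1L):min(d[1L], z + 1L)
    yy <- max(1L, y - 1L):min(d[2L], y + 1L)
    xx <- max(1L, x - 1L):min(d[3L], x + 1L)
    nm[i] <- mean(v[zz, yy, xx])
  }
  out <- data.frame(z = hits[, 1L], y = hits[, 2L], x = hits[, 3L],
                    raw_intensity = v[hits], neighborhood_mean = nm)
  class(out) <- c("foci", "data.frame")
  out
}

#' Knockout-calibrated focus intensity cutoff
#'
#' Separates genuine hybridisation foci from random clustering of probe
#' molecules by comparing focus-intensity histograms between each strain and
#' a knockout strain carrying no target sequence. Histograms share a common
#' binning from zero at \code{bin_width} and are normalised by probability.
#' For each strain the tentative cutoff is the left edge of the first bin
#' with nonzero strain density at least 10 times the knockout density; the
#' final cutoff is the mean of the tentative cutoffs. If the knockout is
#' empty in a bin, any occupied strain bin passes the rule there.
#'
#' @param strain_intensities named list of numeric vectors of focus
#'   intensities, one per strain.
#' @param knockout_intensities numeric vector of knockout focus intensities.
#' @param bin_width histogram bin width (250 for the GAL1 profile, 50 for the
#'   endogenous profile).
#' @param ratio required strain/knockout density ratio (default 10).
#' @return The cutoff intensity, with the per-strain tentative cutoffs as
#'   attribute \code{"tentative"}.
#' @export
determine_cutoff <- function(strain_intensities, knockout_intensities,
                             bin_width, ratio = 10) {
  if (!is.list(strain_intensities) || !length(strain_intensities))
    stop("'strain_intensities' must be a non-empty list")
  stopifnot_scalar(bin_width, "bin_width")
  if (bin_width <= 0) stop("'bin_width' must be positive")
  top <- max(c(unlist(strain_intensities), knockout_intensities, bin_width))
  breaks <- seq(0, top + bin_width, by = bin_width)
  dens <- function(x) {
    if (!length(x)) return(numeric(length(breaks) - 1L))
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    h$counts / length(x)
  }
  ko <- dens(knockout_intensities)
  tentative <- vapply(strain_intensities, function(s) {
    d <- dens(s)
    ok <- which(d > 0 & d >= ratio * ko)
    if (!length(ok)) NA_real_ else breaks[ok[1L]]
  }, double(1L))
  if (anyNA(tentative)) {
    bad <- names(tentative)[is.na(tentative)]
    if (all(is.na(tentative)))
      stop("no strain satisfies the cutoff rule against the knockout")
    warning("no cutoff bin found for strain(s): ",
            paste(bad, collapse = ", "), "; excluded from the mean")
  }
  structure(mean(tentative, na.rm = TRUE), tentative = tentative)
}
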