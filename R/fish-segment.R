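# --- small image utilities ---------------------------------------------------

# separable Gaussian filter for 3D arrays with replicate padding,
# kernel radius ceil(2*sigma) (truncated, renormalised)
gaussian_filter_3d <- function(v, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  r <- ceiling(2 * sigma)
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(v, perm)
    d <- dim(a)
    m <- matrix(a, d[1L], d[2L] * d[3L])
    m <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(d[1L], r), , drop = FALSE])
    f <- stats::filter(m, kern, sides = 2)
    m <- f[(r + 1L):(r + d[1L]), , drop = FALSE]
    a <- array(m, d)
    v <- aperm(a, order(perm))
  }
  v
}

min_max_scale <- function(v) {
  rng <- range(v)
  if (rng[2L] <= rng[1L]) return(array(0, dim(v)))
  (v - rng[1L]) / (rng[2L] - rng[1L])
}

#' Multi-level Otsu thresholds
#'
#' Chooses \code{n} thresholds maximising the between-class variance of the
#' intensity histogram (256 bins), by dynamic programming over bin
#' boundaries; ties resolve to the lowest threshold set. With \code{n = 1}
#' this reduces to classic Otsu thresholding.
#'
#' @param x numeric vector (or array) of intensities.
#' @param n number of thresholds (classes = n + 1).
#' @param nbins histogram resolution.
#' @return Numeric vector of \code{n} threshold values.
#' @export
multi_otsu <- function(x, n, nbins = 256L) {
  x <- as.vector(x)
  rng <- range(x)
  if (rng[2L] <= rng[1L]) stop("cannot threshold a constant image")
  h <- graphics::hist(x, breaks = seq(rng[1L], rng[2L], length.out = nbins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  P <- cumsum(p)
  M <- cumsum(p * mids)
  # class score for bins i..j: (M_j - M_{i-1})^2 / (P_j - P_{i-1})
  sc <- function(i, j) {
    dp <- P[j] - ifelse(i > 1L, P[i - 1L], 0)
    dm <- M[j] - ifelse(i > 1L, M[i - 1L], 0)
    ifelse(dp > 0, dm * dm / dp, 0)
  }
  ncl <- n + 1L
  nb <- nbins
  D <- matrix(-Inf, ncl, nb)
  arg <- matrix(0L, ncl, nb)
  D[1L, ] <- sc(1L, seq_len(nb))
  for (c in 2L:ncl) {
    for (j in c:nb) {
      i <- c:j  # class c occupies bins i..j
      vals <- D[c - 1L, i - 1L] + sc(i, j)
      best <- which.max(vals)
      D[c, j] <- vals[best]
      arg[c, j] <- i[best]
    }
  }
  cuts <- integer(n)
  j <- nb
  for (c in ncl:2L) {
    i <- arg[c, j]
    cuts[c - 1L] <- i - 1L  # class boundary between bins i-1 and i
    j <- i - 1L
  }
  h$breaks[cuts + 1L]
}

# quantise intensities into levels 1..(length(th)+1)
quantize_levels <- function(v, th) {
  array(findInterval(as.vector(v), th) + 1L, dim(v))
}

# restrict a stack to an allowed z window by zeroing other planes
restrict_z <- function(v, z_allowed) {
  out <- v
  keep <- seq(z_allowed[1L], z_allowed[2L])
  out[setdiff(seq_len(dim(v)[1L]), keep), , ] <- 0
  out
}

# fill holes slice-wise, then drop 26-connected components outside [comp_min, comp_max]
clean_level_mask <- function(mask, comp_min, comp_max) {
  d <- dim(mask)
  filled <- .fill_holes_slices_cpp(as.logical(mask), d)
  lab <- .label3d_cpp(filled, d)
  if (!max(lab)) return(list(mask = array(FALSE, d), labels = lab))
  sz <- tabulate(lab[lab > 0], max(lab))
  bad <- which(sz < comp_min | sz > comp_max)
  if (length(bad)) lab[lab %in% bad] <- 0L
  lab <- .label3d_cpp(lab > 0, d)
  list(mask = array(lab > 0, d), labels = lab)
}

component_centroids <- function(labels) {
  n <- max(labels)
  if (!n) return(matrix(numeric(0), 0L, 3L))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  t(vapply(seq_len(n), function(l) {
    round(colMeans(idx[lab == l, , drop = FALSE]))
  }, double(3L)))
}

# iteratively merge centroids closer than merge_dist, closest pairs first,
# each centroid used at most once per round; merged coordinates are averaged
# and rounded
merge_centroids <- function(cent, merge_dist = 6) {
  repeat {
    n <- nrow(cent)
    if (n < 2L) return(cent)
    dm <- as.matrix(stats::dist(cent))
    pairs <- which(upper.tri(dm) & dm <= merge_dist, arr.ind = TRUE)
    if (!nrow(pairs)) return(cent)
    dists <- dm[pairs]
    ord <- order(dists)
    pairs <- pairs[ord, , drop = FALSE]
    used <- logical(n)
    keep <- logical(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      if (!used[i] && !used[j]) {
        used[i] <- used[j] <- TRUE
        keep[p] <- TRUE
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
    merged <- t(apply(pairs, 1L, function(pr) {
      round(colMeans(cent[pr, , drop = FALSE]))
    }))
    cent <- rbind(cent[!used, , drop = FALSE], merged)
  }
}

# --- nuclei detection --------------------------------------------------------

#' Detect nuclei in 3D from the DAPI channel
#'
#' Multi-level segmentation of the (min-max scaled, Gaussian-filtered,
#' z-restricted) DAPI stack, designed to resolve nuclei that differ in
#' brightness or sit close together. The image is quantised around
#' multi-level Otsu thresholds; segmentation levels are cycled from
#' \code{first_level} to the top, and size-filtered connected components not
#' overlapping the (identically cleaned) level above become centroid
#' candidates - a component overlapping a brighter level defers to the
#' superior candidate(s) there. Nearby centroids (Euclidean distance at most
#' 6) are merged, closest pairs first. Each surviving centroid then grows a
#' 3D nucleus mask from the voxels at or above 0.65 times the mean intensity
#' of its local neighbourhood (27 or 125 voxels by profile), keeping the
#' connected component containing the centroid. Dim centroids (local mean
#' below 0.025 of the scaled intensity range) and small masks are rejected.
#'
#' @param dapi an [image_stack()] with the DAPI channel.
#' @param profile a [fish_profile()] list (or profile name).
#' @return A list of class \code{"nuclei_set"}: \code{labels} (3D integer
#'   array; 0 = background), \code{centroids}, \code{volumes}, and the
#'   filtered stack used for growing.
#' @export
detect_nuclei <- function(dapi, profile = fish_profile("gal1")) {
  stopifnot(inherits(dapi, "image_stack"))
  if (is.character(profile)) profile <- fish_profile(profile)
  if (profile$sigma <= 0) stop("profile sigma must be positive")
  v <- min_max_scale(dapi$voxels)
  v <- gaussian_filter_3d(v, profile$sigma)
  v <- restrict_z(v, dapi$z_allowed)
  d <- dim(v)

  th <- multi_otsu(v, profile$n_thresholds)
  lev <- quantize_levels(v, th)
  n_levels <- profile$n_thresholds + 1L

  cleaned <- vector("list", n_levels)
  for (L in profile$first_level:n_levels)
    cleaned[[L]] <- clean_level_mask(lev == L, profile$comp_min, profile$comp_max)

  cents <- NULL
  for (L in profile$first_level:n_levels) {
    labs <- cleaned[[L]]$labels
    if (!max(labs)) next
    if (L < n_levels) {
      above <- cleaned[[L + 1L]]$mask
      keep_comp <- vapply(seq_len(max(labs)), function(l) {
        !any(above[labs == l])
      }, logical(1L))
      if (!any(keep_comp)) next
      labs[!(labs %in% which(keep_comp))] <- 0L
    }
    cc <- component_centroids(labs)
    if (nrow(cc)) cents <- rbind(cents, cc)
  }
  if (is.null(cents) || !nrow(cents)) {
    return(structure(list(labels = array(0L, d),
                          centroids = matrix(numeric(0), 0L, 3L),
                          volumes = integer(0), filtered = v),
                     class = "nuclei_set"))
  }
  cents <- merge_centroids(cents, profile$merge_dist)

  labels <- array(0L, d)
  volumes <- integer(0)
  kept <- NULL
  r <- profile$nbhd_radius
  nucleus_id <- 0L
  for (i in seq_len(nrow(cents))) {
    z <- cents[i, 1L]; y <- cents[i, 2L]; x <- cents[i, 3L]
    if (z < 1 || z > d[1L] || y < 1 || y > d[2L] || x < 1 || x > d[3L]) next
    zz <- max(1L, z - r):min(d[1L], z + r)
    yy <- max(1L, y - r):min(d[2L], y + r)
    xx <- max(1L, x - r):min(d[3L], x + r)
    m <- mean(v[zz, yy, xx])
    if (m < profile$mean_floor) next
    grow <- v >= profile$grow_frac * m
    lab <- .label3d_cpp(as.logical(grow), d)
    comp <- lab[z, y, x]
    if (!comp) next
    mask <- lab == comp
    vol <- sum(mask)
    if (vol < profile$vol_floor) next
    nucleus_id <- nucleus_id + 1L
    labels[mask & labels == 0L] <- nucleus_id
    volumes <- c(volumes, vol)
    kept <- rbind(kept, cents[i, ])
  }
  structure(list(labels = labels,
                 centroids = if (is.null(kept)) matrix(numeric(0), 0L, 3L) else kept,
                 volumes = volumes, filtered = v),
            class = "nuclei_set")
}

#' @export
print.nuclei_set <- function(x, ...) {
  cat(sprintf("nuclei_set: %d nuclei, volumes %s\n",
              length(x$volumes),
              if (length(x$volumes)) paste(range(x$volumes), collapse = "-")
              else "-"))
  invisible(x)
}

# --- cell segmentation -------------------------------------------------------

#' Segment cells around nuclear seeds
#'
#' Assigns every foreground pixel of \code{support_2d} to a nuclear seed by
#' intensity-weighted geodesic propagation: stepping between neighbouring
#' pixels costs \code{sqrt(dI^2 + reg * step^2)}, so with a small
#' regularisation factor boundaries follow intensity structure, and in
#' uniform regions fall on the equidistant midline between seeds. After
#' propagation, cells touching the image border are removed, as are cells
#' without a nucleus, nuclei without a cell, and (with their nuclei) cells
#' containing two or more nuclei.
#'
#' @param nuclei_2d integer matrix of labelled nuclear seeds (0 = background).
#' @param intensity_2d numeric matrix guiding the propagation (combined
#'   flattened DAPI + FISH image).
#' @param support_2d logical matrix of candidate cell area.
#' @param reg regularisation factor (default 1e-4).
#' @param drop_nucleus_labels nucleus labels to discard after propagation but
#'   before the consistency filters (used for oversized nuclei, which help
#'   cell boundary placement but are unreliable themselves).
#' @return A list with matrices \code{cells_2d} and \code{nuclei_2d} after
#'   filtering (cell label c corresponds to nucleus label c).
#' @export
segment_cells <- function(nuclei_2d, intensity_2d, support_2d, reg = 1e-4,
                          drop_nucleus_labels = integer(0)) {
  if (!any(nuclei_2d > 0)) {
    z <- matrix(0L, nrow(nuclei_2d), ncol(nuclei_2d))
    return(list(cells_2d = z, nuclei_2d = z))
  }
  support <- support_2d | nuclei_2d > 0  # seeds always belong to their cell
  cells <- .propagate_cpp(intensity_2d, nuclei_2d, support, reg)

  # border clearing
  border_labels <- unique(c(cells[1L, ], cells[nrow(cells), ],
                            cells[, 1L], cells[, ncol(cells)]))
  border_labels <- setdiff(border_labels, 0L)
  cells[cells %in% border_labels] <- 0L

  nuc <- nuclei_2d
  if (length(drop_nucleus_labels)) nuc[nuc %in% drop_nucleus_labels] <- 0L

  # consistency filters
  cell_ids <- setdiff(unique(as.vector(cells)), 0L)
  nuc_ids <- setdiff(unique(as.vector(nuc)), 0L)
  keep_cell <- logical(0)
  for (cid in cell_ids) {
    inside <- unique(nuc[cells == cid])
    inside <- setdiff(inside, 0L)
    if (length(inside) == 1L) keep_cell <- c(keep_cell, cid)
  }
  cells[!(cells %in% keep_cell)] <- 0L
  # nuclei must lie in a kept cell
  for (nid in nuc_ids) {
    host <- unique(cells[nuc == nid])
    host <- setdiff(host, 0L)
    if (!length(host)) nuc[nuc == nid] <- 0L
  }
  list(cells_2d = cells, nuclei_2d = nuc)
}

# flatten 3D nucleus labels over the allowed z window and relabel 8-connected
flatten_nuclei <- function(labels3d, z_allowed) {
  keep <- seq(z_allowed[1L], z_allowed[2L])
  flat <- apply(labels3d[keep, , , drop = FALSE] > 0, c(2, 3), any)
  d2 <- dim(flat)
  lab <- .label3d_cpp(as.logical(array(flat, c(1L, d2))), c(1L, d2))
  matrix(lab, d2[1L], d2[2L])
}

#' Full segmentation of a two-channel stack
#'
#' Orchestrates nuclei detection and cell segmentation: detects 3D nuclei
#' from DAPI ([detect_nuclei()]), removes nuclei touching the stack border,
#' flattens them over the allowed z window into 2D seeds (relabelled by
#' 8-connectivity, since disjoint 3D nuclei can overlap when flattened),
#' builds the propagation intensity image (z-summed, min-max scaled DAPI and
#' FISH channels averaged and smoothed) and the support mask (per-channel
#' smoothed flattened images thresholded at the lowest of three Otsu levels,
#' combined by OR), segments cells ([segment_cells()]) - dropping oversized
#' 3D nuclei after propagation - and derives the cytoplasmic compartment
#' (cell minus nucleus, extruded over the allowed z window).
#'
#' @param dapi,fish background-subtracted [image_stack()] objects.
#' @param profile a [fish_profile()] list or name.
#' @param reg propagation regularisation factor.
#' @return An object of class \code{"segmentation_result"}: \code{nuclei_3d},
#'   \code{nuclei_2d}, \code{cells_2d}, \code{z_allowed}.
#' @export
segment_stack <- function(dapi, fish, profile = fish_profile("gal1"),
                          reg = 1e-4) {
  stopifnot(inherits(dapi, "image_stack"), inherits(fish, "image_stack"))
  if (is.character(profile)) profile <- fish_profile(profile)
  nuc <- detect_nuclei(dapi, profile)
  d <- dim(dapi$voxels)

  # clear 3D nuclei touching the stack border
  lab3 <- nuc$labels
  border <- unique(c(lab3[1L, , ], lab3[d[1L], , ],
                     lab3[, 1L, ], lab3[, d[2L], ],
                     lab3[, , 1L], lab3[, , d[3L]]))
  border <- setdiff(border, 0L)
  if (length(border)) lab3[lab3 %in% border] <- 0L

  nuclei_2d <- flatten_nuclei(lab3, dapi$z_allowed)

  flat_norm <- function(v) {
    f <- apply(v, c(2, 3), sum)
    rng <- range(f)
    if (rng[2L] <= rng[1L]) matrix(0, d[2L], d[3L])
    else (f - rng[1L]) / (rng[2L] - rng[1L])
  }
  fd <- flat_norm(dapi$voxels)
  ff <- flat_norm(fish$voxels)
  intensity_2d <- gaussian_filter_2d((fd + ff) / 2, 2)

  sup <- function(flat, sigma) {
    g <- gaussian_filter_2d(flat, sigma)
    th <- tryCatch(multi_otsu(g, 3L)[1L], error = function(e) Inf)
    g >= th
  }
  support_2d <- sup(fd, 5) | sup(ff, 2)

  # oversized flattened nuclei (likely merged multiples) seed cells but are
  # then dropped, so their cells fall to the no-nucleus filter
  drop2d <- oversized_nuclei_2d(lab3, nuclei_2d, dapi$z_allowed,
                                profile$vol_ceiling)

  seg <- segment_cells(nuclei_2d, intensity_2d, support_2d, reg,
                       drop_nucleus_labels = drop2d)
  structure(list(nuclei_3d = lab3,
                 nuclei_2d = seg$nuclei_2d,
                 cells_2d = seg$cells_2d,
                 z_allowed = dapi$z_allowed),
            class = "segmentation_result")
}

# 2D nucleus labels whose underlying 3D voxel count exceeds the ceiling
oversized_nuclei_2d <- function(lab3, nuclei_2d, z_allowed, vol_ceiling) {
  out <- integer(0)
  zz <- seq(z_allowed[1L], z_allowed[2L])
  sub <- lab3[zz, , , drop = FALSE]
  flat <- matrix(sub, length(zz), prod(dim(sub)[2:3]))
  for (nid in setdiff(unique(as.vector(nuclei_2d)), 0L)) {
    vox <- sum(flat[, as.vector(nuclei_2d == nid)] > 0)
    if (vox > vol_ceiling) out <- c(out, nid)
  }
  out
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d cells, z window %d-%d\n",
              length(setdiff(unique(as.vector(x$cells_2d)), 0L)),
              x$z_allowed[1L], x$z_allowed[2L]))
  invisible(x)
}

# 2D Gaussian filter via the 3D machinery
gaussian_filter_2d <- function(m, sigma) {
  a <- gaussian_filter_3d(array(m, c(1L, dim(m))), sigma)
  matrix(a, dim(m)[1L], dim(m)[2L])
}
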