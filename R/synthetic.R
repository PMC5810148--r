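# Synthetic-data generators with planted ground truth. Every generator is
# seed-deterministic and records its full argument set in a manifest from
# which the fixture can be regenerated identically.

new_manifest <- function(generator, seed, args, truth = NULL) {
  structure(list(generator = generator, seed = seed, args = args,
                 truth = truth),
            class = "fixture_manifest")
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf("fixture_manifest: %s (seed %s)\n", x$generator,
              format(x$seed)))
  invisible(x)
}

#' Regenerate a fixture from its manifest
#'
#' @param manifest a \code{fixture_manifest}.
#' @return The regenerated fixture, identical to the original.
#' @export
regenerate_fixture <- function(manifest) {
  stopifnot(inherits(manifest, "fixture_manifest"))
  fn <- switch(manifest$generator,
               fish_counts = gen_fish_counts,
               decay = gen_decay,
               image_stack = gen_image_stack,
               genome = gen_genome_fixture,
               stop("unknown generator: ", manifest$generator))
  do.call(fn, c(manifest$args, list(seed = manifest$seed)))
}

#' Generate per-cell transcript counts with known generating rates
#'
#' Delegates to [simulate_population()] under the default study conditions
#' (10,000 cells simulated for 500 minutes) and records the generating
#' parameters in the manifest.
#'
#' @param params a [model_params()] object (the planted truth).
#' @param n_cells cells to simulate.
#' @param t_end minutes.
#' @param seed integer seed.
#' @return List with \code{counts} (a [count_distribution()]) and
#'   \code{manifest}.
#' @export
gen_fish_counts <- function(params, n_cells = 10000L, t_end = 500, seed = 1L) {
  counts <- simulate_population(params, n_cells, t_end, seed)
  list(counts = counts,
       manifest = new_manifest("fish_counts", seed,
                               list(params = params, n_cells = n_cells,
                                    t_end = t_end),
                               truth = unclass(params)))
}

#' Generate shutdown decay time courses
#'
#' Exponential decay \code{exp(-delta * t)} at the standard shutdown
#' timepoints with additive Gaussian measurement noise (clipped positive and
#' renormalised to the first timepoint, as blot quantification normalises to
#' the pre-shift sample). The defaults mirror the shutdown experiment design:
#' six timepoints over an hour, nine biological replicates, and measurement
#' noise of a few percent of the initial level.
#'
#' @param delta generating degradation rate (1/min), > 0.
#' @param times timepoints in minutes (first must be 0).
#' @param noise_sd Gaussian noise standard deviation (abundance units).
#' @param n_reps replicate time courses.
#' @param seed integer seed.
#' @return List with \code{timecourses} (list of [decay_timecourse()]),
#'   \code{mean_timecourse} (replicate average, renormalised) and
#'   \code{manifest}.
#' @export
gen_decay <- function(delta, times = c(0, 5, 10, 20, 30, 60),
                      noise_sd = 0.02, n_reps = 9L, seed = 1L) {
  if (delta <= 0) stop("'delta' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  base <- exp(-delta * times)
  tcs <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      ab <- base + stats::rnorm(length(times), sd = noise_sd)
      ab <- pmax(ab, 1e-6)
      decay_timecourse(times, ab)
    })
  })
  ab_mat <- vapply(tcs, function(tc) tc$abundance, double(length(times)))
  mean_tc <- decay_timecourse(times, rowMeans(ab_mat))
  list(timecourses = tcs,
       mean_timecourse = mean_tc,
       manifest = new_manifest("decay", seed,
                               list(delta = delta, times = times,
                                    noise_sd = noise_sd, n_reps = n_reps),
                               truth = list(delta = delta,
                                            half_life = log(2) / delta)))
}

# soft ellipsoid intensity at integer voxel offsets
.ellipsoid_blob <- function(dims, center, semi, amplitude) {
  out <- array(0, dims)
  zr <- max(1L, floor(center[1L] - 2 * semi[1L])):min(dims[1L], ceiling(center[1L] + 2 * semi[1L]))
  yr <- max(1L, floor(center[2L] - 2 * semi[2L])):min(dims[2L], ceiling(center[2L] + 2 * semi[2L]))
  xr <- max(1L, floor(center[3L] - 2 * semi[3L])):min(dims[3L], ceiling(center[3L] + 2 * semi[3L]))
  for (z in zr) for (y in yr) for (x in xr) {
    rho2 <- ((z - center[1L]) / semi[1L])^2 + ((y - center[2L]) / semi[2L])^2 +
      ((x - center[3L]) / semi[3L])^2
    out[z, y, x] <- amplitude * exp(-rho2)
  }
  out
}

#' Generate a two-channel image stack with planted ground truth
#'
#' Builds a DAPI stack of well-separated ellipsoidal nuclei on a dark
#' background and a FISH stack with a constant camera background, a dim
#' cytoplasmic autofluorescence disc per cell, and one 3D Gaussian spot per
#' planted RNA molecule at integer voxel positions (amplitude
#' \code{single_rna_intensity}). Per-cell RNA numbers are uniform over
#' \code{rna_range} and split between nucleus and cytoplasm by
#' \code{nuclear_frac}. Optional Poisson shot noise and additive Gaussian
#' noise emulate acquisition; with both disabled the whole quantification
#' pipeline recovers the planted counts exactly. The knockout variant plants
#' zero RNAs (noise and autofluorescence only) for cutoff calibration.
#'
#' @param n_cells number of cells (placed on a jittered grid; an error is
#'   raised if they cannot be placed without overlap).
#' @param rna_range inclusive range of RNAs per cell.
#' @param single_rna_intensity peak amplitude of a single-RNA spot (a.u.).
#' @param background_level constant camera background (a.u.).
#' @param noise_sd additive Gaussian noise sd (0 disables).
#' @param shot_noise logical: apply Poisson shot noise.
#' @param shape stack dimensions \code{c(nz, ny, nx)}.
#' @param z_allowed allowed z window.
#' @param nuclear_frac expected fraction of RNAs in the nucleus.
#' @param knockout logical: plant no RNAs.
#' @param seed integer seed.
#' @return List with \code{dapi} and \code{fish} ([image_stack()]s),
#'   \code{truth} (cell table, spot table, nucleus/cell label masks) and
#'   \code{manifest}.
#' @export
gen_image_stack <- function(n_cells = 6L, rna_range = c(1L, 8L),
                            single_rna_intensity = 500,
                            background_level = 200,
                            noise_sd = 0, shot_noise = FALSE,
                            shape = c(15L, 120L, 120L),
                            z_allowed = c(4L, 12L),
                            nuclear_frac = 0.35,
                            knockout = FALSE,
                            seed = 1L) {
  dims <- as.integer(shape)
  grid_n <- ceiling(sqrt(n_cells))
  cell_px <- 36L
  margin <- 6L
  if (grid_n * cell_px + 2L * margin > min(dims[2L], dims[3L]))
    stop("infeasible packing: enlarge 'shape' or reduce 'n_cells'")
  semi <- c(2.5, 5, 5)
  cell_r <- 15
  af <- 0.05 * single_rna_intensity
  sigma_spot <- 1.1

  with_seed(seed, {
    centers <- NULL
    for (i in seq_len(n_cells)) {
      gy <- (i - 1L) %% grid_n
      gx <- (i - 1L) %/% grid_n
      cy <- margin + gy * cell_px + cell_px / 2 + sample(-2:2, 1L)
      cx <- margin + gx * cell_px + cell_px / 2 + sample(-2:2, 1L)
      cz <- (z_allowed[1L] + z_allowed[2L]) / 2 + sample(-1:1, 1L)
      centers <- rbind(centers, c(cz, cy, cx))
    }

    dapi <- array(0, dims)
    nuc_truth <- array(0L, dims)
    cell_truth <- matrix(0L, dims[2L], dims[3L])
    for (i in seq_len(n_cells)) {
      dapi <- dapi + .ellipsoid_blob(dims, centers[i, ], semi, 1000)
      # ground-truth nucleus: voxels within the ellipsoid
      zr <- max(1L, floor(centers[i, 1L] - semi[1L])):min(dims[1L], ceiling(centers[i, 1L] + semi[1L]))
      yr <- max(1L, floor(centers[i, 2L] - semi[2L])):min(dims[2L], ceiling(centers[i, 2L] + semi[2L]))
      xr <- max(1L, floor(centers[i, 3L] - semi[3L])):min(dims[3L], ceiling(centers[i, 3L] + semi[3L]))
      for (z in zr) for (y in yr) for (x in xr) {
        rho2 <- ((z - centers[i, 1L]) / semi[1L])^2 +
          ((y - centers[i, 2L]) / semi[2L])^2 +
          ((x - centers[i, 3L]) / semi[3L])^2
        if (rho2 <= 1) nuc_truth[z, y, x] <- i
      }
      yy <- matrix(seq_len(dims[2L]), dims[2L], dims[3L])
      xx <- matrix(seq_len(dims[3L]), dims[2L], dims[3L], byrow = TRUE)
      disc <- (yy - centers[i, 2L])^2 + (xx - centers[i, 3L])^2 <= cell_r^2
      cell_truth[disc] <- i
    }

    fish <- array(background_level, dims)
    # cytoplasmic autofluorescence disc across the allowed z window
    for (i in seq_len(n_cells)) {
      disc <- cell_truth == i
      for (z in seq(z_allowed[1L], z_allowed[2L]))
        fish[z, , ][disc] <- fish[z, , ][disc] + af
    }

    spots <- NULL
    cells_df <- data.frame(cell = seq_len(n_cells),
                           z = centers[, 1L], y = centers[, 2L],
                           x = centers[, 3L],
                           nuclear = 0L, cytoplasmic = 0L)
    if (!knockout) {
      occupied <- NULL
      for (i in seq_len(n_cells)) {
        n_rna <- sample(seq(rna_range[1L], rna_range[2L]), 1L)
        n_nuc <- stats::rbinom(1L, n_rna, nuclear_frac)
        comp <- c(rep("nuclear", n_nuc), rep("cytoplasmic", n_rna - n_nuc))
        for (cp in comp) {
          placed <- FALSE
          for (try in 1:200) {
            if (cp == "nuclear") {
              pz <- round(centers[i, 1L] + stats::runif(1L, -semi[1L] + 1, semi[1L] - 1))
              py <- round(centers[i, 2L] + stats::runif(1L, -semi[2L] + 1.5, semi[2L] - 1.5))
              px <- round(centers[i, 3L] + stats::runif(1L, -semi[3L] + 1.5, semi[3L] - 1.5))
              rho2 <- ((pz - centers[i, 1L]) / semi[1L])^2 +
                ((py - centers[i, 2L]) / semi[2L])^2 +
                ((px - centers[i, 3L]) / semi[3L])^2
              # keep nuclear spots well inside the nucleus so the planted
              # compartment is unambiguous for any reasonable segmentation
              ok_comp <- rho2 <= 0.6 && nuc_truth[pz, py, px] == i
            } else {
              ang <- stats::runif(1L, 0, 2 * pi)
              rad <- stats::runif(1L, semi[2L] + 4, cell_r - 2)
              py <- round(centers[i, 2L] + rad * sin(ang))
              px <- round(centers[i, 3L] + rad * cos(ang))
              pz <- sample(seq(z_allowed[1L] + 1L, z_allowed[2L] - 1L), 1L)
              ok_comp <- py >= 1 && py <= dims[2L] && px >= 1 && px <= dims[3L] &&
                cell_truth[py, px] == i && !any(nuc_truth[, py, px] > 0)
            }
            if (!ok_comp) next
            if (!is.null(occupied) &&
                any((occupied[, 1L] - pz)^2 + (occupied[, 2L] - py)^2 +
                    (occupied[, 3L] - px)^2 < 9)) next
            placed <- TRUE
            break
          }
          if (!placed) stop("could not place a spot; geometry infeasible")
          occupied <- rbind(occupied, c(pz, py, px))
          spots <- rbind(spots,
                         data.frame(z = pz, y = py, x = px, cell = i,
                                    compartment = cp))
          if (cp == "nuclear") cells_df$nuclear[i] <- cells_df$nuclear[i] + 1L
          else cells_df$cytoplasmic[i] <- cells_df$cytoplasmic[i] + 1L
        }
      }
      if (!is.null(spots)) {
        r <- 4L
        for (s in seq_len(nrow(spots))) {
          zr <- max(1L, spots$z[s] - r):min(dims[1L], spots$z[s] + r)
          yr <- max(1L, spots$y[s] - r):min(dims[2L], spots$y[s] + r)
          xr <- max(1L, spots$x[s] - r):min(dims[3L], spots$x[s] + r)
          for (z in zr) for (y in yr) for (x in xr) {
            d2 <- (z - spots$z[s])^2 + (y - spots$y[s])^2 + (x - spots$x[s])^2
            fish[z, y, x] <- fish[z, y, x] +
              single_rna_intensity * exp(-d2 / (2 * sigma_spot^2))
          }
        }
      }
    }

    if (shot_noise) fish <- array(stats::rpois(length(fish), fish), dims)
    if (noise_sd > 0) {
      fish <- fish + stats::rnorm(length(fish), sd = noise_sd)
      dapi <- dapi + stats::rnorm(length(dapi), sd = noise_sd)
      fish[fish < 0] <- 0
      dapi[dapi < 0] <- 0
    }

    list(dapi = image_stack(dapi, "dapi", z_allowed),
         fish = image_stack(fish, "fish", z_allowed),
         truth = list(cells = cells_df,
                      spots = if (is.null(spots))
                        data.frame(z = integer(0), y = integer(0),
                                   x = integer(0), cell = integer(0),
                                   compartment = character(0)) else spots,
                      nuclei_labels = nuc_truth,
                      cell_labels = cell_truth),
         manifest = new_manifest("image_stack", seed,
                                 list(n_cells = n_cells, rna_range = rna_range,
                                      single_rna_intensity = single_rna_intensity,
                                      background_level = background_level,
                                      noise_sd = noise_sd,
                                      shot_noise = shot_noise,
                                      shape = shape, z_allowed = z_allowed,
                                      nuclear_frac = nuclear_frac,
                                      knockout = knockout)))
  })
}

#' Generate a synthetic genome with planted sense/antisense TSS geometry
#'
#' Lays out non-overlapping genes on one synthetic chromosome, plants a
#' sense tag cluster at each gene's TSS and, for a configurable fraction of
#' genes, an antisense cluster at a planted fractional position between the
#' sTSS and the first exon-intron boundary. Nascent-transcription coverage
#' satisfying the TSS validation rules (at least 3 reads in the 200-bp
#' downstream window) is painted on both strands; per-gene antisense levels
#' follow a two-group (high/low) design, which also drives the synthetic
#' chromatin track and the intragenic Micro-C style contact sums, so that
#' quintile grouping, metagene profiling and compaction scoring all have
#' known expected contrasts. A one-tag decoy cluster inside each gene body
#' checks the minimum-tag filter.
#'
#' @param n_genes number of genes.
#' @param frac_with_astss fraction of genes given an antisense TSS.
#' @param distance_distribution function \code{n -> fractions} (of the
#'   sTSS-to-boundary distance) or a length-2 range for uniform draws.
#' @param signal_rules list with \code{as_high}, \code{as_low} (antisense
#'   nascent levels per bp), \code{chromatin_high}, \code{chromatin_low}
#'   (promoter chromatin levels), \code{compaction_high_as},
#'   \code{compaction_low_as} (contacts per bp).
#' @param gene_length range of gene lengths (bp).
#' @param exon1_length range of first-exon lengths (bp).
#' @param seed integer seed.
#' @return List with \code{genes} ([gene_table()]), \code{clusters},
#'   \code{nascent} / \code{chromatin} ([signal_track()]s), \code{contacts},
#'   \code{truth} (planted asTSS positions, fractions, groups) and
#'   \code{manifest}.
#' @export
gen_genome_fixture <- function(n_genes = 60L, frac_with_astss = 0.8,
                               distance_distribution = c(0.6, 1.2),
                               signal_rules = list(as_high = 1.0, as_low = 0.1,
                                                   chromatin_high = 2.0,
                                                   chromatin_low = 1.0,
                                                   compaction_high_as = 0.5,
                                                   compaction_low_as = 1.0),
                               gene_length = c(1500L, 3000L),
                               exon1_length = c(300L, 600L),
                               seed = 1L) {
  if (n_genes < 1) stop("'n_genes' must be >= 1")
  dist_fun <- if (is.function(distance_distribution)) distance_distribution
  else function(n) stats::runif(n, distance_distribution[1L],
                                distance_distribution[2L])
  gap <- 1500L
  with_seed(seed, {
    lens <- sample(seq(gene_length[1L], gene_length[2L]), n_genes, replace = TRUE)
    ex1 <- sample(seq(exon1_length[1L], exon1_length[2L]), n_genes, replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    has_as <- seq_len(n_genes) %in%
      sample(n_genes, round(frac_with_astss * n_genes))
    high_as <- has_as & (seq_len(n_genes) %in% sample(n_genes, floor(n_genes / 2)))
    fracs <- dist_fun(n_genes)

    starts <- gap + cumsum(c(0L, (lens + gap)[-n_genes]))
    ends <- starts + lens
    chrom_len <- ends[n_genes] + gap

    nascent <- signal_track(chrom_len, stranded = TRUE)
    chromatin <- signal_track(chrom_len, stranded = FALSE)
    clusters <- list()
    astss <- rep(NA_integer_, n_genes)
    stss <- integer(n_genes)
    boundary <- integer(n_genes)

    for (i in seq_len(n_genes)) {
      st <- strands[i]
      if (st == "+") {
        s_tss <- starts[i]
        bnd <- s_tss + ex1[i]
        t_end <- ends[i]
      } else {
        s_tss <- ends[i] - 1L
        bnd <- s_tss - ex1[i]
        t_end <- starts[i]
      }
      stss[i] <- s_tss
      boundary[i] <- bnd

      # sense cluster: 5 bp wide, peak 5 at the planted TSS, flanked by 1s
      clusters[[length(clusters) + 1L]] <-
        list(start = s_tss - 2L, strand = st, counts = c(1, 1, 5, 1, 1),
             gene_id = sprintf("g%03d", i), role = "sense")
      # decoy: single tag mid-gene on the sense strand (must be ignored)
      mid <- (starts[i] + ends[i]) %/% 2L
      clusters[[length(clusters) + 1L]] <-
        list(start = mid, strand = st, counts = c(1),
             gene_id = sprintf("g%03d", i), role = "decoy")

      # sense nascent support downstream of the sTSS
      if (st == "+") nascent <- track_add(nascent, s_tss + 1L, s_tss + 201L, 0.1, "+")
      else nascent <- track_add(nascent, s_tss - 200L, s_tss, 0.1, "-")

      if (has_as[i]) {
        off <- as.integer(round(fracs[i] * ex1[i]))
        off <- max(10L, min(off, lens[i] - 10L))
        a_tss <- if (st == "+") s_tss + off else s_tss - off
        astss[i] <- a_tss
        anti <- if (st == "+") "-" else "+"
        # peak of the antisense cluster sits at a_tss
        clusters[[length(clusters) + 1L]] <-
          list(start = a_tss - 2L, strand = anti, counts = c(1, 1, 4, 1, 1),
               gene_id = sprintf("g%03d", i), role = "antisense")
        lv <- if (high_as[i]) signal_rules$as_high else signal_rules$as_low
        # antisense transcription runs from the asTSS back past the sTSS
        if (st == "+")
          nascent <- track_add(nascent, s_tss - 100L, a_tss + 1L, lv, anti)
        else
          nascent <- track_add(nascent, a_tss, s_tss + 101L, lv, anti)
      }

      clv <- if (has_as[i] && high_as[i]) signal_rules$chromatin_high
             else signal_rules$chromatin_low
      if (st == "+")
        chromatin <- track_add(chromatin, s_tss - 300L,
                               if (has_as[i]) astss[i] + 300L else s_tss + 600L, clv)
      else
        chromatin <- track_add(chromatin,
                               if (has_as[i]) astss[i] - 300L else s_tss - 600L,
                               s_tss + 301L, clv)
    }

    contacts <- ifelse(has_as & high_as,
                       signal_rules$compaction_high_as,
                       signal_rules$compaction_low_as) * lens

    genes <- gene_table(data.frame(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      chrom = "chrS", start = starts, end = ends, strand = strands,
      exon1_end = boundary, tss_left = stss, tss_right = stss,
      transcript_end = ifelse(strands == "+", ends, starts)))

    truth <- data.frame(gene_id = genes$gene_id, stss = stss,
                        boundary = boundary, astss = astss,
                        fraction = ifelse(has_as, fracs, NA_real_),
                        high_as = high_as, has_as = has_as,
                        strand = strands)

    list(genes = genes, clusters = clusters, nascent = nascent,
         chromatin = chromatin, contacts = contacts, truth = truth,
         chrom_len = chrom_len,
         manifest = new_manifest("genome", seed,
                                 list(n_genes = n_genes,
                                      frac_with_astss = frac_with_astss,
                                      distance_distribution = distance_distribution,
                                      signal_rules = signal_rules,
                                      gene_length = gene_length,
                                      exon1_length = exon1_length),
                                 truth = truth))
  })
}
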