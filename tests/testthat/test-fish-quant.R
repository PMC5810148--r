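# smFISH quantification: background subtraction, foci detection, knockout
# cutoff, nuclei detection, cell segmentation and RNA counting.

test_that("background subtraction handles uniform and bimodal images", {
  u <- image_stack(array(7, c(4, 6, 6)))
  expect_true(all(subtract_background(u)$voxels == 0))

  # half 0, half 10, even count: lower-of-two-middle median is 0, spread over
  # the voxels at or below it is 0, so nothing is subtracted
  v <- array(0, c(2, 6, 6))
  v[1, , ] <- 10
  bs <- subtract_background(image_stack(v))
  expect_identical(bs$voxels, v)
})

test_that("background estimate recovers a planted offset", {
  set.seed(5)
  dims <- c(8, 40, 40)
  bg <- 100
  v <- array(stats::rnorm(prod(dims), mean = bg, sd = 5), dims)
  v[v < 0] <- 0
  # plant bright sparse spots
  for (i in 1:10) {
    z <- sample(2:7, 1); y <- sample(5:36, 1); x <- sample(5:36, 1)
    v[z, y, x] <- v[z, y, x] + 500
  }
  peak_before <- max(v)
  bs <- subtract_background(image_stack(v))
  reduction <- peak_before - max(bs$voxels)
  # the subtracted background is the offset plus (one-sided) noise spread
  expect_lt(abs(reduction - bg) / bg, 0.10)
})

test_that("foci detection finds strict local maxima with 1-voxel radius", {
  v <- array(0, c(5, 9, 9))
  v[3, 5, 5] <- 10
  f <- detect_foci(image_stack(v))
  expect_identical(nrow(f), 1L)
  expect_identical(c(f$z, f$y, f$x), c(3L, 5L, 5L))
  expect_equal(f$raw_intensity, 10)
  expect_equal(f$neighborhood_mean, 10 / 27)

  v[3, 5, 8] <- 10  # 3 voxels away: both strict maxima
  expect_identical(nrow(detect_foci(image_stack(v))), 2L)

  expect_identical(nrow(detect_foci(image_stack(array(0, c(3, 4, 4))))), 0L)
  # adjacent equal voxels are not strict maxima
  v2 <- array(0, c(3, 5, 5))
  v2[2, 3, 3] <- v2[2, 3, 4] <- 5
  expect_identical(nrow(detect_foci(image_stack(v2))), 0L)
})

test_that("planted spots are recovered at SNR 10", {
  set.seed(31)
  dims <- c(12, 80, 80)
  amp <- 500
  v <- array(stats::rnorm(prod(dims), 100, amp / 10), dims)
  v[v < 0] <- 0
  pos <- NULL
  while (is.null(pos) || nrow(pos) < 50) {
    cand <- c(sample(3:10, 1), sample(6:75, 1), sample(6:75, 1))
    if (!is.null(pos) &&
        any(colSums((t(pos) - cand)^2) < 36)) next
    pos <- rbind(pos, cand)
  }
  for (i in 1:50) {
    for (dz in -2:2) for (dy in -2:2) for (dx in -2:2) {
      d2 <- dz^2 + dy^2 + dx^2
      v[pos[i, 1] + dz, pos[i, 2] + dy, pos[i, 3] + dx] <-
        v[pos[i, 1] + dz, pos[i, 2] + dy, pos[i, 3] + dx] +
        amp * exp(-d2 / (2 * 1.1^2))
    }
  }
  f <- detect_foci(subtract_background(image_stack(v)))
  f <- f[f$raw_intensity > amp / 2, ]
  hits <- 0
  for (i in 1:50) {
    d2 <- (f$z - pos[i, 1])^2 + (f$y - pos[i, 2])^2 + (f$x - pos[i, 3])^2
    if (any(d2 <= 3)) hits <- hits + 1
  }
  expect_gte(hits, 49)
})

test_that("knockout cutoff follows the 10x first-bin rule", {
  bw <- 50
  # knockout identically empty: first occupied strain bin wins
  cut <- determine_cutoff(list(s = c(120, 130, 380)), numeric(0), bw)
  expect_equal(as.numeric(cut), 100)

  # strain identical to knockout: no bin passes
  expect_error(
    determine_cutoff(list(s = c(10, 60, 110)), c(10, 60, 110), bw),
    "no strain")

  # constructed case: bin 3 ([100,150)) is the first with >= 10x density
  ko <- c(rep(25, 100), rep(75, 100), rep(125, 4), rep(175, 5))
  s <- c(rep(25, 100), rep(75, 100), rep(125, 100), rep(175, 40))
  # normalised densities: bin1 and bin2 comparable, bin3 ratio >= 10
  cut2 <- determine_cutoff(list(a = s), ko, bw)
  expect_equal(as.numeric(cut2), 100)

  # one strain failing the rule is excluded with a warning, mean over the rest
  expect_warning(
    cut3 <- determine_cutoff(list(good = c(rep(25, 10), rep(225, 50)),
                                  bad = c(25, 25, 25)),
                             rep(25, 1000), bw),
    "excluded")
  expect_equal(as.numeric(cut3), 200)
})

test_that("multi-level Otsu matches a brute-force single threshold", {
  set.seed(8)
  x <- c(rnorm(400, 10, 1), rnorm(300, 30, 2))
  t1 <- multi_otsu(x, 1)
  expect_equal(t1, otsu_brute_force(x), tolerance = 1e-8)
  # two thresholds match the exhaustive-search oracle and separate the modes
  y <- c(rnorm(300, 5, 0.5), rnorm(300, 20, 1), rnorm(300, 50, 2))
  t3 <- multi_otsu(y, 2)
  expect_true(all(diff(t3) > 0))
  expect_equal(t3, otsu2_brute_force(y), tolerance = 1e-8)
  expect_true(t3[1] > 5 && t3[1] < 20)
  expect_true(t3[2] > 20 && t3[2] < 50)
})

test_that("centroid merging follows the closest-pairs-first rule", {
  merge_centroids <- senseDynamics:::merge_centroids
  # two points 4 apart merge to the rounded average
  m <- merge_centroids(rbind(c(5, 10, 10), c(5, 14, 10)), 6)
  expect_identical(nrow(m), 1L)
  expect_equal(as.vector(m), c(5, 12, 10))
  # two points 10 apart stay separate
  m2 <- merge_centroids(rbind(c(5, 10, 10), c(5, 20, 10)), 6)
  expect_identical(nrow(m2), 2L)
})

test_that("nuclei detection finds planted ellipsoids", {
  # single bright ellipsoid
  fx1 <- gen_image_stack(n_cells = 1, knockout = TRUE, shape = c(15, 48, 48),
                         seed = 2)
  nuc <- detect_nuclei(fx1$dapi, fish_profile("gal1"))
  expect_identical(length(nuc$volumes), 1L)
  ctr <- fx1$truth$cells
  expect_gt(nuc$labels[round(ctr$z), round(ctr$y), round(ctr$x)], 0)

  # two nuclei with centres 4 voxels apart merge into one
  v <- array(0, c(15, 40, 40))
  blob <- senseDynamics:::.ellipsoid_blob
  v <- v + blob(dim(v), c(8, 18, 20), c(2.5, 5, 5), 1000)
  v <- v + blob(dim(v), c(8, 22, 20), c(2.5, 5, 5), 1000)
  nuc2 <- detect_nuclei(image_stack(v, "dapi", c(4, 12)), fish_profile("gal1"))
  expect_identical(length(nuc2$volumes), 1L)

  # many well-separated nuclei: all found, centroids within 2 voxels
  fx <- gen_image_stack(n_cells = 12, knockout = TRUE,
                        shape = c(15, 160, 160), seed = 9)
  nuc3 <- detect_nuclei(fx$dapi, fish_profile("gal1"))
  expect_identical(length(nuc3$volumes), 12L)
  for (i in seq_len(12)) {
    d <- sqrt(colSums((t(nuc3$centroids) - unlist(fx$truth$cells[i, c("z", "y", "x")]))^2))
    expect_lte(min(d), 2)
  }
})

test_that("cell propagation splits a uniform corridor at the midline", {
  ny <- 9; nx <- 41
  support <- matrix(TRUE, ny, nx)
  intensity <- matrix(1, ny, nx)
  seeds <- matrix(0L, ny, nx)
  seeds[5, 6] <- 1L
  seeds[5, 36] <- 2L
  lab <- senseDynamics:::.propagate_cpp(intensity, seeds, support, 1e-4)
  expect_true(all(lab[, 2:20] == 1))
  expect_true(all(lab[, 22:40] == 2))

  # support confinement: only the component reachable through support is labelled
  support2 <- matrix(FALSE, ny, nx)
  support2[, 1:15] <- TRUE
  support2[, 25:41] <- TRUE
  seeds1 <- matrix(0L, ny, nx)
  seeds1[5, 6] <- 1L
  lab2 <- senseDynamics:::.propagate_cpp(intensity, seeds1, support2, 1e-4)
  expect_true(all(lab2[, 25:41] == 0))  # right block unreachable from the seed
  expect_true(all(lab2[, 1:15] == 1))
})

test_that("segment_cells applies border and nucleus-consistency filters", {
  ny <- 30; nx <- 30
  intensity <- matrix(1, ny, nx)
  support <- matrix(TRUE, ny, nx)   # everything touches the border
  seeds <- matrix(0L, ny, nx)
  seeds[15, 15] <- 1L
  out <- segment_cells(seeds, intensity, support)
  expect_true(all(out$cells_2d == 0))  # the single cell reaches the border

  # confined support away from borders: cell survives
  support3 <- matrix(FALSE, ny, nx)
  support3[5:25, 5:25] <- TRUE
  out3 <- segment_cells(seeds, intensity, support3)
  expect_gt(sum(out3$cells_2d == 1), 0)
  expect_true(all(which(out3$cells_2d == 1) %in% which(support3 | seeds > 0)))

  # a cell containing two nuclei is removed together with its nuclei
  seeds2 <- matrix(0L, ny, nx)
  seeds2[14, 14] <- 1L
  seeds2[16, 16] <- 2L
  out4 <- segment_cells(seeds2, intensity, support3,
                        drop_nucleus_labels = integer(0))
  # both seeds propagate into one connected support; each keeps its own cell
  # area, so both survive the single-nucleus rule
  expect_setequal(setdiff(unique(as.vector(out4$cells_2d)), 0L), c(1L, 2L))
})

test_that("RNA quantification divides by the median intensity and rounds", {
  seg <- structure(list(
    nuclei_2d = matrix(0L, 10, 10),
    cells_2d = matrix(1L, 10, 10),
    z_allowed = c(1L, 5L)), class = "segmentation_result")
  seg$nuclei_2d[5, 5] <- 1L
  foci <- data.frame(z = c(2L, 3L, 4L), y = c(2L, 5L, 8L), x = c(2L, 5L, 8L),
                     raw_intensity = c(50, 60, 80),
                     neighborhood_mean = c(10, 20, 41))
  q <- classify_and_quantify(foci, seg, cutoff = 0)
  expect_identical(q$foci$rna_count, c(1L, 1L, 2L))
  expect_identical(q$foci$compartment, c("cytoplasmic", "nuclear", "cytoplasmic"))
  expect_identical(q$counts$nuclear, 1L)
  expect_identical(q$counts$cytoplasmic, 3L)

  # equal intensities give one RNA each
  foci2 <- data.frame(z = 2L, y = c(2L, 4L, 8L), x = c(2L, 4L, 8L),
                      raw_intensity = 50, neighborhood_mean = 30)
  q2 <- classify_and_quantify(foci2, seg, cutoff = 0)
  expect_true(all(q2$foci$rna_count == 1L))

  # partition is exhaustive and mutually exclusive
  foci3 <- data.frame(z = c(2L, 2L, 7L), y = c(5L, 8L, 3L), x = c(5L, 8L, 3L),
                      raw_intensity = c(50, 10, 50),
                      neighborhood_mean = c(30, 30, 30))
  q3 <- classify_and_quantify(foci3, seg, cutoff = 20)
  expect_identical(q3$foci$compartment, c("nuclear", "discarded", "discarded"))
  expect_true(all(q3$foci$compartment %in%
                  c("nuclear", "cytoplasmic", "discarded")))

  # nothing above the cutoff: empty distribution with a warning
  expect_warning(q4 <- classify_and_quantify(foci2, seg, cutoff = 1e6),
                 "no foci")
  expect_identical(nrow(q4$counts), 0L)
})

test_that("the pipeline recovers planted counts exactly at zero noise", {
  for (sd in c(3, 11)) {
    fx <- gen_image_stack(n_cells = 6, seed = sd)
    q <- quantify_stack(fx$dapi, fx$fish, cutoff = 100)
    rec <- match_cells_to_truth(q, fx$truth$cells)
    expect_false(anyNA(rec))
    expect_identical(rec[, "nuclear"], fx$truth$cells$nuclear)
    expect_identical(rec[, "cytoplasmic"], fx$truth$cells$cytoplasmic)
  }
})

test_that("at SNR 10 with a knockout-calibrated cutoff recovery stays exact", {
  fx <- gen_image_stack(n_cells = 6, noise_sd = 50, shot_noise = TRUE, seed = 5)
  ko <- gen_image_stack(n_cells = 6, noise_sd = 50, shot_noise = TRUE,
                        knockout = TRUE, seed = 6)
  f_s <- detect_foci(subtract_background(fx$fish))
  f_k <- detect_foci(subtract_background(ko$fish))
  cut <- determine_cutoff(list(strain = f_s$raw_intensity),
                          f_k$raw_intensity, bin_width = 50)
  q <- quantify_stack(fx$dapi, fx$fish, cutoff = cut)
  rec <- match_cells_to_truth(q, fx$truth$cells)
  tru <- fx$truth$cells$nuclear + fx$truth$cells$cytoplasmic
  tot <- rec[, 1] + rec[, 2]
  expect_gte(mean(tot == tru, na.rm = TRUE), 0.95)
  expect_lte(abs(sum(tot) - sum(tru)) / sum(tru), 0.05)
})
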