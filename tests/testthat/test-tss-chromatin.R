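# sTSS/asTSS identification, positional statistics, metagene binning,
# quintiles and compaction.

mk_nascent <- function(len = 10000) {
  tr <- signal_track(len, stranded = TRUE)
  tr$plus[] <- 1
  tr$minus[] <- 1
  tr
}

test_that("TSS calling applies the tag and nascent-support rules", {
  nas <- mk_nascent()
  # single tag: ignored
  expect_null(call_tss_from_cluster(
    list(start = 100, strand = "+", counts = c(1)), nas))
  # peak position and density
  r <- call_tss_from_cluster(
    list(start = 100, strand = "+", counts = c(0, 5, 2)), nas)
  expect_identical(r$position, 101)
  expect_identical(r$peak_density, 5)
  # tie resolves to the 5'-most base on the cluster strand
  tp <- call_tss_from_cluster(
    list(start = 200, strand = "+", counts = c(3, 3)), nas)
  expect_identical(tp$position, 200)
  tm <- call_tss_from_cluster(
    list(start = 200, strand = "-", counts = c(3, 3)), nas)
  expect_identical(tm$position, 201)
  # insufficient nascent support vetoes the call
  weak <- signal_track(10000, stranded = TRUE)
  weak$plus[300:302] <- 1  # 2 reads in any 200-bp window after position ~100
  expect_null(call_tss_from_cluster(
    list(start = 500, strand = "+", counts = c(5, 1)), weak))
  # unstranded nascent track is a strand mismatch
  un <- signal_track(1000, stranded = FALSE)
  expect_error(call_tss_from_cluster(
    list(start = 10, strand = "+", counts = c(5)), un), "strand")
})

test_that("gene TSS assignment picks highest density in the right windows", {
  gene <- data.frame(gene_id = "g1", chrom = "chrS", start = 1000, end = 3000,
                     strand = "+", exon1_end = 1400, tss_left = 1000,
                     tss_right = 1000, transcript_end = 3000)
  tss <- data.frame(position = c(900, 1020, 2000, 2500, 3500),
                    strand = c("+", "+", "-", "-", "-"),
                    peak_density = c(5, 9, 4, 7, 50))
  r <- assign_gene_tss(gene, tss)
  expect_identical(r$sTSS, 1020)    # density 9 beats 5
  expect_identical(r$asTSS, 2500)   # 7 beats 4; 3500 outside the gene body
  # no antisense candidates
  r2 <- assign_gene_tss(gene, tss[tss$strand == "+", ])
  expect_identical(r2$sTSS, 1020)
  expect_null(r2$asTSS)
  # no sense TSS in the scan window: signalled, not an error
  far <- data.frame(position = 9000, strand = "+", peak_density = 5)
  expect_identical(assign_gene_tss(gene, far)$status, "no_sTSS")
  # minus-strand gene mirrors the window logic
  gm <- data.frame(gene_id = "g2", chrom = "chrS", start = 1000, end = 3000,
                   strand = "-", exon1_end = 2600, tss_left = 2999,
                   tss_right = 2999, transcript_end = 1000)
  tssm <- data.frame(position = c(3100, 2400, 1500),
                     strand = c("-", "+", "+"),
                     peak_density = c(6, 3, 8))
  rm_ <- assign_gene_tss(gm, tssm)
  expect_identical(rm_$sTSS, 3100)
  expect_identical(rm_$asTSS, 1500)
})

test_that("isoform-based TSS derivation enforces encompass/overlap rules", {
  gene <- data.frame(gene_id = "y1", chrom = "chrS", start = 2000, end = 3500,
                     strand = "+", exon1_end = 2300, tss_left = 2000,
                     tss_right = 2000, transcript_end = 3500)
  iso <- data.frame(start = c(1900, 2100, 2500, 1500),
                    end = c(3600, 3600, 3300, 3900),
                    strand = c("+", "+", "-", "+"),
                    read_support = c(10, 50, 8, 3))
  r <- yeast_tss_from_isoforms(gene, iso)
  # the 2100 isoform has the most support but does not encompass the ORF
  expect_identical(r$sTSS, 1900)
  expect_identical(r$asTSS, 3300 - 1)  # 5' end of the antisense isoform
  # antisense isoform must overlap the ORF
  iso2 <- iso[c(1, 4), ]
  expect_null(yeast_tss_from_isoforms(gene, iso2)$asTSS)
  # no encompassing sense isoform
  iso3 <- data.frame(start = 2100, end = 3000, strand = "+", read_support = 9)
  expect_identical(yeast_tss_from_isoforms(gene, iso3)$status, "no_sTSS")
})

test_that("relative position is the signed fraction along the sense strand", {
  expect_equal(relative_position(100, 100, 400), 0)
  expect_equal(relative_position(100, 400, 400), 1)
  expect_equal(relative_position(100, 250, 400), 0.5)
  expect_equal(relative_position(500, 350, 200, strand = "-"), 0.5)
  expect_error(relative_position(100, 200, 100), "coincides")
  # upstream asTSS yields a negative fraction
  expect_lt(relative_position(100, 50, 400), 0)
})

test_that("randomised null is reproducible, degenerate for 1-bp regions, and flat", {
  g1 <- data.frame(stss = 0, boundary = 1000, strand = "+")
  r1 <- randomized_null(g1, data.frame(start = 500, end = 501), n_iter = 1,
                        seed = 4)
  expect_equal(sum(r1$density > 0), 1L)  # a delta distribution

  genes <- data.frame(stss = rep(0, 50), boundary = rep(1000, 50),
                      strand = "+")
  regions <- data.frame(start = rep(0, 50), end = rep(1000, 50))
  n1 <- randomized_null(genes, regions, n_iter = 1000, seed = 9,
                        breaks = seq(0, 1, 0.1))
  n2 <- randomized_null(genes, regions, n_iter = 1000, seed = 9,
                        breaks = seq(0, 1, 0.1))
  expect_identical(n1, n2)
  counts <- n1$density * 0.1 * 50 * 1000
  expected <- 50 * 1000 / 10
  chi <- sum((counts - expected)^2 / expected)
  expect_gt(stats::pchisq(chi, df = 9, lower.tail = FALSE), 0.01)
})

test_that("metagene profiles bin correctly and conserve mass", {
  tr <- signal_track(5000, stranded = FALSE)
  tr$value[] <- 3
  pairs <- data.frame(stss = 1000, astss = 1900, strand = "+")
  mp <- metagene_profile(tr, pairs, flank = 300, n_bins = 30)
  expect_true(all(abs(mp$upstream - 3) < 1e-12))
  expect_true(all(abs(mp$inter - 3) < 1e-12))
  expect_true(all(abs(mp$downstream - 3) < 1e-12))

  # unit impulse inside the inter-TSS region lands in the expected bin
  tr2 <- signal_track(5000, stranded = FALSE)
  delta_off <- 451
  tr2 <- track_add(tr2, 1000 + delta_off, 1000 + delta_off + 1, 1)
  mp2 <- metagene_profile(tr2, pairs, flank = 300, n_bins = 30)
  expect_equal(which(mp2$inter > 0), floor(30 * delta_off / 900) + 1)

  # mass conservation for one gene: bin means x widths = body sum
  tr3 <- signal_track(5000, stranded = FALSE)
  set.seed(2)
  tr3$value[] <- rpois(5000, 2)
  body_sum <- sum(track_values(tr3, 1000, 1900))
  mp3 <- metagene_profile(tr3, pairs, flank = 300, n_bins = 30)
  widths <- diff(floor(900 * (0:30) / 30))
  expect_equal(sum(mp3$inter * widths), body_sum)

  # strand mirror: a minus-strand gene on the coordinate-reversed track
  L <- 5000
  trR <- signal_track(L, stranded = FALSE)
  trR$value <- rev(tr3$value)
  pairsR <- data.frame(stss = L - 1 - 1000, astss = L - 1 - 1900,
                       strand = "-")
  mpR <- metagene_profile(trR, pairsR, flank = 300, n_bins = 30)
  expect_equal(mpR$upstream, mp3$upstream)
  expect_equal(mpR$inter, mp3$inter)
  expect_equal(mpR$downstream, mp3$downstream)

  # pairs with the asTSS upstream of the sTSS are excluded with a warning
  badp <- data.frame(stss = c(1000, 2000), astss = c(1900, 1500),
                     strand = "+")
  expect_warning(metagene_profile(tr, badp, 300, 30), "excluded")
})

test_that("compaction is contacts per bp and scale invariant", {
  g <- data.frame(start = c(0, 100), end = c(1000, 300))
  expect_equal(gene_compaction(c(0, 100), g), c(0, 0.5))
  expect_equal(gene_compaction(100, data.frame(start = 0, end = 1000)), 0.1)
  expect_equal(gene_compaction(200, data.frame(start = 0, end = 2000)), 0.1)
  expect_error(gene_compaction(5, data.frame(start = 10, end = 10)),
               "zero-length")
})

test_that("quintile grouping sizes and tie handling", {
  q10 <- quintile_groups(1:10)
  expect_identical(q10$size, 2)
  expect_identical(q10$high, c(9L, 10L))
  expect_identical(q10$low, c(1L, 2L))
  expect_error(quintile_groups(1:4), "at least 5")
  expect_warning(qd <- quintile_groups(rep(1, 10)), "degenerate")
  expect_identical(qd$low, 1:2)
  expect_identical(qd$high, 9:10)
})

test_that("planted genome geometry is fully recovered", {
  g <- gen_genome_fixture(n_genes = 40, seed = 2)
  tss <- do.call(rbind, lapply(g$clusters, function(cl) {
    r <- call_tss_from_cluster(cl, g$nascent)
    if (is.null(r)) NULL
    else data.frame(position = r$position, strand = r$strand,
                    peak_density = r$peak_density)
  }))
  # decoy single-tag clusters must all be filtered
  n_real <- sum(vapply(g$clusters, function(cl) cl$role != "decoy", TRUE))
  expect_identical(nrow(tss), n_real)

  rel <- rep(NA_real_, nrow(g$genes))
  for (i in seq_len(nrow(g$genes))) {
    res <- assign_gene_tss(g$genes[i, ], tss)
    tr <- g$truth[i, ]
    expect_identical(res$sTSS, tr$stss)
    if (tr$has_as) {
      expect_identical(res$asTSS, tr$astss)
      rel[i] <- relative_position(res$sTSS, res$asTSS, tr$boundary,
                                  g$genes$strand[i])
    } else {
      expect_null(res$asTSS)
    }
  }
  # median planted fractional distance recovered within one 0.05-wide bin
  planted_med <- median(g$truth$fraction, na.rm = TRUE)
  expect_lt(abs(median(rel, na.rm = TRUE) - planted_med), 0.05)

  # quintile grouping by antisense signal downstream of the sTSS separates
  # the planted high-antisense group from the rest
  lv <- vapply(seq_len(nrow(g$genes)), function(i) {
    gn <- g$genes[i, ]
    anti <- if (gn$strand == "+") "-" else "+"
    w <- if (gn$strand == "+") c(gn$tss_left + 1, gn$tss_left + 301)
         else c(gn$tss_left - 300, gn$tss_left)
    sum(track_values(g$nascent, w[1], w[2], anti))
  }, double(1))
  qq <- quintile_groups(lv, g$genes$gene_id)
  expect_true(all(g$truth$high_as[match(qq$high, g$truth$gene_id)]))
  expect_true(!any(g$truth$high_as[match(qq$low, g$truth$gene_id)]))

  # compaction contrast: planted high-antisense genes are less compact
  comp <- gene_compaction(g$contacts, g$genes)
  expect_lt(max(comp[g$truth$high_as]), min(comp[!g$truth$high_as]))

  # chromatin metagene contrast between high and low antisense genes
  pairs <- data.frame(stss = g$truth$stss, astss = g$truth$astss,
                      strand = g$truth$strand)[g$truth$has_as, ]
  hi <- g$truth$high_as[g$truth$has_as]
  mp_hi <- metagene_profile(g$chromatin, pairs[hi, ], 300, 30)
  mp_lo <- metagene_profile(g$chromatin, pairs[!hi, ], 300, 30)
  expect_gt(mean(mp_hi$inter), mean(mp_lo$inter))
})
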