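test_that("consensus peaks are the intersection cores of all replicates", {
  a <- gr_of("c1", 100, 200)
  b <- gr_of("c1", 150, 250)
  cons <- consensus_peaks(list(a, b))
  expect_equal(GenomicRanges::start(cons) - 1, 150)
  expect_equal(GenomicRanges::end(cons), 200)
  # three replicates sharing a core
  cc <- consensus_peaks(list(gr_of("c1", 100, 200), gr_of("c1", 120, 260),
                             gr_of("c1", 90, 180)))
  expect_equal(c(GenomicRanges::start(cc) - 1, GenomicRanges::end(cc)),
               c(120, 180))
  expect_warning(empty <- consensus_peaks(list(gr_of("c1", 0, 10),
                                               gr_of("c1", 50, 60))),
                 "no consensus")
  expect_equal(length(empty), 0L)
  # containment: consensus is inside every replicate's coverage
  set.seed(2)
  p <- random_peaks(30)
  reps <- lapply(1:3, function(i) {
    sh <- sample(-8:8, nrow(p), replace = TRUE)
    gr_of(p$chrom, pmax(0, p$start + sh), p$end + sh)
  })
  cons3 <- consensus_peaks(reps)
  expect_gt(length(cons3), 0L)
  for (r in reps) {
    hits <- GenomicRanges::findOverlaps(cons3, r, type = "within")
    expect_equal(length(unique(S4Vectors::queryHits(hits))), length(cons3))
  }
})

test_that("zone clustering follows the documented gap rule", {
  # worked example: gaps 50 and 850 -> median 450; first two peaks chain
  pk <- gr_of("c1", c(0, 100, 1000), c(50, 150, 1050))
  z <- cluster_initiation_zones(pk)
  expect_equal(z$gap_bp, 450)
  expect_equal(length(z$zones), 1L)
  expect_equal(GenomicRanges::start(z$zones) - 1, 0)
  expect_equal(GenomicRanges::end(z$zones), 150)
  expect_equal(length(z$retained), 2L)
  expect_equal(z$zones$n_peaks, 2L)

  # all gaps equal g with gap_bp = g: one zone holds every peak
  pk2 <- gr_of("c1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  z2 <- cluster_initiation_zones(pk2, gap_bp = 50)
  expect_equal(length(z2$zones), 1L)
  expect_equal(z2$zones$n_peaks, 4L)
  # min_peaks = 1 retains every peak
  z3 <- cluster_initiation_zones(pk, min_peaks = 1, gap_bp = 10)
  expect_equal(length(z3$retained), 3L)
})

test_that("zone clustering agrees with the transitive-closure oracle", {
  set.seed(14)
  for (case in 1:200) {
    n <- sample(2:50, 1)
    p <- random_peaks(n)
    gap <- sample(c(3, 10, 40, 120, 400), 1)
    got <- cluster_initiation_zones(gr_of(p$chrom, p$start, p$end),
                                    min_peaks = 2, gap_bp = gap)
    oracle <- zones_brute(p$chrom, p$start, p$end, gap, 2)
    expect_equal(length(got$retained), sum(oracle$member))
    if (sum(oracle$member)) {
      kept <- p[oracle$member, ]
      expect_equal(GenomicRanges::start(got$retained) - 1, kept$start)
      # zones = per-component spans
      comp <- oracle$component[oracle$member]
      spans <- do.call(rbind, lapply(unique(comp), function(cp)
        c(min(kept$start[comp == cp]), max(kept$end[comp == cp]))))
      ord <- order(match(kept$chrom[!duplicated(comp)],
                         unique(p$chrom)),
                   spans[, 1])
      expect_equal(GenomicRanges::start(got$zones) - 1, spans[ord, 1])
      expect_equal(GenomicRanges::end(got$zones), spans[ord, 2])
      # every retained peak lies inside exactly one zone
      expect_true(all(GenomicRanges::countOverlaps(
        got$retained, got$zones, type = "within") == 1L))
    }
  }
})

test_that("density quantification is RPM-normalized per condition", {
  pk <- gr_of("c1", c(0, 1000), c(100, 1100))
  tab <- quantify_is(pk, list(a = c(10, 90), b = c(5, 5)),
                     totals = c(a = 1e6, b = 1e6))
  expect_equal(tab$density_a, c(10, 90))
  # doubling library size halves RPM
  tab2 <- quantify_is(pk, list(a = c(10, 90)), totals = c(a = 2e6))
  expect_equal(tab2$density_a, c(5, 45))
  # densities reconstruct the library: sum(density)*total/1e6 = reads
  tab3 <- quantify_is(pk, list(a = c(10, 90)))
  expect_equal(sum(tab3$density_a) * 100 / 1e6, 100)
  expect_error(quantify_is(pk, list(a = c(0, 0))), "library")
})

test_that("1.5-fold classification and quintiles respect the stated rules", {
  d_a <- c(16, 10, 5, 30, 1, 8, 12, 45, 2, 20, 7, 9)
  d_b <- c(10, 10, 10, 10, 10, 10, 10, 30, 30, 20, 7, 6)
  pk <- gr_of("c1", seq(0, by = 1000, length.out = 12),
              seq(100, by = 1000, length.out = 12))
  tab <- quantify_is(pk, list(x = d_a, y = d_b),
                     totals = c(x = 1e6, y = 1e6))
  tab <- classify_fold_change(tab, "x", "y", 1.5, pseudocount = 0)
  expect_equal(sum(attr(tab, "fractions")), 1)
  fc <- d_a / d_b
  expect_equal(tab$change_class,
               ifelse(fc >= 1.5, "up", ifelse(fc <= 1 / 1.5, "down",
                                              "unchanged")))
  # boundary semantics: fc = 1.6 up, 1.0 unchanged, 0.5 down
  expect_equal(tab$change_class[c(1, 2, 5)], c("up", "unchanged", "down"))

  tab <- quintile_classes(tab)
  sizes <- as.numeric(table(tab$quintile))
  expect_equal(sum(sizes), 12)
  expect_lte(diff(range(sizes)), 1)
})

test_that("quintile partition is balanced, ordered and deterministic", {
  mk <- function(n) {
    pk <- gr_of("c1", seq(0, by = 1000, length.out = n),
                seq(100, by = 1000, length.out = n))
    set.seed(n)
    tab <- quantify_is(pk, list(x = runif(n, 1, 50), y = runif(n, 1, 50)),
                       totals = c(x = 1e6, y = 1e6))
    quintile_classes(classify_fold_change(tab, "x", "y"))
  }
  t10 <- mk(10)
  expect_equal(as.numeric(table(t10$quintile)), rep(2, 5))
  t11 <- mk(11)
  expect_equal(as.numeric(table(t11$quintile)), c(3, 2, 2, 2, 2))
  # lowest fold-change always lands in class 1; concatenated classes in
  # rank order reproduce the sorted table
  expect_equal(t11$quintile[which.min(t11$log2_fc)], 1L)
  ord <- order(t11$log2_fc, t11$chrom, t11$start)
  expect_true(!is.unsorted(t11$quintile[ord]))
  expect_error(quintile_classes(mk(10)[1:4, ]), "at least")
})

test_that("per-class RT profiling mirrors the planted strong-origin coupling", {
  cfg <- synth_config(chrom_lengths = c(c1 = 40e6, c2 = 30e6))
  trb <- make_truth(cfg, "baseline", 3)
  tra <- make_truth(cfg, "mcm_depletion", 3)
  isb <- simulate_is_replicates(trb)
  isa <- simulate_is_replicates(tra)
  zb <- cluster_initiation_zones(consensus_peaks(isb))
  za <- cluster_initiation_zones(consensus_peaks(isa))
  merged <- normalize_intervals(GenomicRanges::reduce(
    c(GenomicRanges::granges(zb$retained),
      GenomicRanges::granges(za$retained))))
  cnt <- function(reps) Reduce(`+`, lapply(reps, function(r)
    count_reads_in_peaks(merged, r)))
  tab <- quantify_is(merged, list(ref = cnt(isb), alt = cnt(isa)))
  tab <- quintile_classes(classify_fold_change(tab, "alt", "ref"))
  cts <- simulate_repli_counts(trb, 200)
  rt <- loess_smooth(compute_rt(cts$early, cts$late, 1))
  pr <- class_rt_profile(tab, list(ref = rt))
  med <- pr$medians
  # most-downregulated origins are early-replicating, most-upregulated late
  expect_gt(med$median_rt[med$class == 1], med$median_rt[med$class == 5])
  expect_gt(med$median_rt[med$class == 1], 1)
  expect_lt(med$median_rt[med$class == 5], -1)
})
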