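plaid_oe <- function(n_bins = 300, seed = 4, mean_pair_reads = 3,
                     delta = 0.5, chrom_mb = NULL) {
  cfg <- synth_config(chrom_lengths = c(c1 = n_bins * 20000))
  tr <- make_truth(cfg, "baseline", seed)
  cm <- simulate_contacts(tr, mean_pair_reads, delta, 1)[[1]]
  cm <- balance_matrix(cm)
  list(truth = tr, cm = cm, oe = observed_expected(cm))
}

test_that("Sinkhorn balancing reaches uniform row sums", {
  # 2x2 antidiagonal: balanced matrix is [[0,1],[1,0]]
  gl <- genome_layout("c", 40000, 20000)
  cm <- contact_matrix(gl, "c", matrix(c(0, 4, 4, 0), 2))
  b <- balanced_values(balance_matrix(cm, mask_min_nonzero = 1))
  expect_equal(b, matrix(c(0, 1, 1, 0), 2), tolerance = 1e-7)

  # equal off-diagonal entries -> equal weights
  gl3 <- genome_layout("c", 100000, 20000)
  m <- matrix(3, 5, 5); diag(m) <- 0
  w <- balance_matrix(contact_matrix(gl3, "c", m), 1)$weights
  expect_equal(w, rep(w[1], 5), tolerance = 1e-9)

  # random positive symmetric 50x50: row sums uniform to rtol 1e-8
  set.seed(10)
  gl50 <- genome_layout("c", 50 * 20000, 20000)
  r <- matrix(runif(2500, 0.5, 4), 50); r <- r + t(r)
  cmb <- balance_matrix(contact_matrix(gl50, "c", r))
  rs <- rowSums(balanced_values(cmb))
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-8)
})

test_that("observed/expected has unit diagonal means and scale invariance", {
  p <- plaid_oe(200)
  n <- nrow(p$oe$oe)
  for (d in c(1, 3, 10, 50)) {
    i <- seq_len(n - d)
    m <- mean(p$oe$oe[cbind(i, i + d)], na.rm = TRUE)
    expect_equal(m, 1, tolerance = 1e-12)
  }
  # doubling all counts leaves O/E unchanged
  cm2 <- p$cm; cm2$counts <- 2 * cm2$counts; cm2$weights <- NULL
  oe2 <- observed_expected(balance_matrix(cm2))
  expect_equal(oe2$oe, p$oe$oe, tolerance = 1e-7)
  # planted plaid separates same- from cross-compartment O/E
  idx <- chrom_bins(p$truth$layout, "c1")
  keep <- which(!p$oe$mask)
  same <- outer(p$truth$compartment[idx][keep],
                p$truth$compartment[idx][keep], "==")
  sub <- p$oe$oe[keep, keep]
  d <- abs(outer(seq_along(keep), seq_along(keep), "-"))
  sel <- d > 5
  expect_gt(mean(sub[sel & same], na.rm = TRUE),
            mean(sub[sel & !same], na.rm = TRUE))
})

test_that("PC1 recovers planted compartments and obeys the sign contract", {
  p <- plaid_oe(400, seed = 6)
  ref <- binned_track(p$truth$layout, p$truth$rt, "log2ratio")
  pc1 <- compartment_pc1(p$oe, ref)
  ok <- !is.na(pc1$values)
  agree <- mean(sign(pc1$values[ok]) ==
                  ifelse(p$truth$compartment[ok] == "A", 1, -1))
  expect_gte(agree, 0.95)
  # flipping the reference flips the orientation
  ref_neg <- binned_track(ref$layout, -ref$values, ref$units)
  pc1_neg <- compartment_pc1(p$oe, ref_neg)
  expect_equal(pc1_neg$values, -pc1$values)
  # noise-free expected plaid: sign agreement >= 99%
  idx <- chrom_bins(p$truth$layout, "c1")
  n <- length(idx)
  same <- outer(p$truth$compartment[idx], p$truth$compartment[idx], "==")
  dd <- abs(outer(seq_len(n), seq_len(n), "-")); diag(dd) <- NA
  e <- ifelse(dd >= 1, 1 + 0.5 * same, NA)
  expected_oe <- structure(list(
    oe = e / mean(e, na.rm = TRUE), expected = rep(1, n),
    mask = rep(FALSE, n), chrom = "c1", layout = p$truth$layout),
    class = "OEMatrix")
  pc1_exp <- compartment_pc1(expected_oe, ref)
  agree_exp <- mean(sign(pc1_exp$values) ==
                      ifelse(p$truth$compartment == "A", 1, -1),
                    na.rm = TRUE)
  expect_gte(agree_exp, 0.99)
})

test_that("saddle matches the exhaustive pair-averaging oracle", {
  p <- plaid_oe(100, seed = 8)
  ref <- binned_track(p$truth$layout, p$truth$rt, "log2ratio")
  pc1 <- compartment_pc1(p$oe, ref)
  min_sep <- 400000   # 20 bins on a 100-bin chromosome
  for (ng in c(2, 5)) {
    s <- saddle(p$oe, pc1, n_groups = ng, min_sep_bp = min_sep)
    keep <- which(!p$oe$mask & !is.na(pc1$values))
    groups <- rep(NA_integer_, 100)
    r <- rank(pc1$values[keep], ties.method = "first")
    N <- length(keep)
    groups[keep] <- sapply(r, function(ri)
      min(which(ri <= ceiling(seq_len(ng) * N / ng))))
    oracle <- saddle_brute(p$oe$oe, groups, ng, min_sep / 20000)
    expect_equal(s$matrix, oracle, tolerance = 1e-12)
  }
  # flat O/E gives a flat saddle
  flat <- p$oe; flat$oe[!is.na(flat$oe)] <- 1
  s1 <- saddle(flat, pc1, 5, min_sep)
  expect_true(all(abs(s1$matrix - 1) < 1e-12, na.rm = TRUE))
})

test_that("saddle fold-change propagates ratios and missing cells", {
  m <- matrix(1:4 / 2, 2)
  sa <- structure(list(matrix = 2 * m, counts = matrix(5, 2, 2),
                       n_groups = 2, breaks = NULL, min_sep_bp = 0),
                  class = "SaddleMatrix")
  sb <- sa; sb$matrix <- m
  expect_equal(saddle_fold_change(sa, sb)$matrix, matrix(2, 2, 2))
  expect_true(all(saddle_fold_change(sa, sa)$matrix == 1))
  sz <- sb; sz$matrix[1, 1] <- 0
  expect_true(is.na(saddle_fold_change(sa, sz)$matrix[1, 1]))
})

test_that("PC1/RT joint table partitions bins into quadrants", {
  gl <- tiny_layout(100)
  set.seed(3)
  v <- rnorm(100)
  pc1 <- binned_track(gl, v, "eigen")
  rt <- binned_track(gl, v, "log2ratio")
  j <- pc1_rt_joint(pc1, rt)
  expect_equal(sum(j$quadrant_fractions), 1)
  expect_equal(unname(j$quadrant_fractions[c("A_late", "B_early")]),
               c(0, 0))   # identical tracks live on the diagonal
  rt2 <- binned_track(gl, rnorm(100), "log2ratio")
  j2 <- pc1_rt_joint(pc1, rt2)
  expect_equal(sum(j2$quadrant_fractions), 1)
  expect_equal(nrow(j2$table), 100)
})
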