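#' Balance a contact matrix to uniform row sums
#'
#' Sinkhorn-Knopp iteration toward the doubly-stochastic fixed point also
#' targeted by Knight-Ruiz balancing: per-bin weights `w` such that every
#' unmasked row sum of `w_i * M_ij * w_j` equals 1 within `tol` (relative).
#' Bins with a zero marginal or fewer than `mask_min_nonzero` nonzero
#' entries are masked before balancing and get undefined weights.
#'
#' @param cm A [contact_matrix()].
#' @param mask_min_nonzero Minimum nonzero entries for a bin to be kept.
#' @param tol Relative row-sum uniformity tolerance.
#' @param max_iter Maximum iterations.
#' @return The `ContactMatrix` with `weights` and `mask` filled in.
#' @export
balance_matrix <- function(cm, mask_min_nonzero = 10, tol = 1e-8,
                           max_iter = 1000L) {
  m <- cm$counts
  nz <- rowSums(m > 0)
  mask <- rowSums(m) == 0 | nz < mask_min_nonzero
  keep <- which(!mask)
  if (length(keep) < 2L) stop("fewer than 2 unmasked bins")
  sub <- m[keep, keep, drop = FALSE]
  w <- rep(1, length(keep))
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    r <- as.numeric(sub %*% w) * w
    rel <- r / mean(r)
    if (max(abs(rel - 1)) < tol) { ok <- TRUE; break }
    w <- w / sqrt(rel)
  }
  if (!ok) {
    r <- as.numeric(sub %*% w) * w
    worst <- keep[which.max(abs(r / mean(r) - 1))]
    stop("balancing did not converge in ", max_iter,
         " iterations (worst row: bin ", worst, ")")
  }
  # scale so unmasked row sums equal 1 exactly (up to tol)
  w <- w / sqrt(mean(as.numeric(sub %*% w) * w))
  weights <- rep(NA_real_, nrow(m))
  weights[keep] <- w
  cm$weights <- weights
  cm$mask <- mask
  cm
}

#' Balanced contact values
#' @param cm A balanced `ContactMatrix`.
#' @return Matrix `w_i * M_ij * w_j` with NA on masked rows/columns.
#' @export
balanced_values <- function(cm) {
  if (is.null(cm$weights)) stop("matrix is not balanced")
  outer(cm$weights, cm$weights) * cm$counts
}

#' Expected contact frequency by genomic separation
#'
#' Mean balanced value over all unmasked pairs at each bin separation
#' `d = 0 .. n-1` of one chromosome.
#'
#' @param cm A balanced `ContactMatrix`.
#' @return Numeric vector indexed by `d + 1` (NA where no unmasked pair
#'   exists).
#' @export
expected_by_distance <- function(cm) {
  b <- balanced_values(cm)
  n <- nrow(b)
  exp_d <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    v <- b[cbind(i, i + d)]
    v <- v[!is.na(v)]
    if (length(v)) exp_d[d + 1] <- mean(v)
  }
  exp_d
}

#' Observed/expected contact matrix
#'
#' Balanced values divided by the expected value at their separation; by
#' construction the mean over each diagonal with a defined expectation is 1.
#'
#' @param cm A balanced `ContactMatrix`.
#' @return Object of class `OEMatrix`: `oe` (matrix, NA on masked bins and
#'   empty diagonals), `expected`, `mask`, `chrom`, `layout`.
#' @export
observed_expected <- function(cm) {
  b <- balanced_values(cm)
  n <- nrow(b)
  exp_d <- expected_by_distance(cm)
  dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
  oe <- b / matrix(exp_d[dmat + 1], n, n)
  oe[is.nan(oe)] <- NA
  structure(list(oe = oe, expected = exp_d, mask = cm$mask,
                 chrom = cm$chrom, layout = cm$layout),
            class = "OEMatrix")
}

.roll_mean <- function(v, k) {
  # centered rolling mean over a window of k bins, NA-tolerant
  if (k <= 1L) return(v)
  half <- k %/% 2
  n <- length(v)
  out <- v
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    vv <- v[lo:hi]
    out[i] <- if (all(is.na(vv))) NA_real_ else mean(vv, na.rm = TRUE)
  }
  out
}

#' Compartment eigenvector (PC1) from observed/expected matrices
#'
#' Per chromosome: the Pearson correlation matrix of the O/E columns over
#' unmasked bins is eigendecomposed and the leading eigenvector taken; the
#' values are smoothed by a centered rolling mean over `smooth_bp`, then the
#' sign is oriented so the track correlates positively with `reference`
#' (gene density or RT). Chromosome tracks are concatenated into one
#' genome-wide `BinnedTrack`.
#'
#' @param oe_list Named list of `OEMatrix` (one per chromosome), or a single
#'   `OEMatrix`.
#' @param reference `BinnedTrack` used for sign orientation.
#' @param smooth_bp Smoothing window in bp (default 200000).
#' @return `BinnedTrack` with units `"eigen"`; masked bins are NA.
#' @export
compartment_pc1 <- function(oe_list, reference, smooth_bp = 200000) {
  if (inherits(oe_list, "OEMatrix")) oe_list <- list(oe_list)
  layout <- oe_list[[1]]$layout
  stop_if_layout_mismatch(layout, reference$layout)
  vals <- rep(NA_real_, layout$total_bins)
  for (oe in oe_list) {
    idx <- chrom_bins(layout, oe$chrom)
    keep <- which(!oe$mask)
    sub <- oe$oe[keep, keep, drop = FALSE]
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)
    v <- ev$vectors[, 1]
    full <- rep(NA_real_, length(idx))
    full[keep] <- v
    k <- max(1L, round(smooth_bp / layout$bin_size))
    if (k %% 2 == 0) k <- k + 1L
    full <- .roll_mean(full, k)
    ref <- reference$values[idx]
    co <- !is.na(full) & !is.na(ref)
    if (sum(co) >= 3) {
      r <- suppressWarnings(stats::cor(full[co], ref[co]))
      if (is.na(r) || abs(r) < 0.05)
        warning("PC1 on ", oe$chrom,
                " nearly uncorrelated with reference; sign left as computed")
      else if (r < 0) full <- -full
    }
    vals[idx] <- full
  }
  binned_track(layout, vals, "eigen")
}

.quantile_groups <- function(v, n_groups) {
  # rank-quantile groups, ties broken by position (stable): sizes differ
  # by <= 1; group 1 = lowest values
  N <- length(v)
  r <- rank(v, ties.method = "first")
  findInterval(r, ceiling(seq_len(n_groups) * N / n_groups),
               left.open = TRUE) + 1L
}

#' Saddle matrix of long-range contact enrichment by compartment strength
#'
#' Bins with defined PC1 and unmasked contacts are ranked genome-wide by PC1
#' and split into `n_groups` rank-quantile groups (group 1 = lowest PC1,
#' most B; group `n_groups` = highest, most A). Cell (g, h) is the pooled
#' mean O/E over all intra-chromosomal unmasked pairs at separation greater
#' than `min_sep_bp`, aggregated across chromosomes.
#'
#' @param oe_list Named list of `OEMatrix`, or a single one.
#' @param pc1 Compartment `BinnedTrack` from [compartment_pc1()].
#' @param n_groups Number of PC1 groups (default 50).
#' @param min_sep_bp Minimum pair separation in bp (default 2e6).
#' @return Object of class `SaddleMatrix`: `matrix` (mean O/E), `counts`
#'   (pairs per cell), `n_groups`, `breaks` (PC1 group boundaries),
#'   `min_sep_bp`.
#' @export
saddle <- function(oe_list, pc1, n_groups = 50, min_sep_bp = 2e6) {
  if (inherits(oe_list, "OEMatrix")) oe_list <- list(oe_list)
  layout <- oe_list[[1]]$layout
  stop_if_layout_mismatch(layout, pc1$layout)
  usable <- rep(FALSE, layout$total_bins)
  for (oe in oe_list)
    usable[chrom_bins(layout, oe$chrom)[!oe$mask]] <- TRUE
  usable <- usable & !is.na(pc1$values)
  gbin <- rep(NA_integer_, layout$total_bins)
  gbin[usable] <- .quantile_groups(pc1$values[usable], n_groups)
  brk <- stats::quantile(pc1$values[usable],
                         probs = seq(0, 1, length.out = n_groups + 1),
                         names = FALSE)
  S <- matrix(0, n_groups, n_groups)
  N <- matrix(0, n_groups, n_groups)
  min_bins <- min_sep_bp / layout$bin_size
  for (oe in oe_list) {
    idx <- chrom_bins(layout, oe$chrom)
    loc <- which(usable[idx])
    if (length(loc) < 2L) next
    g <- gbin[idx][loc]
    sub <- oe$oe[loc, loc, drop = FALSE]
    d <- abs(outer(seq_along(loc), seq_along(loc), function(a, b)
      loc[a] - loc[b]))
    sel <- which(upper.tri(sub) & d > min_bins & !is.na(sub),
                 arr.ind = TRUE)
    if (nrow(sel) == 0L) next
    ga <- g[sel[, 1]]; gb <- g[sel[, 2]]; v <- sub[sel]
    for (k in seq_along(v)) {
      S[ga[k], gb[k]] <- S[ga[k], gb[k]] + v[k]
      N[ga[k], gb[k]] <- N[ga[k], gb[k]] + 1
      if (ga[k] != gb[k]) {
        S[gb[k], ga[k]] <- S[gb[k], ga[k]] + v[k]
        N[gb[k], ga[k]] <- N[gb[k], ga[k]] + 1
      }
    }
  }
  m <- S / N
  m[N == 0] <- NA
  structure(list(matrix = m, counts = N, n_groups = n_groups,
                 breaks = brk, min_sep_bp = min_sep_bp),
            class = "SaddleMatrix")
}

#' @export
print.SaddleMatrix <- function(x, ...) {
  n <- x$n_groups
  cat(sprintf("SaddleMatrix %dx%d: BB=%.3f AA=%.3f AB=%.3f\n", n, n,
              x$matrix[1, 1], x$matrix[n, n], x$matrix[1, n]))
  invisible(x)
}

#' Fold-change between two saddle matrices
#'
#' Elementwise ratio `a / b` for saddles sharing shape and group
#' definitions; missing or zero-denominator cells propagate as NA.
#'
#' @param s_a,s_b `SaddleMatrix` objects with equal `n_groups`.
#' @return A `SaddleMatrix` of ratios.
#' @export
saddle_fold_change <- function(s_a, s_b) {
  if (s_a$n_groups != s_b$n_groups) stop("saddle group counts differ")
  m <- s_a$matrix / s_b$matrix
  m[!is.finite(m)] <- NA
  structure(list(matrix = m, counts = pmin(s_a$counts, s_b$counts),
                 n_groups = s_a$n_groups, breaks = s_a$breaks,
                 min_sep_bp = s_a$min_sep_bp),
            class = "SaddleMatrix")
}

#' Joint PC1/RT table and sign-quadrant fractions
#'
#' Pairs PC1 and RT values on co-defined bins (for density-contour plots)
#' and reports the fraction of bins in each sign quadrant (values of exactly
#' 0 count as positive).
#'
#' @param pc1,rt `BinnedTrack`s on one layout.
#' @return List with `table` (data.frame bin, chrom, pc1, rt) and
#'   `quadrant_fractions` (named: `A_early`, `A_late`, `B_early`, `B_late`),
#'   summing to 1.
#' @export
pc1_rt_joint <- function(pc1, rt) {
  stop_if_layout_mismatch(pc1$layout, rt$layout)
  co <- which(!is.na(pc1$values) & !is.na(rt$values))
  df <- data.frame(bin = co, chrom = bin_chroms(pc1$layout)[co],
                   pc1 = pc1$values[co], rt = rt$values[co],
                   stringsAsFactors = FALSE)
  ap <- df$pc1 >= 0; ep <- df$rt >= 0
  q <- c(A_early = mean(ap & ep), A_late = mean(ap & !ep),
         B_early = mean(!ap & ep), B_late = mean(!ap & !ep))
  list(table = df, quadrant_fractions = q)
}
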