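#' Counts-per-million normalization of a binned track
#'
#' @param counts `BinnedTrack` of non-negative raw counts.
#' @return `BinnedTrack` with units `"CPM"`; defined values sum to 1e6.
#'   An all-zero (or all-missing) input yields an all-missing track with a
#'   warning.
#' @export
counts_to_cpm <- function(counts) {
  stopifnot(inherits(counts, "BinnedTrack"))
  v <- counts$values
  if (any(v < 0, na.rm = TRUE)) stop("negative counts")
  total <- sum(v, na.rm = TRUE)
  if (!is.finite(total) || total == 0) {
    warning("all-zero count track; CPM undefined")
    return(binned_track(counts$layout, NA_real_, "CPM"))
  }
  binned_track(counts$layout, v * 1e6 / total, "CPM")
}

#' Compute a log2(E/L) replication-timing profile
#'
#' `rt_i = log2((E_i + p) / (L_i + p))` per bin, on CPM-normalized early and
#' late fraction tracks. Bins missing in either input are missing in the
#' output; with `pseudocount = 0`, bins where either fraction is zero are
#' set to missing rather than +/-Inf.
#'
#' @param early,late `BinnedTrack`s on the same layout (CPM scale).
#' @param pseudocount Non-negative pseudocount `p` (default 1, CPM scale).
#' @return `BinnedTrack` with units `"log2ratio"` carrying a `provenance`
#'   attribute.
#' @export
compute_rt <- function(early, late, pseudocount = 1) {
  stop_if_layout_mismatch(early$layout, late$layout)
  stopifnot(pseudocount >= 0)
  num <- early$values + pseudocount
  den <- late$values + pseudocount
  rt <- ifelse(num > 0 & den > 0, log2(num / den), NA_real_)
  out <- binned_track(early$layout, rt, "log2ratio")
  attr(out, "provenance") <- list(pseudocount = pseudocount)
  out
}

# Tricube-weighted local linear fit at each defined bin, window = all
# defined bins within half_bp of the bin center on the same chromosome.
.local_linear <- function(x, y, half_bp) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- i; hi <- i
    while (lo > 1L && x[i] - x[lo - 1L] <= half_bp) lo <- lo - 1L
    while (hi < n && x[hi + 1L] - x[i] <= half_bp) hi <- hi + 1L
    u <- x[lo:hi] - x[i]
    w <- (1 - pmin(abs(u) / half_bp, 1)^3)^3
    yy <- y[lo:hi]
    sw <- sum(w); swu <- sum(w * u); swuu <- sum(w * u * u)
    swy <- sum(w * yy); swuy <- sum(w * u * yy)
    den <- sw * swuu - swu^2
    out[i] <- if (den > .Machine$double.eps * sw * max(swuu, 1))
      (swy * swuu - swu * swuy) / den
    else swy / sw
  }
  out
}

#' Loess-smooth an RT profile over a genomic span
#'
#' Tricube-weighted local linear regression where the window is a fixed
#' genomic distance (`span_bp / 2` on each side of the bin center, i.e. 15
#' bins each side at the default 300 kb span and 20 kb bins), not a fraction
#' of points. Smoothing is per chromosome, never crosses chromosome
#' boundaries, skips missing bins (they stay missing and do not contribute),
#' and reproduces constant and exactly linear tracks. A chromosome with
#' fewer than 3 defined bins is passed through with a warning.
#'
#' @param rt `BinnedTrack` of log2(E/L) values.
#' @param span_bp Full genomic span in bp (default 300000); must be at least
#'   twice the bin size.
#' @return Smoothed `BinnedTrack` with units `"log2ratio"`.
#' @export
loess_smooth <- function(rt, span_bp = 300000) {
  stopifnot(inherits(rt, "BinnedTrack"))
  layout <- rt$layout
  if (span_bp < 2 * layout$bin_size)
    stop("span_bp must be >= 2 * bin_size")
  half <- span_bp / 2
  centers <- (bin_starts(layout) + bin_ends(layout)) / 2
  out <- rep(NA_real_, layout$total_bins)
  for (ch in layout$chroms) {
    idx <- chrom_bins(layout, ch)
    def <- idx[!is.na(rt$values[idx])]
    if (length(def) == 0L) next
    if (length(def) < 3L) {
      warning("chromosome ", ch, " has < 3 defined bins; not smoothed")
      out[def] <- rt$values[def]
      next
    }
    out[def] <- .local_linear(centers[def], rt$values[def], half)
  }
  res <- binned_track(layout, out, "log2ratio")
  attr(res, "provenance") <- c(attr(rt, "provenance"),
                               list(span_bp = span_bp))
  res
}

#' Quantile-normalize a set of RT tracks to a common reference
#'
#' Optional cross-sample normalization (off by default in the pipeline):
#' each track's defined values are replaced by the mean of the sorted values
#' across tracks at the same quantile (sort-and-average reference mapping,
#' interpolating when tracks have different numbers of defined bins).
#'
#' @param tracks Named list of `BinnedTrack`s on one layout.
#' @return List of normalized `BinnedTrack`s.
#' @export
quantile_normalize_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 2)
  for (t in tracks[-1]) stop_if_layout_mismatch(tracks[[1]]$layout, t$layout)
  probs <- seq(0, 1, length.out = 1001)
  qs <- sapply(tracks, function(t)
    stats::quantile(t$values, probs, na.rm = TRUE, names = FALSE, type = 7))
  ref <- rowMeans(qs)
  lapply(tracks, function(t) {
    def <- !is.na(t$values)
    r <- (rank(t$values[def], ties.method = "average") - 1) /
      max(1, sum(def) - 1)
    v <- t$values
    v[def] <- stats::approx(probs, ref, xout = r, rule = 2)$y
    binned_track(t$layout, v, t$units)
  })
}
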