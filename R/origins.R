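#' Consensus peaks across replicates
#'
#' Maximal regions covered by a peak in every replicate (interval
#' intersection with >= 1 bp overlap); coordinates are the intersected
#' cores.
#'
#' @param replicates List of >= 2 `GRanges` peak sets.
#' @return Sorted `GRanges` of consensus regions (empty with a warning if
#'   replicates share no region).
#' @export
consensus_peaks <- function(replicates) {
  if (length(replicates) < 2L) stop("need >= 2 replicate peak sets")
  out <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), replicates)
  if (length(out) == 0L) warning("no consensus regions across replicates")
  normalize_intervals(out)
}

#' Cluster consensus peaks into initiation zones
#'
#' Consecutive peaks on a chromosome are chained whenever the gap from the
#' end of one peak to the start of the next is at most `gap_bp`; chains with
#' at least `min_peaks` members become zones spanning first start to last
#' end. When `gap_bp` is `NULL` it is set to the genome-wide median
#' interpeak (boundary-to-boundary) distance of the peak set, making the
#' clustering scale data-driven. Peaks outside every zone are dropped.
#'
#' @param peaks Sorted, non-overlapping `GRanges` (e.g. from
#'   [consensus_peaks()]).
#' @param min_peaks Minimum peaks per zone (default 2).
#' @param gap_bp Maximum chaining gap in bp, or `NULL` for the median
#'   interpeak distance.
#' @return List with `zones` (`GRanges` with `n_peaks`), `retained`
#'   (`GRanges` of peaks inside zones, with `zone` index) and `gap_bp`
#'   (the gap actually used).
#' @export
cluster_initiation_zones <- function(peaks, min_peaks = 2, gap_bp = NULL) {
  peaks <- normalize_intervals(peaks)
  if (length(peaks) > 1L) {
    ch <- as.character(GenomicRanges::seqnames(peaks))
    same <- ch[-1] == ch[-length(peaks)]
    if (any(same & GenomicRanges::start(peaks)[-1] <=
              GenomicRanges::end(peaks)[-length(peaks)]))
      stop("peaks must be non-overlapping")
  }
  ch <- as.character(GenomicRanges::seqnames(peaks))
  st0 <- GenomicRanges::start(peaks) - 1L   # 0-based
  en0 <- GenomicRanges::end(peaks)
  n <- length(peaks)
  if (n == 0L)
    return(list(zones = peaks, retained = peaks, gap_bp = gap_bp))
  same <- if (n > 1L) ch[-1] == ch[-n] else logical(0)
  gaps <- st0[-1] - en0[-n]                 # end-to-next-start distances
  gaps_same <- gaps[same]
  if (is.null(gap_bp)) {
    if (length(gaps_same) == 0L)
      stop("cannot derive a median interpeak distance from < 2 peaks")
    gap_bp <- stats::median(gaps_same)
  }
  # chain id: break where chromosome changes or gap exceeds gap_bp
  brk <- c(TRUE, !same | gaps > gap_bp)
  chain <- cumsum(brk)
  sizes <- tabulate(chain)
  keep_chain <- which(sizes >= min_peaks)
  retained <- peaks[chain %in% keep_chain]
  zone_id <- match(chain[chain %in% keep_chain], keep_chain)
  S4Vectors::mcols(retained)$zone <- zone_id
  zones <- GenomicRanges::GRanges(
    seqnames = ch[match(keep_chain, chain)],
    ranges = IRanges::IRanges(
      start = as.integer(tapply(GenomicRanges::start(retained),
                                zone_id, min)),
      end = as.integer(tapply(GenomicRanges::end(retained),
                              zone_id, max))),
    n_peaks = as.integer(sizes[keep_chain]),
    seqinfo = GenomeInfoDb::seqinfo(peaks))
  list(zones = zones, retained = retained, gap_bp = gap_bp)
}

#' Reads falling in each peak
#'
#' For a `BinnedTrack` of counts, a peak's reads are the coverage-weighted
#' sum of the counts of the bins it overlaps; for a `GRanges` with a
#' `count` column (e.g. simulated replicate peaks), reads of all
#' overlapping records are summed.
#'
#' @param peaks `GRanges`.
#' @param reads `BinnedTrack` (raw counts) or `GRanges` with `count`.
#' @return Numeric vector of per-peak read counts.
#' @export
count_reads_in_peaks <- function(peaks, reads) {
  if (inherits(reads, "BinnedTrack")) {
    bins <- layout_bins_gr(reads$layout)
    hits <- GenomicRanges::findOverlaps(peaks, bins)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(peaks[qi],
                                                         bins[si]))
    frac <- ov / GenomicRanges::width(bins)[si]
    v <- frac * ifelse(is.na(reads$values[si]), 0, reads$values[si])
    out <- numeric(length(peaks))
    agg <- tapply(v, qi, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  } else if (inherits(reads, "GRanges")) {
    hits <- GenomicRanges::findOverlaps(peaks, reads, ignore.strand = TRUE)
    out <- numeric(length(peaks))
    agg <- tapply(reads$count[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  } else stop("reads must be a BinnedTrack or a GRanges with a count column")
}

#' Quantify initiation-site densities per condition
#'
#' Density of a peak is `reads_in_peak * 1e6 / total_condition_reads`
#' (RPM). Per-condition input is either a per-peak read-count vector
#' (totals then default to the vector sum), a `BinnedTrack` of counts, or a
#' `GRanges` with a `count` column.
#'
#' @param peaks `GRanges` of initiation sites.
#' @param reads_by_condition Named list (one entry per condition).
#' @param totals Optional named vector of library sizes overriding the
#'   per-condition sums.
#' @return Data frame (`ISTable`): `chrom`, `start`, `end` (0-based
#'   half-open) plus one `density_<condition>` column per condition.
#' @export
quantify_is <- function(peaks, reads_by_condition, totals = NULL) {
  stopifnot(!is.null(names(reads_by_condition)))
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                    start = GenomicRanges::start(peaks) - 1L,
                    end = GenomicRanges::end(peaks),
                    stringsAsFactors = FALSE)
  for (cond in names(reads_by_condition)) {
    r <- reads_by_condition[[cond]]
    counts <- if (is.numeric(r)) {
      if (length(r) != length(peaks))
        stop("per-peak count vector length mismatch for ", cond)
      r
    } else count_reads_in_peaks(peaks, r)
    total <- if (!is.null(totals) && cond %in% names(totals))
      totals[[cond]]
    else if (is.numeric(r)) sum(r)
    else if (inherits(r, "BinnedTrack")) sum(r$values, na.rm = TRUE)
    else sum(r$count)
    if (!is.finite(total) || total <= 0)
      stop("zero library size for condition ", cond)
    tab[[paste0("density_", cond)]] <- counts * 1e6 / total
  }
  class(tab) <- c("ISTable", class(tab))
  tab
}

#' Classify initiation sites by density fold-change
#'
#' `fc = (d_a + p) / (d_b + p)`; a site is `up` when `fc >= threshold`,
#' `down` when `fc <= 1/threshold`, else `unchanged`. Adds `log2_fc` and
#' `change_class` columns and attaches the three class fractions
#' (summing to 1) as attribute `"fractions"`.
#'
#' @param table An `ISTable` from [quantify_is()].
#' @param cond_a,cond_b Condition names (fold-change is a over b).
#' @param threshold Fold-change threshold (default 1.5).
#' @param pseudocount Density pseudocount in RPM (default 0.01).
#' @return The table with `log2_fc` and `change_class` added.
#' @export
classify_fold_change <- function(table, cond_a, cond_b, threshold = 1.5,
                                 pseudocount = 0.01) {
  da <- table[[paste0("density_", cond_a)]]
  db <- table[[paste0("density_", cond_b)]]
  if (is.null(da) || is.null(db)) stop("unknown condition name")
  fc <- (da + pseudocount) / (db + pseudocount)
  table$log2_fc <- log2(fc)
  table$change_class <- ifelse(fc >= threshold, "up",
                               ifelse(fc <= 1 / threshold, "down",
                                      "unchanged"))
  frac <- c(up = mean(table$change_class == "up"),
            unchanged = mean(table$change_class == "unchanged"),
            down = mean(table$change_class == "down"))
  attr(table, "fractions") <- frac
  table
}

#' Split initiation sites into fold-change quintiles
#'
#' Sites are ranked by `log2_fc` ascending (ties broken by genomic
#' position, stable) and partitioned so class `i` gets ranks in
#' `(ceil((i-1)N/5), ceil(iN/5)]`: class 1 holds the most downregulated
#' sites, class 5 the most upregulated, and class sizes differ by at most
#' one.
#'
#' @param table An `ISTable` with `log2_fc` (see
#'   [classify_fold_change()]).
#' @param n_classes Number of classes (default 5).
#' @return The table with an integer `quintile` column added.
#' @export
quintile_classes <- function(table, n_classes = 5) {
  N <- nrow(table)
  if (N < n_classes) stop("need at least ", n_classes, " sites")
  ord <- order(table$log2_fc, table$chrom, table$start)
  r <- integer(N); r[ord] <- seq_len(N)
  table$quintile <- findInterval(
    r, ceiling(seq_len(n_classes) * N / n_classes), left.open = TRUE) + 1L
  table
}

#' RT profile of each initiation-site class
#'
#' Each site contributes the RT value of the bin containing its midpoint;
#' sites falling in undefined RT bins are excluded and counted.
#'
#' @param table An `ISTable` with a `quintile` column.
#' @param rt_by_condition Named list of RT `BinnedTrack`s.
#' @return List with `values` (`class -> condition -> numeric`), `medians`
#'   (data.frame) and `n_excluded` per condition.
#' @export
class_rt_profile <- function(table, rt_by_condition) {
  layout <- rt_by_condition[[1]]$layout
  mid <- floor((table$start + table$end) / 2)
  bins <- bin_at(layout, table$chrom, mid)
  classes <- sort(unique(table$quintile))
  values <- list(); rows <- list(); excl <- integer(0)
  for (cond in names(rt_by_condition)) {
    rt <- rt_by_condition[[cond]]$values[bins]
    excl[cond] <- sum(is.na(rt))
    for (cl in classes) {
      v <- rt[table$quintile == cl]
      v <- v[!is.na(v)]
      values[[as.character(cl)]][[cond]] <- v
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, condition = cond, n = length(v),
        median_rt = if (length(v)) stats::median(v) else NA_real_)
    }
  }
  list(values = values, medians = do.call(rbind, rows),
       n_excluded = excl)
}
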