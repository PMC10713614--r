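#' Summit of a signal track within an interval
#'
#' Leftmost genomic coordinate (0-based) achieving the maximum signal
#' within the interval; for a piecewise-constant binned track this is the
#' start of the leftmost maximal bin, clipped to the interval start.
#'
#' @param track A `BinnedTrack` (typically at fine, e.g. 50 bp,
#'   resolution).
#' @param interval A length-1 `GRanges`.
#' @return 0-based bp position of the summit.
#' @export
summit <- function(track, interval) {
  stopifnot(length(interval) == 1L)
  layout <- track$layout
  ch <- as.character(GenomicRanges::seqnames(interval))
  s0 <- GenomicRanges::start(interval) - 1L
  e0 <- GenomicRanges::end(interval)
  b1 <- bin_at(layout, ch, s0)
  b2 <- bin_at(layout, ch, e0 - 1L)
  if (is.na(b1) || is.na(b2)) stop("interval outside layout")
  bins <- b1:b2
  v <- track$values[bins]
  if (all(is.na(v))) stop("no defined signal within interval")
  i <- which(v == max(v, na.rm = TRUE))[1]
  max(s0, bin_starts(layout)[bins[i]])
}

#' Summit-centered signal matrix
#'
#' For each site (summit = interval midpoint) and each track, the signal in
#' `window_bp / bin_bp` consecutive `bin_bp` windows centered on the summit
#' (80 columns at the default 4 kb / 50 bp). Each column takes the track
#' value at the column center; positions outside the chromosome or on
#' missing bins are set to 0.
#'
#' @param sites `GRanges` of summit positions (or peaks; midpoints are
#'   used).
#' @param tracks Named list of `BinnedTrack`s at matching fine resolution.
#' @param window_bp Window width in bp (default 4000); must be divisible by
#'   `bin_bp`.
#' @param bin_bp Column width in bp (default 50).
#' @return Object of class `MetaMatrix`: `sites`, `matrices` (named list of
#'   site x column matrices), `window_bp`, `bin_bp`.
#' @export
site_matrix <- function(sites, tracks, window_bp = 4000, bin_bp = 50) {
  if (window_bp %% bin_bp != 0)
    stop("window_bp must be divisible by bin_bp")
  stopifnot(!is.null(names(tracks)))
  ncol_ <- window_bp %/% bin_bp
  ch <- as.character(GenomicRanges::seqnames(sites))
  mid <- floor((GenomicRanges::start(sites) - 1 +
                  GenomicRanges::end(sites)) / 2)
  offs <- -window_bp / 2 + (seq_len(ncol_) - 1) * bin_bp + bin_bp / 2
  mats <- lapply(tracks, function(tr) {
    m <- matrix(0, length(sites), ncol_)
    for (j in seq_len(ncol_)) {
      b <- bin_at(tr$layout, ch, mid + offs[j])
      v <- ifelse(is.na(b), 0, tr$values[ifelse(is.na(b), 1L, b)])
      m[, j] <- ifelse(is.na(v), 0, v)
    }
    m
  })
  structure(list(sites = sites, matrices = mats, window_bp = window_bp,
                 bin_bp = bin_bp),
            class = "MetaMatrix")
}

#' @export
print.MetaMatrix <- function(x, ...) {
  cat(sprintf("MetaMatrix: %d sites x %d columns, tracks: %s\n",
              length(x$sites), x$window_bp %/% x$bin_bp,
              paste(names(x$matrices), collapse = ", ")))
  invisible(x)
}

#' k-means clustering of summit-centered sites
#'
#' Per-track signal matrices are standardized (z-score over all entries of
#' that track, so no track's scale dominates; disable with
#' `standardize = FALSE` for raw-matrix behavior) and concatenated into one
#' feature vector per site. k-means labels are renumbered by descending
#' mean focal-track signal (cluster 1 = strongest) and rows within each
#' cluster are ordered by descending focal signal, the conventional heatmap
#' layout.
#'
#' @param meta A `MetaMatrix`.
#' @param k Number of clusters (default 3).
#' @param focal Name of the ordering track (default: first).
#' @param seed Seed for k-means restarts.
#' @param n_restarts k-means random starts (default 10).
#' @param standardize Standardize per track before clustering.
#' @return List with `labels` (per site), `order` (row order for heatmaps),
#'   `profiles` (`cluster -> track -> column means`), `sizes`, and
#'   `focal_mean` per site.
#' @export
kmeans_cluster_sites <- function(meta, k = 3, focal = names(meta$matrices)[1],
                                 seed = 1L, n_restarts = 10,
                                 standardize = TRUE) {
  n <- length(meta$sites)
  if (n < k) stop("need at least k sites")
  feats <- lapply(meta$matrices, function(m) {
    if (!standardize) return(m)
    s <- stats::sd(m)
    if (!is.finite(s) || s == 0) s <- 1
    (m - mean(m)) / s
  })
  x <- do.call(cbind, feats)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  focal_mean <- rowMeans(meta$matrices[[focal]])
  cl_mean <- tapply(focal_mean, km$cluster, mean)
  new_id <- integer(k)
  new_id[order(-cl_mean)] <- seq_len(k)   # 1 = strongest focal signal
  labels <- new_id[km$cluster]
  ord <- order(labels, -focal_mean)
  profiles <- lapply(seq_len(k), function(cl)
    lapply(meta$matrices, function(m)
      colMeans(m[labels == cl, , drop = FALSE])))
  names(profiles) <- paste0("cluster", seq_len(k))
  list(labels = labels, order = ord, profiles = profiles,
       sizes = tabulate(labels, k), focal_mean = focal_mean)
}

#' Remove peaks overlapping broad domains
#'
#' Keeps only peaks with zero bp overlap with any domain (1 bp overlap
#' already removes a peak); idempotent.
#'
#' @param peaks,domains `GRanges`.
#' @return Filtered `GRanges`.
#' @export
filter_peaks_by_domains <- function(peaks, domains) {
  if (length(domains) == 0L) return(peaks)
  hits <- GenomicRanges::findOverlaps(peaks, domains, ignore.strand = TRUE)
  keep <- setdiff(seq_along(peaks),
                  unique(S4Vectors::queryHits(hits)))
  peaks[sort(keep)]
}

#' Annotate sites as TSS, gene body or intergenic
#'
#' Precedence TSS > gene body > intergenic: a site within `tss_window_bp`
#' of a strand-aware transcription start site is `TSS`; otherwise a site
#' overlapping a gene is `gene_body`; otherwise `intergenic`.
#'
#' @param sites `GRanges`.
#' @param genes `GRanges` with strand (TSS = start on `+`, end on `-`).
#' @param tss_window_bp Promoter window half-width (default 1000).
#' @return Character vector per site.
#' @export
annotate_intervals <- function(sites, genes, tss_window_bp = 1000) {
  tss_pos <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                    GenomicRanges::end(genes), GenomicRanges::start(genes))
  tss <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(start = pmax(1, tss_pos - tss_window_bp),
                              end = tss_pos + tss_window_bp))
  lab <- rep("intergenic", length(sites))
  in_gene <- IRanges::overlapsAny(sites, genes, ignore.strand = TRUE)
  lab[in_gene] <- "gene_body"
  in_tss <- IRanges::overlapsAny(sites, tss, ignore.strand = TRUE)
  lab[in_tss] <- "TSS"
  lab
}

#' Mean RT and RT-class assignment of intervals
#'
#' Per site, the mean RT over covered defined bins and the majority RT
#' class among covered bins (ties resolved by the class of the bin holding
#' the site midpoint). Sites entirely in undefined bins are excluded and
#' counted.
#'
#' @param sites `GRanges`.
#' @param rt RT `BinnedTrack`.
#' @param seg `RTStateSegmentation` on the same layout.
#' @return List with `table` (site, mean_rt, class), `class_fractions`
#'   (over included sites, summing to 1) and `n_excluded`.
#' @export
interval_rt <- function(sites, rt, seg) {
  layout <- rt$layout
  bins <- layout_bins_gr(layout)
  hits <- GenomicRanges::findOverlaps(sites, bins, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  mid <- floor((GenomicRanges::start(sites) - 1 +
                  GenomicRanges::end(sites)) / 2)
  mid_bin <- bin_at(layout, as.character(GenomicRanges::seqnames(sites)),
                    mid)
  mean_rt <- rep(NA_real_, length(sites))
  cls <- rep(NA_character_, length(sites))
  for (i in unique(qi)) {
    bb <- si[qi == i]
    v <- rt$values[bb]
    if (all(is.na(v))) next
    mean_rt[i] <- mean(v, na.rm = TRUE)
    cc <- seg$class[bb]
    cc <- cc[!is.na(cc)]
    if (length(cc) == 0L) next
    tab <- table(cc)
    top <- names(tab)[tab == max(tab)]
    cls[i] <- if (length(top) == 1L) top
      else if (!is.na(mid_bin[i]) && !is.na(seg$class[mid_bin[i]]) &&
                 seg$class[mid_bin[i]] %in% top) seg$class[mid_bin[i]]
      else top[1]
  }
  inc <- !is.na(cls)
  frac <- table(factor(cls[inc], c("E", "E-like", "L-like", "L"))) /
    max(1, sum(inc))
  list(table = data.frame(site = seq_along(sites), mean_rt = mean_rt,
                          class = cls, stringsAsFactors = FALSE),
       class_fractions = as.numeric(frac),
       class_names = names(frac),
       n_excluded = sum(!inc))
}
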