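#' Fixed-bin genome layout
#'
#' A `GenomeLayout` tiles each chromosome into consecutive half-open windows
#' of `bin_size` bp (the last bin of a chromosome may be shorter and is kept,
#' not dropped). All binned tracks, contact matrices and segmentations in the
#' package are indexed against one shared layout, with global bin indices
#' running 1..`total_bins` in chromosome order.
#'
#' @param chroms Character vector of chromosome names (order is kept).
#' @param lengths Integer-like vector of chromosome lengths in bp, parallel
#'   to `chroms`.
#' @param bin_size Bin width in bp (default 20000, the resolution used for
#'   RT, compartment and transcription tracks throughout).
#' @return An object of class `GenomeLayout` with fields `chroms`, `lengths`,
#'   `bin_size`, `n_bins` (per chromosome), `offsets` (global index of the
#'   bin before each chromosome's first bin) and `total_bins`.
#' @examples
#' gl <- genome_layout(c("chr1", "chr2"), c(100000, 40000), 20000)
#' gl$total_bins  # 7
#' @export
genome_layout <- function(chroms, lengths, bin_size = 20000L) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (anyDuplicated(chroms))
    stop("duplicate chromosome name: ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a positive scalar")
  bin_size <- as.integer(bin_size)
  n_bins <- as.integer(ceiling(lengths / bin_size))
  offsets <- c(0L, cumsum(n_bins))[seq_along(chroms)]
  names(n_bins) <- names(offsets) <- names(lengths) <- chroms
  structure(
    list(chroms = chroms, lengths = lengths, bin_size = bin_size,
         n_bins = n_bins, offsets = offsets,
         total_bins = as.integer(sum(n_bins))),
    class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout: %d chromosome(s), bin_size=%d, %d bins\n",
              length(x$chroms), x$bin_size, x$total_bins))
  invisible(x)
}

#' Chromosome of each global bin
#' @param layout A `GenomeLayout`.
#' @return Character vector of length `layout$total_bins`.
#' @export
bin_chroms <- function(layout) {
  rep(layout$chroms, layout$n_bins)
}

#' Start/end coordinates of each global bin
#'
#' Coordinates are 0-based half-open (BED convention); the terminal bin of a
#' chromosome is clipped to the chromosome length.
#'
#' @param layout A `GenomeLayout`.
#' @return Numeric vector of per-bin starts (`bin_starts`) or ends
#'   (`bin_ends`) in bp.
#' @export
bin_starts <- function(layout) {
  unlist(lapply(seq_along(layout$chroms), function(i) {
    (seq_len(layout$n_bins[i]) - 1) * layout$bin_size
  }), use.names = FALSE)
}

#' @rdname bin_starts
#' @export
bin_ends <- function(layout) {
  unlist(lapply(seq_along(layout$chroms), function(i) {
    pmin(seq_len(layout$n_bins[i]) * layout$bin_size, layout$lengths[i])
  }), use.names = FALSE)
}

#' Global bin indices of one chromosome
#' @param layout A `GenomeLayout`.
#' @param chrom Chromosome name.
#' @return Integer vector of global (1-based) bin indices.
#' @export
chrom_bins <- function(layout, chrom) {
  if (!chrom %in% layout$chroms) stop("unknown chromosome: ", chrom)
  layout$offsets[[chrom]] + seq_len(layout$n_bins[[chrom]])
}

#' Map genomic positions to global bin indices
#' @param layout A `GenomeLayout`.
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 0-based bp position(s).
#' @return Global bin index per position (NA for positions outside the
#'   chromosome).
#' @export
bin_at <- function(layout, chrom, pos) {
  chrom <- rep_len(as.character(chrom), length(pos))
  idx <- rep(NA_integer_, length(pos))
  ok <- chrom %in% layout$chroms
  valid <- ok & pos >= 0 & pos < layout$lengths[chrom]
  idx[valid] <- layout$offsets[chrom[valid]] +
    as.integer(pos[valid] %/% layout$bin_size) + 1L
  idx
}

#' All layout bins as a GRanges
#' @param layout A `GenomeLayout`.
#' @return `GRanges` with one range per global bin, in global order.
#' @export
layout_bins_gr <- function(layout) {
  gr <- GenomicRanges::GRanges(
    seqnames = bin_chroms(layout),
    ranges = IRanges::IRanges(start = bin_starts(layout) + 1L,
                              end = bin_ends(layout)))
  GenomeInfoDb::seqlengths(gr) <- layout$lengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Per-bin numeric signal track
#'
#' A `BinnedTrack` couples a numeric vector (one value per global layout bin;
#' `NA` marks bins where the signal is undefined, never silently zero) with
#' its layout and a units tag.
#'
#' @param layout A `GenomeLayout`.
#' @param values Numeric vector of length `layout$total_bins` (or a scalar,
#'   recycled).
#' @param units One of `"counts"`, `"CPM"`, `"log2ratio"`, `"RPM"`,
#'   `"eigen"`, or any descriptive string.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(layout, values = NA_real_, units = "counts") {
  stopifnot(inherits(layout, "GenomeLayout"))
  values <- as.numeric(values)
  if (length(values) == 1L) values <- rep(values, layout$total_bins)
  if (length(values) != layout$total_bins)
    stop("values length ", length(values), " != total bins ",
         layout$total_bins)
  structure(list(layout = layout, values = values, units = units),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack [%s]: %d bins, %d defined\n", x$units,
              length(x$values), sum(!is.na(x$values))))
  invisible(x)
}

same_layout <- function(a, b) {
  identical(a$chroms, b$chroms) && identical(a$lengths, b$lengths) &&
    identical(a$bin_size, b$bin_size)
}

stop_if_layout_mismatch <- function(a, b) {
  if (!same_layout(a, b)) stop("tracks are defined on different layouts")
  invisible(TRUE)
}

#' Normalize an interval set
#'
#' Sorts a `GRanges` by (chromosome, start) with chromosome order taken from
#' the object's seqlevels, and drops records that violate basic interval
#' sanity. Normalization is idempotent. Strand is carried but ignored by all
#' downstream computations.
#'
#' @param gr A `GRanges`.
#' @return The sorted `GRanges`.
#' @export
normalize_intervals <- function(gr) {
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
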