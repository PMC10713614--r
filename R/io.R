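#' Read a chrom.sizes file into a genome layout
#'
#' @param path Two-column whitespace-separated text (name, length in bp);
#'   gzip-transparent.
#' @param bin_size Bin width in bp.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path, bin_size = 20000L) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) < 1L) stop("empty chrom.sizes file: ", path)
  genome_layout(df$chrom, df$length, bin_size)
}

#' Read a BED file as a normalized interval set
#'
#' Accepts BED3 to BED6 (gzip-transparent). Records with `start >= end` are
#' rejected with a warning; records on chromosomes absent from `layout` are
#' skipped or raise an error according to `on_unknown`. Output is sorted by
#' (chromosome, start); the number of rejected records is attached as
#' attribute `"n_rejected"`.
#'
#' @param path BED text file.
#' @param layout A `GenomeLayout` providing the chromosome universe.
#' @param on_unknown `"skip"` (default) or `"fail"` for records on unknown
#'   chromosomes.
#' @return A sorted `GRanges` (1-based internally; BED coordinates are
#'   0-based half-open on disk).
#' @export
read_intervals <- function(path, layout, on_unknown = c("skip", "fail")) {
  on_unknown <- match.arg(on_unknown)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs >= 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  bad <- !(df$start < df$end) | df$start < 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with start >= end rejected in ", path)
    df <- df[!bad, , drop = FALSE]
  }
  unknown <- !df$chrom %in% layout$chroms
  if (any(unknown)) {
    if (on_unknown == "fail")
      stop("unknown chromosome(s) in ", path, ": ",
           paste(unique(df$chrom[unknown]), collapse = ", "))
    df <- df[!unknown, , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    name = if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_,
    score = if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5L]]))
            else NA_real_,
    strand = if (ncol(df) >= 6L && all(df[[6L]] %in% c("+", "-", ".")))
               df[[6L]] else "*")
  GenomeInfoDb::seqlevels(gr) <- layout$chroms
  GenomeInfoDb::seqlengths(gr) <- layout$lengths
  out <- normalize_intervals(gr)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write an interval set as BED
#' @param gr A `GRanges` (optionally with `name`/`score` metadata columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) {
    df$name <- mc$name
    df$score <- if (!is.null(mc$score)) mc$score else 0
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file onto a genome layout
#'
#' bedGraph intervals that align with layout bins map directly; rows covering
#' several bins assign their value to each covered bin; several rows falling
#' on one bin are combined by coverage-weighted mean. Bins with no covering
#' row are `NA`. Overlapping bedGraph rows are a format error.
#'
#' @param path bedGraph text (gzip-transparent).
#' @param layout A `GenomeLayout`.
#' @param units Units tag for the resulting track.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, layout, units = "counts") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% layout$chroms]
  GenomeInfoDb::seqlevels(gr) <- layout$chroms
  gr <- normalize_intervals(gr)
  if (length(gr) > 1L) {
    same <- as.character(GenomicRanges::seqnames(gr))[-1] ==
      as.character(GenomicRanges::seqnames(gr))[-length(gr)]
    if (any(same & GenomicRanges::start(gr)[-1] <=
              GenomicRanges::end(gr)[-length(gr)]))
      stop("overlapping bedGraph rows in ", path)
  }
  bins <- layout_bins_gr(layout)
  hits <- GenomicRanges::findOverlaps(bins, gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(bins[qi], gr[si])
  w <- GenomicRanges::width(ov)
  vals <- rep(NA_real_, layout$total_bins)
  num <- tapply(w * gr$score[si], qi, sum)
  den <- tapply(w, qi, sum)
  vals[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  binned_track(layout, vals, units)
}

#' Write a binned track as bedGraph
#'
#' Defined bins are written one row per bin; `NA` bins are absent from the
#' file, so `read_bedgraph(write_bedgraph(t))` reproduces `t` on defined
#' bins.
#'
#' @param track A `BinnedTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  keep <- !is.na(track$values)
  gr <- layout_bins_gr(track$layout)[keep]
  gr$score <- track$values[keep]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Per-chromosome Hi-C contact matrix
#'
#' Symmetric raw counts for one chromosome of a layout, plus (after
#' [balance_matrix()]) balancing weights and a mask of excluded bins.
#'
#' @param layout A `GenomeLayout`.
#' @param chrom Chromosome name.
#' @param counts Symmetric non-negative square matrix with one row per bin
#'   of `chrom`.
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(layout, chrom, counts) {
  n <- layout$n_bins[[chrom]]
  counts <- as.matrix(counts)
  if (!all(dim(counts) == n))
    stop("counts must be ", n, "x", n, " for ", chrom)
  if (any(counts < 0)) stop("negative contact counts")
  if (!isTRUE(all.equal(counts, t(counts))))
    stop("contact counts must be symmetric")
  structure(list(layout = layout, chrom = chrom, counts = counts,
                 weights = NULL, mask = rep(FALSE, n)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix %s: %d bins, %.0f contacts, %s\n", x$chrom,
              nrow(x$counts), sum(x$counts) / 2,
              if (is.null(x$weights)) "unbalanced" else "balanced"))
  invisible(x)
}

#' Read a sparse contact-triplet file
#'
#' Each row is `binA binB count` with 0-based bin ordinals within the
#' chromosome. Entries are mirrored to enforce symmetry; duplicate triplets
#' (including mirrored duplicates) are summed.
#'
#' @param path Triplet text (gzip-transparent).
#' @param layout A `GenomeLayout`.
#' @param chrom Chromosome the matrix belongs to.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, layout, chrom) {
  n <- layout$n_bins[[chrom]]
  m <- matrix(0, n, n)
  df <- tryCatch(
    utils::read.table(path, header = FALSE,
                      col.names = c("i", "j", "count")),
    error = function(e) NULL)
  if (!is.null(df) && nrow(df) > 0L) {
    if (any(df$i < 0 | df$i >= n | df$j < 0 | df$j >= n))
      stop("bin ordinal out of range [0,", n - 1L, ") in ", path)
    if (any(df$count < 0)) stop("negative count in ", path)
    for (k in seq_len(nrow(df))) {
      a <- df$i[k] + 1L; b <- df$j[k] + 1L
      m[a, b] <- m[a, b] + df$count[k]
      if (a != b) m[b, a] <- m[b, a] + df$count[k]
    }
  }
  contact_matrix(layout, chrom, m)
}

#' Write a contact matrix as sparse triplets
#'
#' Writes the upper triangle (including diagonal) of the raw counts, 0-based
#' ordinals, omitting zero cells.
#'
#' @param cm A `ContactMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
               arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   count = cm$counts[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
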