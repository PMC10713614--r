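#' Transcription-based grouping of early-replicating bins
#'
#' Bins below `min_rpm` nascent-transcription density are `Untranscribed`;
#' the remaining bins are ranked by RPM and split into three equal-count
#' tertiles, `High` (top third), `Medium`, `Low`. The tertile RPM ranges
#' are data-dependent outputs, reported as boundaries. Ties at tertile
#' boundaries are broken by bin index (stable).
#'
#' @param e_bins Integer vector of global bin indices (typically the E bins
#'   of a reference [segment_rt()] call).
#' @param proseq `BinnedTrack` of transcription density (RPM); must be
#'   defined on every `e_bins` bin.
#' @param min_rpm Transcription threshold in RPM (default 10).
#' @return Object of class `TranscriptionGrouping`: `bins`, `group`
#'   (character per bin in High/Medium/Low/Untranscribed), `rpm`,
#'   `boundaries` (data.frame of per-group RPM ranges), `threshold`.
#' @export
transcription_groups <- function(e_bins, proseq, min_rpm = 10) {
  rpm <- proseq$values[e_bins]
  if (any(is.na(rpm))) stop("transcription track undefined on some bins")
  txn <- rpm >= min_rpm
  if (sum(txn) < 3) stop("fewer than 3 transcribed bins")
  group <- rep("Untranscribed", length(e_bins))
  ter <- .quantile_groups(rpm[txn], 3)       # 1 = lowest RPM
  group[txn] <- c("Low", "Medium", "High")[ter]
  bounds <- do.call(rbind, lapply(c("High", "Medium", "Low",
                                    "Untranscribed"), function(g) {
    v <- rpm[group == g]
    data.frame(group = g, n = length(v),
               rpm_min = if (length(v)) min(v) else NA_real_,
               rpm_max = if (length(v)) max(v) else NA_real_)
  }))
  structure(list(bins = e_bins, group = group, rpm = rpm,
                 boundaries = bounds, threshold = min_rpm),
            class = "TranscriptionGrouping")
}

#' @export
print.TranscriptionGrouping <- function(x, ...) {
  cat("TranscriptionGrouping:",
      paste(x$boundaries$group, x$boundaries$n, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Per-group RT distributions across conditions
#'
#' For every transcription group and condition, the RT values of member
#' bins, plus a long-format table with rows ordered by descending reference
#' transcription (the heatmap row order).
#'
#' @param grouping A `TranscriptionGrouping`.
#' @param rt_by_condition Named list of RT `BinnedTrack`s.
#' @return List with `values` (`group -> condition -> numeric`), `table`
#'   (long data.frame ordered by descending RPM) and `modes` (data.frame of
#'   per-group, per-condition KDE modes).
#' @export
group_rt_distributions <- function(grouping, rt_by_condition) {
  stopifnot(!is.null(names(rt_by_condition)))
  groups <- c("High", "Medium", "Low", "Untranscribed")
  ord <- order(-grouping$rpm)
  values <- list(); tabs <- list(); modes <- list()
  for (g in groups) {
    sel <- grouping$group == g
    values[[g]] <- list()
    for (cond in names(rt_by_condition)) {
      v <- rt_by_condition[[cond]]$values[grouping$bins[sel]]
      values[[g]][[cond]] <- v[!is.na(v)]
      modes[[length(modes) + 1L]] <- data.frame(
        group = g, condition = cond, n = sum(!is.na(v)),
        mode = if (sum(!is.na(v)) >= 2)
          as.numeric(kde_mode(v[!is.na(v)])) else NA_real_)
    }
  }
  for (cond in names(rt_by_condition))
    tabs[[cond]] <- data.frame(
      bin = grouping$bins[ord], group = grouping$group[ord],
      rpm = grouping$rpm[ord], condition = cond,
      rt = rt_by_condition[[cond]]$values[grouping$bins[ord]],
      stringsAsFactors = FALSE)
  list(values = values, table = do.call(rbind, tabs),
       modes = do.call(rbind, modes))
}

#' Distance between distribution modes
#'
#' Gaussian KDEs (Silverman bandwidth) of two samples are evaluated on one
#' shared grid spanning the pooled range; the result is
#' `mode(a) - mode(b)`. When either density has a near-tied secondary peak
#' (within 1% of the maximum), the `ambiguous` attribute is set.
#'
#' @param values_a,values_b Numeric samples (>= 30 values each).
#' @param grid_points Shared grid size (default 512).
#' @return Scalar mode difference with attribute `ambiguous`.
#' @export
mode_shift <- function(values_a, values_b, grid_points = 512) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 30 || length(values_b) < 30)
    stop("need >= 30 values per sample")
  lo <- min(values_a, values_b); hi <- max(values_a, values_b)
  ma <- kde_mode(values_a, grid_points, lo, hi)
  mb <- kde_mode(values_b, grid_points, lo, hi)
  structure(as.numeric(ma) - as.numeric(mb),
            ambiguous = attr(ma, "ambiguous") || attr(mb, "ambiguous"))
}
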