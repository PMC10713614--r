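# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use naive enumeration / per-point fits so
# they share no code path with the package implementation.

tiny_layout <- function(n_bins = 10, bin_size = 20000, chroms = "chrT") {
  genome_layout(chroms, rep(n_bins * bin_size, length(chroms)), bin_size)
}

track_of <- function(values, bin_size = 20000, units = "counts",
                     chroms = "chrT") {
  layout <- genome_layout(chroms, length(values) * bin_size /
                            length(chroms), bin_size)
  binned_track(layout, values, units)
}

gr_of <- function(chrom, start0, end0, seqlen = NULL, ...) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1,
                                                end = end0), ...)
  if (!is.null(seqlen))
    GenomeInfoDb::seqlengths(gr) <- seqlen[GenomeInfoDb::seqlevels(gr)]
  gr
}

# exhaustive max-product Viterbi over all K^T paths
viterbi_brute <- function(y, means, vars, init, trans) {
  K <- length(means); Tn <- length(y)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf; best_path <- NULL
  for (row in seq_len(nrow(grid))) {
    path <- grid[row, ]
    lp <- log(init[path[1]]) +
      sum(stats::dnorm(y, means[path], sqrt(vars[path]), log = TRUE))
    if (Tn > 1)
      lp <- lp + sum(log(trans[cbind(path[-Tn], path[-1])]))
    if (lp > best) { best <- lp; best_path <- path }
  }
  as.integer(unname(best_path))
}

# per-point tricube local linear regression via lm()
loess_brute <- function(x, y, half_bp) {
  sapply(seq_along(x), function(i) {
    d <- abs(x - x[i])
    sel <- d <= half_bp
    w <- (1 - (d[sel] / half_bp)^3)^3
    fit <- stats::lm(y[sel] ~ I(x[sel] - x[i]), weights = w)
    unname(stats::coef(fit)[1])
  })
}

# exhaustive pair-average saddle for arbitrary group assignment
saddle_brute <- function(oe, groups, n_groups, min_sep_bins) {
  S <- matrix(0, n_groups, n_groups); N <- matrix(0, n_groups, n_groups)
  n <- nrow(oe)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i <= min_sep_bins) next
    v <- oe[i, j]
    if (is.na(v) || is.na(groups[i]) || is.na(groups[j])) next
    a <- groups[i]; b <- groups[j]
    S[a, b] <- S[a, b] + v; N[a, b] <- N[a, b] + 1
    if (a != b) { S[b, a] <- S[b, a] + v; N[b, a] <- N[b, a] + 1 }
  }
  out <- S / N
  out[N == 0] <- NA
  out
}

# transitive-closure zone clustering: connected components of the
# "boundary gap <= g" relation over all peak pairs, then size filter
zones_brute <- function(chrom, start0, end0, gap_bp, min_peaks) {
  n <- length(start0)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || chrom[i] != chrom[j]) next
    gap <- max(start0[i], start0[j]) - min(end0[i], end0[j])
    adj[i, j] <- gap <= gap_bp
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    if (!changed) break
  }
  sizes <- table(comp)
  keep <- comp %in% as.integer(names(sizes)[sizes >= min_peaks])
  list(member = keep, component = comp)
}

# random disjoint sorted peak set on one or two chromosomes
random_peaks <- function(n, chroms = c("c1", "c2"), span = 2e5) {
  ch <- sort(sample(chroms, n, replace = TRUE))
  out <- NULL
  for (cc in unique(ch)) {
    k <- sum(ch == cc)
    s <- sort(sample.int(span, k))
    w <- sample(5:30, k, replace = TRUE)
    s <- s + cumsum(c(0, head(w, -1) + 5))   # enforce disjointness
    out <- rbind(out, data.frame(chrom = cc, start = s, end = s + w))
  }
  out
}

# planted three-archetype summit matrices on a 50 bp layout
archetype_sites <- function(n_per = 100, seed = 1) {
  set.seed(seed)
  bin <- 50
  n_sites <- 3 * n_per
  spacing <- 10000
  layout <- genome_layout("chrF", n_sites * spacing + 20000, bin)
  centers <- spacing * seq_len(n_sites)
  truth <- rep(1:3, each = n_per)[sample(n_sites)]
  mk <- function() binned_track(layout, 0, "RPM")
  focal <- mk(); txn <- mk(); acc <- mk()
  shape <- exp(-((-40:39) + 0.5)^2 / (2 * 8^2))   # gaussian bump, 80 cols
  for (i in seq_len(n_sites)) {
    b <- bin_at(layout, "chrF", centers[i] - 2000 + bin * (0:79))
    focal$values[b] <- 5 * shape + rnorm(80, 0, 0.2)
    if (truth[i] == 1) {            # active-TSS-like
      txn$values[b] <- 8 * shape + rnorm(80, 0, 0.2)
      acc$values[b] <- 6 * shape + rnorm(80, 0, 0.2)
    } else if (truth[i] == 2) {     # accessible-only
      txn$values[b] <- rnorm(80, 0, 0.2)
      acc$values[b] <- 6 * shape + rnorm(80, 0, 0.2)
    } else {                        # silent
      txn$values[b] <- rnorm(80, 0, 0.2)
      acc$values[b] <- rnorm(80, 0, 0.2)
    }
  }
  sites <- gr_of("chrF", centers - 1, centers,
                 seqlen = c(chrF = layout$lengths[[1]]))
  list(sites = sites, truth = truth,
       tracks = list(focal = focal, txn = txn, acc = acc))
}
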