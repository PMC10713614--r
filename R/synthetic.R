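#' Default synthetic-genome configuration
#'
#' Returns the configuration list used by [make_truth()], describing a small
#' multi-chromosome genome tiled in 20 kb bins with alternating early/late
#' replication domains, a two-compartment plaid tied to RT sign,
#' transcription concentrated in a fraction of A-compartment bins, and a
#' catalog of replication initiation sites whose strength is coupled to RT.
#'
#' Scenario parameters:
#' * `mcm_c`: under `mcm_depletion`, RT is compressed genome-wide toward 0
#'   by this factor (`rt <- mcm_c * rt`).
#' * `rif1_delta_e`: under `rif1_loss`, every bin of an early domain is
#'   delayed by this amount (log2 units).
#' * `rif1_l_frac` / `rif1_l_delta`: fraction of late domains perturbed
#'   under `rif1_loss`, half advanced by `+rif1_l_delta` and half delayed by
#'   `-rif1_l_delta`; the remaining late domains keep their RT, so the
#'   late-class mode shift planted by the scenario is 0.
#' * `txn_rt_delay`: optional transcription-coupled extra delay (log2 units
#'   at high transcription) applied with the MCM-depletion component; 0 by
#'   default so that plain `mcm_depletion` is a pure compression.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
synth_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chrS1 = 30e6, chrS2 = 24e6, chrS3 = 16e6),
    bin_size = 20000,
    rt_amplitude = 1.5,        # log2(E/L) at domain plateaus
    domain_bins = 50,          # mean domain size in bins (1 Mb at 20 kb)
    min_domain_bins = 10,
    ramp_bins = 5,             # moving-average half-smoothing at boundaries
    txn_fraction = 0.5,        # fraction of A bins that are transcribed
    txn_block_bins = 10,       # mean transcribed-block length (gene cluster)
    txn_meanlog = log(80), txn_sdlog = 1.2,  # block-level RPM
    txn_bin_jitter = 0.2,      # per-bin lognormal jitter within a block
    txn_background_rpm = 5,    # upper bound of untranscribed bin RPM
    origins_per_mb = 20,
    origin_width = 300,
    origin_rt_coupling = 0.6,  # log-strength per unit RT
    origin_sdlog = 0.5,
    mcm_c = 0.3,
    mcm_is_effect = 0.45,      # log2 IS fold-change per unit RT under MCM loss
    rif1_delta_e = 0.8,
    rif1_l_frac = 0.3,
    rif1_l_delta = 0.4,
    rif1_is_frac = 0.05,       # fraction of ISs downregulated under rif1_loss
    rif1_is_log2fc = -1,
    txn_rt_delay = 0,
    compartment_mixing = 0)    # fractional loss of plaid strength
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# Child seeds: one master seed drives every assay through fixed offsets, so
# each assay can be regenerated independently and scenario perturbations do
# not disturb the base genome structure.
.seed_offsets <- c(structure = 0L, scenario = 1013904L, repli = 104729L,
                   contacts = 217645L, proseq = 319993L, is = 611953L)

child_seed <- function(seed, what) {
  (as.integer(seed) + .seed_offsets[[what]]) %% .Machine$integer.max
}

#' Plant a synthetic replication-timing ground truth
#'
#' Builds a genome of alternating early/late RT domains (square wave at
#' `rt_amplitude`, smoothed over `ramp_bins` bins so that boundary bins take
#' intermediate "mid" RT values), assigns A/B compartments by RT sign,
#' plants a transcription track concentrated in A bins, and a catalog of
#' replication initiation sites with RT-coupled latent strength. The chosen
#' `scenario` then transforms RT (and IS strengths) while leaving the base
#' structure untouched, so baseline and perturbed truths generated with the
#' same seed share bins, domains, compartments, transcription and origin
#' positions.
#'
#' @param config A [synth_config()] list.
#' @param scenario One of `"baseline"`, `"mcm_depletion"`, `"rif1_loss"`,
#'   `"rif1_mcm"`.
#' @param seed Integer master seed.
#' @return An object of class `SyntheticTruth` with fields `layout`,
#'   `rt_base`, `rt` (scenario-applied), `domain_label` (`"E"`/`"L"` per
#'   bin), `compartment` (`"A"`/`"B"`), `txn_level` (RPM), `is_catalog`
#'   (data.frame with per-condition latent strengths), `scenario`, `config`,
#'   `seed`.
#' @export
make_truth <- function(config = synth_config(),
                       scenario = c("baseline", "mcm_depletion",
                                    "rif1_loss", "rif1_mcm"),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  layout <- genome_layout(names(config$chrom_lengths),
                          config$chrom_lengths, config$bin_size)
  set.seed(child_seed(seed, "structure"))

  domain_id <- integer(layout$total_bins)
  domain_sign <- numeric(layout$total_bins)
  rt01 <- numeric(layout$total_bins)
  next_id <- 0L
  for (ch in layout$chroms) {
    idx <- chrom_bins(layout, ch)
    n <- length(idx)
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, max(config$min_domain_bins,
                            stats::rpois(1, config$domain_bins)))
    lab <- rep(seq_along(sizes), sizes)[seq_len(n)]
    # alternate E/L; random phase per chromosome
    phase <- sample(c(1, -1), 1)
    sgn <- phase * ifelse(lab %% 2 == 1, 1, -1)
    sq <- sgn
    k <- config$ramp_bins
    if (k > 0) {
      # centered moving average of width 2k+1 creates boundary ramps
      sm <- stats::filter(c(rep(sq[1], k), sq, rep(sq[n], k)),
                          rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
      sq <- as.numeric(sm[(k + 1):(k + n)])
    }
    domain_id[idx] <- next_id + lab
    domain_sign[idx] <- sgn
    rt01[idx] <- sq
    next_id <- next_id + max(lab)
  }
  rt_base <- config$rt_amplitude * rt01
  domain_label <- ifelse(domain_sign > 0, "E", "L")
  compartment <- ifelse(rt_base > 0, "A",
                        ifelse(rt_base < 0, "B",
                               ifelse(domain_sign > 0, "A", "B")))

  # transcription in contiguous blocks (gene clusters) inside A runs, so
  # transcribed and untranscribed neighborhoods are spatially coherent
  txn_level <- stats::runif(layout$total_bins, 0,
                            config$txn_background_rpm)
  txn_level[compartment == "B"] <-
    stats::runif(sum(compartment == "B"), 0, config$txn_background_rpm / 2)
  for (ch in layout$chroms) {
    idx <- chrom_bins(layout, ch)
    r <- rle(compartment[idx] == "A")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- idx[starts[k]:ends[k]]
      p <- 1L
      while (p <= length(run)) {
        len <- 1L + stats::rpois(1, config$txn_block_bins - 1)
        blk <- run[p:min(length(run), p + len - 1L)]
        if (stats::runif(1) < config$txn_fraction) {
          lev <- stats::rlnorm(1, config$txn_meanlog, config$txn_sdlog)
          txn_level[blk] <- lev *
            exp(stats::rnorm(length(blk), 0, config$txn_bin_jitter))
        }
        p <- p + len
      }
    }
  }

  n_origins <- round(config$origins_per_mb * sum(layout$lengths) / 1e6)
  ori_chrom <- sample(layout$chroms, n_origins, replace = TRUE,
                      prob = layout$lengths / sum(layout$lengths))
  ori_pos <- floor(stats::runif(n_origins,
                                config$origin_width / 2,
                                layout$lengths[ori_chrom] -
                                  config$origin_width / 2))
  ori_bin <- bin_at(layout, ori_chrom, ori_pos)
  ord <- order(match(ori_chrom, layout$chroms), ori_pos)
  ori_chrom <- ori_chrom[ord]; ori_pos <- ori_pos[ord]; ori_bin <- ori_bin[ord]
  strength_base <- exp(config$origin_rt_coupling * rt_base[ori_bin] +
                         stats::rnorm(n_origins, 0, config$origin_sdlog))

  # scenario transform (separate child seed: base structure is shared
  # between scenarios generated from the same master seed)
  set.seed(child_seed(seed, "scenario"))
  rt <- rt_base
  strength <- strength_base
  if (scenario %in% c("rif1_loss", "rif1_mcm")) {
    rt[domain_label == "E"] <- rt[domain_label == "E"] - config$rif1_delta_e
    l_domains <- unique(domain_id[domain_label == "L"])
    n_chg <- round(config$rif1_l_frac * length(l_domains))
    chg <- sample(l_domains, n_chg)
    sgn <- rep(c(1, -1), length.out = n_chg)
    for (k in seq_along(chg))
      rt[domain_id == chg[k]] <- rt[domain_id == chg[k]] +
        sgn[k] * config$rif1_l_delta
    n_is <- round(config$rif1_is_frac * n_origins)
    hit <- sample(n_origins, n_is,
                  prob = exp(2 * rt_base[ori_bin]))  # biased to early ISs
    strength[hit] <- strength[hit] * 2^config$rif1_is_log2fc
  }
  if (scenario %in% c("mcm_depletion", "rif1_mcm")) {
    rt <- config$mcm_c * rt
    if (config$txn_rt_delay > 0) {
      d <- config$txn_rt_delay *
        log2(1 + txn_level / 10) / log2(1 + 200 / 10)
      e_dom <- domain_label == "E"
      rt[e_dom] <- rt[e_dom] - d[e_dom]
    }
    strength <- strength *
      2^(-config$mcm_is_effect * rt_base[ori_bin] +
           stats::rnorm(n_origins, 0, 0.1))
  }

  structure(list(
    layout = layout, rt_base = rt_base, rt = rt,
    domain_id = domain_id, domain_label = domain_label,
    compartment = compartment, txn_level = txn_level,
    is_catalog = data.frame(chrom = ori_chrom,
                            start = ori_pos - config$origin_width %/% 2,
                            end = ori_pos + config$origin_width %/% 2,
                            bin = ori_bin,
                            strength_base = strength_base,
                            strength = strength,
                            stringsAsFactors = FALSE),
    scenario = scenario, config = config, seed = as.integer(seed)),
    class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth [%s]: %d bins, %d origins, seed %d\n",
              x$scenario, x$layout$total_bins, nrow(x$is_catalog), x$seed))
  invisible(x)
}

#' Simulate early/late Repli-seq fraction counts
#'
#' The early read fraction of a bin with latent RT `r` is
#' `f = 2^r / (1 + 2^r)` (logistic link), so that the ratio of expected
#' early and late counts is exactly `2^r` and `log2(E/L)` is a consistent
#' estimator of `r`. Counts are Poisson: `E ~ Pois(2 * depth * f)`,
#' `L ~ Pois(2 * depth * (1 - f))`.
#'
#' @param truth A `SyntheticTruth`.
#' @param depth Mean reads per bin per fraction at `r = 0`.
#' @param seed Integer seed (defaults to a fixed child of the truth's seed).
#' @return List with `early` and `late` count `BinnedTrack`s.
#' @export
simulate_repli_counts <- function(truth, depth = 200,
                                  seed = child_seed(truth$seed, "repli")) {
  stopifnot(depth > 0)
  set.seed(seed)
  f <- 2^truth$rt / (1 + 2^truth$rt)
  n <- truth$layout$total_bins
  list(early = binned_track(truth$layout, stats::rpois(n, 2 * depth * f),
                            "counts"),
       late = binned_track(truth$layout, stats::rpois(n, 2 * depth * (1 - f)),
                           "counts"))
}

#' Simulate Hi-C contact matrices with distance decay and compartment plaid
#'
#' Expected counts follow `E_ij = C * |i-j|^(-alpha) * (1 + delta *
#' [same compartment])` for `|i-j| >= 1` (diagonal left at 0), scaled so the
#' mean expected count over off-diagonal pairs equals `mean_pair_reads`;
#' realized counts are Poisson and symmetric. `compartment_mixing` in the
#' truth's config attenuates `delta` multiplicatively, modelling loss of
#' compartmentalization.
#'
#' @param truth A `SyntheticTruth`.
#' @param mean_pair_reads Mean expected count per intra-chromosomal pair.
#' @param delta Plaid strength (same-compartment enrichment).
#' @param alpha Distance-decay exponent.
#' @param seed Integer seed.
#' @return Named list of [contact_matrix()] objects, one per chromosome.
#' @export
simulate_contacts <- function(truth, mean_pair_reads = 3, delta = 0.5,
                              alpha = 1,
                              seed = child_seed(truth$seed, "contacts")) {
  stopifnot(delta >= 0, alpha > 0)
  set.seed(seed)
  delta_eff <- delta * (1 - truth$config$compartment_mixing)
  out <- list()
  for (ch in truth$layout$chroms) {
    idx <- chrom_bins(truth$layout, ch)
    n <- length(idx)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    same <- outer(truth$compartment[idx], truth$compartment[idx], "==")
    e <- ifelse(d >= 1, d^(-alpha) * (1 + delta_eff * same), 0)
    e <- e * mean_pair_reads * (n * (n - 1)) / sum(e)
    m <- matrix(0, n, n)
    ut <- upper.tri(m)
    m[ut] <- stats::rpois(sum(ut), e[ut])
    m <- m + t(m)
    out[[ch]] <- contact_matrix(truth$layout, ch, m)
  }
  out
}

#' Simulate a nascent-transcription (PRO-seq-like) density track
#'
#' Per-bin counts are Poisson around `txn_level * exposure` and rescaled to
#' the RPM-like `txn_level` scale.
#'
#' @param truth A `SyntheticTruth`.
#' @param exposure Counts per RPM unit.
#' @param seed Integer seed.
#' @return A `BinnedTrack` with units `"RPM"`.
#' @export
simulate_proseq <- function(truth, exposure = 2,
                            seed = child_seed(truth$seed, "proseq")) {
  set.seed(seed)
  n <- truth$layout$total_bins
  counts <- stats::rpois(n, truth$txn_level * exposure)
  binned_track(truth$layout, counts / exposure, "RPM")
}

#' Simulate replicate initiation-site peak sets with read densities
#'
#' Each origin of the truth catalog yields, per replicate, a peak interval
#' whose position is jittered by at most `jitter_bp` and whose read count is
#' Gamma-Poisson (negative binomial) around `reads_per_unit` times the
#' condition's latent strength. Densities are RPM within the replicate.
#'
#' @param truth A `SyntheticTruth` (its `scenario` decides which latent
#'   strength column is sampled).
#' @param n_reps Number of replicates (>= 2).
#' @param jitter_bp Maximal positional jitter per replicate.
#' @param overdispersion Gamma overdispersion of counts (0 = pure Poisson).
#' @param reads_per_unit Expected reads for an origin of strength 1.
#' @param seed Integer seed.
#' @return List of replicate `GRanges`, each carrying `count` and `density`
#'   (RPM) metadata columns.
#' @export
simulate_is_replicates <- function(truth, n_reps = 2, jitter_bp = 50,
                                   overdispersion = 0.05,
                                   reads_per_unit = 50,
                                   seed = child_seed(truth$seed, "is")) {
  stopifnot(n_reps >= 2)
  set.seed(seed)
  cat_ <- truth$is_catalog
  w <- cat_$end - cat_$start
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    shift <- if (jitter_bp > 0)
      round(stats::runif(nrow(cat_), -jitter_bp, jitter_bp)) else 0L
    start <- pmax(0, cat_$start + shift)
    mu <- reads_per_unit * cat_$strength
    counts <- if (overdispersion > 0)
      stats::rnbinom(nrow(cat_), mu = mu, size = 1 / overdispersion)
    else stats::rpois(nrow(cat_), mu)
    gr <- GenomicRanges::GRanges(
      seqnames = cat_$chrom,
      ranges = IRanges::IRanges(start = start + 1L, width = w),
      count = counts,
      density = counts * 1e6 / max(1, sum(counts)))
    GenomeInfoDb::seqlevels(gr) <- truth$layout$chroms
    GenomeInfoDb::seqlengths(gr) <- truth$layout$lengths
    reps[[r]] <- normalize_intervals(gr)
  }
  names(reps) <- paste0("rep", seq_len(n_reps))
  reps
}

#' Assemble a full synthetic dataset for one condition
#'
#' Convenience wrapper running all per-assay simulators from one truth.
#'
#' @param truth A `SyntheticTruth`.
#' @param depth Repli-seq mean reads per bin.
#' @param mean_pair_reads Hi-C mean expected reads per pair.
#' @param delta,alpha Hi-C plaid strength and decay exponent.
#' @param n_reps Initiation-site replicates.
#' @return List with `truth`, `early`, `late`, `contacts`, `proseq`,
#'   `is_replicates`.
#' @export
simulate_dataset <- function(truth, depth = 200, mean_pair_reads = 3,
                             delta = 0.5, alpha = 1, n_reps = 2) {
  counts <- simulate_repli_counts(truth, depth)
  list(truth = truth,
       early = counts$early, late = counts$late,
       contacts = simulate_contacts(truth, mean_pair_reads, delta, alpha),
       proseq = simulate_proseq(truth),
       is_replicates = simulate_is_replicates(truth, n_reps))
}
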