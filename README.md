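# replitimer

Replication-timing (RT) analysis for two-fraction Repli-seq experiments,
with the surrounding genomics a B-cell RT study needs: Hi-C A/B
compartments, replication initiation sites, and transcription-stratified
RT shifts. The package is aimed at genomicists who have binned signal
tracks (bedGraph), interval sets (BED) and per-chromosome contact
matrices, and who want the analysis chain — not read processing — in
reproducible, tested R.

## What it computes

The central quantity is per-bin replication timing,

```
RT_i = log2( (E_i + p) / (L_i + p) )
```

the pseudocounted log2 ratio of early- over late-S-phase read densities
in fixed 20 kb bins, loess-smoothed over a 300 kb genomic span (tricube
local linear regression with a fixed base-pair window). Around it:

* **RT states** — a 3-state Gaussian hidden Markov model (Baum–Welch +
  Viterbi, chains reset at chromosome boundaries and coverage gaps)
  labels bins early (E), mid (M) or late (L); M bins are split at
  RT = 0 into E-like and L-like, giving the four-class segmentation used
  for cross-condition shift analysis.
* **Compartments** — Sinkhorn balancing of contact matrices,
  observed/expected normalization, the leading eigenvector (PC1) of the
  O/E correlation matrix per chromosome with reference-based sign
  orientation, and 50-group saddle plots of long-range (>2 Mb) contact
  enrichment plus fold-change saddles.
* **Initiation sites** — replicate consensus by interval intersection,
  clustering into initiation zones at the median interpeak distance,
  RPM quantification, 1.5-fold up/unchanged/down classification, and
  fold-change quintiles with per-class RT profiles.
* **Stratified RT** — transcribed early bins (≥10 RPM) split into RPM
  tertiles (High/Medium/Low) plus Untranscribed, with RT distribution
  shifts measured as distances between KDE modes.
* **Meta-signal** — summit-centered 4 kb / 50 bp signal matrices,
  k-means site clustering ordered by focal signal, peak-vs-domain
  filtering and TSS/gene-body/intergenic annotation.
* **Synthetic data** — a generator planting RT domains, a compartment
  plaid, blocky transcription and RT-coupled origin strengths, with
  perturbation scenarios (`mcm_depletion`: RT compression toward 0;
  `rif1_loss`: delay of early domains with mixed late behavior), so the
  whole chain is testable against known truth.

## Worked example

Simulate a wild-type and a RIF1-loss condition over a 60 Mb genome,
estimate RT from sampled counts, segment the wild type, and ask how each
reference RT class shifts in the perturbation:

```r
library(replitimer)

cfg      <- synth_config(chrom_lengths = c(chr1 = 40e6, chr2 = 20e6))
truth_wt <- make_truth(cfg, "baseline",  seed = 42)
truth_ko <- make_truth(cfg, "rif1_loss", seed = 42)

rt_of <- function(truth) {
  counts <- simulate_repli_counts(truth, depth = 200)
  loess_smooth(compute_rt(counts$early, counts$late, pseudocount = 1))
}
rt_wt <- rt_of(truth_wt)
rt_ko <- rt_of(truth_ko)

seg <- segment_rt(rt_wt)
seg
#> RTStateSegmentation: E=1129 E-like=395 L-like=384 L=1092

shift <- state_shift_summary(seg, list(wt = rt_wt, ko = rt_ko))
subset(shift$summary, class %in% c("E", "L"))
#>   class condition    n  mean median  mode
#> 1     E        wt 1129  1.48   1.48  1.49
#> 2     E        ko 1129  0.68   0.69  0.69
#> 7     L        wt 1092 -1.48  -1.49 -1.50
#> 8     L        ko 1092 -1.47  -1.48 -1.50
```

The E-class mode moves from 1.49 to 0.69 — recovering the planted 0.8
log2-unit delay of early domains — while the L class is essentially
unchanged, the hallmark of this scenario. `run_pipeline(pipeline_config(),
out_dir)` runs the same chain end to end (RT, states, compartments,
saddles, IS table, stratification) and writes a manifest with per-file
md5 digests; a thin CLI over the same functions lives at
`system.file("cli/replitimer.R", package = "replitimer")` with
subcommands `simulate`, `rt`, `states`, `compartments`, `origins`,
`stratify` and `pipeline`.

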