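---
title: "Replication-timing analysis with replitimer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication-timing analysis with replitimer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replitimer)
```

# Scope

`replitimer` implements the computational core of a two-fraction Repli-seq
study of replication timing (RT) in mammalian cells: binned log2(E/L) RT
profiling, hidden-Markov-model segmentation of RT into early/mid/late
states, Hi-C A/B compartment and saddle analysis, replication
initiation-site (IS) classification from SNS-seq-style peak sets, and
transcription-stratified RT shift analysis. Everything runs end to end on a
bundled synthetic-data generator with known ground truth, so each stage can
be validated by parameter recovery rather than by eye.

This vignette records the models, the parameters that matter, and the
design decisions taken where the underlying methods left genuine freedom.

# The RT profile

RT is quantified per fixed genomic bin (default 20 kb) as the log2 ratio of
early- over late-fraction read density:

$$\mathrm{RT}_i = \log_2\frac{E_i + p}{L_i + p},$$

with a pseudocount $p$ (default 1) guarding empty bins. Positive values
replicate early, negative late. Bins missing in either fraction are
missing, never silently zero.

**Library normalization.** `counts_to_cpm()` rescales each fraction to
counts-per-million. Because the two fractions are normalized independently,
the resulting RT track is only defined up to a global additive constant
$\log_2(T_L/T_E)$ (the ratio of library totals). For real data with
arbitrary sequencing depths this constant is unidentifiable and CPM is the
right first step; comparisons across conditions can additionally use the
optional `quantile_normalize_tracks()` post-step (sort-and-average
reference mapping), which is off by default. The synthetic generator, by
contrast, samples both fractions at one matched exposure
($E_i \sim \mathrm{Pois}(2 d f_i)$, $L_i \sim \mathrm{Pois}(2 d (1-f_i))$),
so the raw count ratio is already calibrated across conditions; the
bundled pipeline therefore computes RT from counts directly, and this is
the estimator whose cross-condition shifts are compared with the planted
truth in the tests. Applying CPM there would re-introduce the
$\log_2(T_L/T_E)$ offset (about +0.35 under the early-delay scenario) and
shift every class distribution by a constant.

**Smoothing.** `loess_smooth()` is a tricube-weighted local *linear*
regression whose window is a fixed genomic distance — `span_bp/2` (default
150 kb, i.e. 15 bins) on each side of the bin center — rather than a
fraction of data points. The span is stated in base pairs because genomic
distance, not rank, is the physically meaningful scale; windows never cross
chromosome boundaries, missing bins neither contribute nor get imputed, and
constant and exactly linear tracks are reproduced to numerical precision
(both properties are tested against a per-point `lm()` oracle).
Chromosomes with fewer than 3 defined bins are passed through unchanged
with a warning.

# RT state segmentation

A univariate Gaussian HMM with three states is fitted to the RT track by
Baum–Welch EM. Chains restart from the initial distribution at every
chromosome start and after every gap of missing bins, so no state
information crosses unmappable regions. Initialization is deterministic —
state means at the 25th/50th/75th RT percentiles, variances at the global
variance, 0.9 self-transitions, uniform initial distribution — so a fit is
reproducible without a seed; random restarts are available (`restarts > 0`)
and on well-separated data converge to the same labeling. Variances are
floored at 1e-8 and flagged if the floor binds. Convergence is declared
when the relative log-likelihood change falls below `tol` (default 1e-6,
maximum 200 iterations); the log-likelihood trace is retained and its
monotonicity asserted in the tests.

Decoding is per-chromosome Viterbi (verified against exhaustive
max-product enumeration on short chains). States are then ranked by fitted
mean: highest = E, lowest = L, middle = M; ties in means are broken by the
smaller variance and flagged. Every M bin is split by the sign of its RT
value into E-like (RT > 0) or L-like (RT < 0); RT exactly 0 goes to E-like
— the split is stated with strict inequalities only, so the boundary needs
an explicit tie rule, and assigning 0 to the early side keeps the
"non-negative RT is early-like" reading consistent.

Cross-condition comparisons (`state_shift_summary()`) always take the
*reference* condition's segmentation and collect the RT values of the same
bins in every other condition, summarizing each distribution by mean,
median and KDE mode. Fitting the HMM per condition is possible but not the
default, since the reference-state projection is what makes shifts
interpretable bin-by-bin.

# Hi-C compartments

Contact matrices are balanced by Sinkhorn–Knopp iteration to uniform row
sums (relative tolerance 1e-8, max 1000 iterations). This targets the same
doubly-stochastic fixed point as Knight–Ruiz balancing with a simpler
scheme; non-convergence is an error naming the worst row. Bins with a zero
marginal or fewer than `mask_min_nonzero` (default 10) nonzero entries are
masked first.

Observed/expected (O/E) divides each balanced entry by the mean balanced
value at its genomic separation; by construction every diagonal of O/E
with a defined expectation has mean 1 (asserted to floating tolerance).
The compartment eigenvector is computed per chromosome as the leading
eigenvector of the Pearson correlation matrix of O/E columns, smoothed by
a centered rolling mean over 200 kb, and then sign-oriented so that it
correlates positively with a reference track (gene density where
available; the planted RT track in the synthetic pipeline). Smoothing
precedes orientation so that the sign decision is made on the track users
actually see. If the reference correlation is below 0.05 in magnitude the
sign is left as computed with a loud warning.

Saddle analysis ranks all usable bins genome-wide by PC1 and splits them
into `n_groups` (default 50) rank-quantile groups — group 1 most-B,
group 50 most-A, ties broken by bin index so group sizes differ by at most
one. Cell $(g,h)$ is the pooled mean O/E over intra-chromosomal unmasked
pairs separated by more than 2 Mb, aggregated across chromosomes.
Fold-change saddles are elementwise ratios with missing-value propagation.
At a few hundred bins per chromosome, single extreme cells of a 50×50
saddle hold very few (sometimes zero) qualifying pairs, so compartment
strength is summarized over 5×5 corner blocks (top/bottom decile), the
standard readout.

# Initiation sites

Consensus peaks are the maximal regions covered by a peak in *every*
replicate (interval intersection). Consensus peaks are chained into
initiation zones whenever the boundary gap (end of one peak to start of
the next) is at most the genome-wide **median interpeak distance** of the
set (or an explicit `gap_bp`); chains of at least 2 peaks become zones and
peaks outside any zone are dropped. The boundary-gap convention is a
documented choice — distance between peak midpoints would be an equally
defensible reading — and the clustering is verified against a
transitive-closure brute-force oracle.

Per-condition IS densities are RPM-normalized read counts. Fold-change
classification uses $fc = (d_a + p)/(d_b + p)$ with $p = 0.01$ RPM
(avoiding division by zero on sparse sites) and the 1.5-fold rule: up if
$fc \ge 1.5$, down if $fc \le 1/1.5$. Quintile classes rank sites by log2
fold-change ascending (ties broken by genomic position) and partition the
ranks with a ceiling rule, so class sizes differ by at most one and
class 1 holds the most downregulated sites. When an upstream analysis
filters the table before quintiling, the classes refer to whatever table
is supplied; the partition itself makes no filtering assumptions.

# Transcription-stratified RT

Early (E-state) bins are split by nascent-transcription density into
Untranscribed (< 10 RPM) and rank-based tertiles High/Medium/Low of the
remaining bins. The tertiles are equal-count by construction; the printed
RPM ranges of each group are data-dependent *outputs*, not inputs.
Distribution shifts are measured as the distance between KDE modes:
Gaussian kernels with Silverman's rule-of-thumb bandwidth, both samples
evaluated on one shared 512-point grid spanning the pooled range, mode =
grid argmax. Near-tied secondary peaks (within 1% of the maximum density)
set an ambiguity flag rather than failing. The mode is preferred over the
mean here because the class distributions are skewed with heavy shoulders,
and the mode tracks the bulk of bins the way the corresponding density
plots are read.

# Summit-centered matrices and site clustering

`site_matrix()` extracts, for each site, the signal in `window_bp/bin_bp`
columns centered on the summit (80 columns at 4 kb / 50 bp), setting
out-of-chromosome and missing values to 0. Summits are the leftmost
position achieving the maximal pile-up (ties go left). For k-means
clustering the per-track matrices are z-scored over all entries of that
track before concatenation, so tracks with large dynamic range cannot
dominate the distance; `standardize = FALSE` restores raw-matrix behavior.
Clusters are renumbered by descending mean focal-track signal and rows
ordered by descending focal signal within cluster — the conventional
heatmap layout. TSS annotation uses a ±1 kb promoter window (precedence
TSS > gene body > intergenic).

# The synthetic-data generator

`make_truth()` plants, per chromosome, alternating early/late RT domains
(mean size 50 bins = 1 Mb, Poisson-distributed, minimum 10) at ±1.5 log2
units, with a 5-bin moving-average ramp at boundaries so that genuine
mid-RT bins exist for the M state. Compartments are A where planted RT is
positive, B where negative. Transcription is planted in contiguous blocks
(mean 10 bins ≈ 200 kb, log-normal block level around 80 RPM, mild per-bin
jitter) covering half of the A compartment — blocks, not scattered bins,
because gene clusters are spatially coherent in real genomes and because
any per-bin signal uncorrelated over 20 kb would be averaged away by
300 kb smoothing. Initiation sites (20 per Mb, 300 bp) get log-normal
latent strengths coupled to RT (`exp(0.6·RT)` times noise), making strong
origins early-replicating.

Sampling models are deliberately minimal: Poisson counts with a logistic
link $f = 2^r/(1+2^r)$ for Repli-seq (so $E[E]/E[L] = 2^r$ exactly and
log2(E/L) is a consistent estimator of the planted $r$); Poisson contacts
with power-law distance decay $d^{-\alpha}$ ($\alpha = 1$, the classical
fractal-globule scaling) and a multiplicative same-compartment plaid
$(1+\delta)$, $\delta = 0.5$; Gamma–Poisson IS replicate counts with
optional overdispersion (default 0.05) and ≤50 bp positional jitter.

Two perturbation regimes transform the planted RT while leaving the base
structure untouched (scenarios generated from one master seed share
domains, transcription and origin positions):

* **`mcm_depletion`** — genome-wide compression `rt ← 0.3·rt`, plus a
  log2 IS fold-change of `−0.45·RT` (early origins down, late origins up),
  sized so that roughly 40–50% of ISs change more than 1.5-fold. An
  optional transcription-coupled extra delay (`txn_rt_delay`, default 0,
  ~1 log2 unit at high transcription when enabled) models the preferential
  delay of highly transcribed early bins; it is off by default so the
  plain scenario is a pure compression.
* **`rif1_loss`** — every early-domain bin delayed by 0.8; 30% of late
  domains perturbed, half advanced and half delayed by 0.4, the rest
  untouched (so the planted late-class mode shift is 0, matching the
  mixed late behavior the scenario emulates); 5% of ISs, biased to early
  ones, halved in strength.

One master seed expands into fixed-offset child seeds per assay, so any
assay can be regenerated independently and identical configurations give
byte-identical serialized datasets.

**What the generator does not emulate** — and therefore what passing
recovery tests do and do not show about real data: mappability and GC
bias, copy-number variation, replicate batch effects, read-level artifacts
(duplicates, multimappers), S-phase substructure beyond two fractions,
inter-chromosomal contacts, real gene annotation (TSS/gene-body calls in
the meta module are tested on constructed annotations), and
cell-to-cell heterogeneity. Recovery under this generator demonstrates
correctness of the estimators and the pipeline plumbing, not robustness to
every artifact of real sequencing data.

# Problem sizes and determinism

The test suite and the acceptance script exercise: RT recovery on 5,000
bins at 200 reads/bin; HMM segmentation on 2,000 bins (state means
−1.5/0/+1.5, σ = 0.35); scenario recovery on 3,000 bins; compartment
recovery on a 500-bin chromosome at ≥2 mean reads per pair; zone
clustering against the brute-force oracle on 200 random sets of up to 50
peaks; k-means archetype recovery on 300 sites; and a full pipeline run on
a two-chromosome 20 Mb genome, executed twice to assert byte-identical
outputs. These sizes were chosen as the smallest at which the planted
effects are comfortably identifiable, keeping a full run on one CPU in the
low minutes.

# Known limitations

* The Gaussian emission model is fitted genome-wide; strongly
  non-stationary RT variance between chromosomes would argue for the
  per-chromosome fitting flag.
* The saddle aggregates pooled pair means across chromosomes; chromosomes
  with few usable bins contribute few pairs rather than being reweighted.
* `compute_rt` does not model count overdispersion; with the optional NB
  noise knob in the generator the estimator stays unbiased but its
  variance is underestimated by the Poisson-based intuition.
* Interval strand is carried through IO but ignored by all computations;
  all analyses here are unstranded.
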