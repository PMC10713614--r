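#' Default end-to-end pipeline configuration
#'
#' Parameters for the synthetic-to-results chain run by [run_pipeline()]:
#' a small bundled genome, one perturbation scenario, and the default
#' analysis parameters of every stage. Unknown keys are rejected.
#'
#' @param ... Named overrides; `synth` may be a list of [synth_config()]
#'   overrides.
#' @return Named configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    scenario = "rif1_loss",
    chrom_lengths = c(chrS1 = 12e6, chrS2 = 8e6),
    bin_size = 20000,
    depth = 200,
    mean_pair_reads = 3,
    delta = 0.5,
    alpha = 1,
    n_reps = 2,
    pseudocount = 1,
    span_bp = 300000,
    n_states = 3,
    n_groups = 50,
    min_sep_bp = 2e6,
    smooth_bp = 200000,
    mask_min_nonzero = 10,
    min_rpm = 10,
    fc_threshold = 1.5,
    fc_pseudocount = 0.01,
    quantile_normalize = FALSE,
    synth = list())
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys are validated against [pipeline_config()]; unknown keys are
#' rejected with the key named.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$chrom_lengths))
    raw$chrom_lengths <- unlist(raw$chrom_lengths)
  do.call(pipeline_config, raw)
}

.write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  path
}

#' Run the full synthetic-to-results pipeline
#'
#' Generates paired baseline/perturbed synthetic datasets, computes RT
#' profiles, HMM state segmentation and cross-condition shift summaries,
#' Hi-C compartment PC1, saddles and fold-change saddles, initiation-site
#' consensus/zones/fold-change classes with per-class RT, and the
#' transcription-stratified RT analysis. All stage outputs are written as
#' plain-text files under `out_dir` and a machine-readable manifest
#' (parameters, seed, per-file md5 digests) is written as
#' `manifest.json`. The run is deterministic given the configuration seed.
#'
#' @param config A [pipeline_config()] list (or path handled by
#'   [load_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(synth_config,
                  c(list(chrom_lengths = config$chrom_lengths,
                         bin_size = config$bin_size), config$synth))

  truth_ref <- make_truth(scfg, "baseline", config$seed)
  truth_alt <- make_truth(scfg, config$scenario, config$seed)
  ds_ref <- simulate_dataset(truth_ref, config$depth,
                             config$mean_pair_reads, config$delta,
                             config$alpha, config$n_reps)
  ds_alt <- simulate_dataset(truth_alt, config$depth,
                             config$mean_pair_reads, config$delta,
                             config$alpha, config$n_reps)

  # the simulated fraction libraries share a matched exposure, so the raw
  # count ratio is calibrated across conditions; CPM would re-introduce a
  # global offset log2(total_late/total_early) under asymmetric perturbations
  rt_of <- function(ds) {
    loess_smooth(compute_rt(ds$early, ds$late, config$pseudocount),
                 config$span_bp)
  }
  rt_ref <- rt_of(ds_ref)
  rt_alt <- rt_of(ds_alt)
  if (isTRUE(config$quantile_normalize)) {
    qn <- quantile_normalize_tracks(list(ref = rt_ref, alt = rt_alt))
    rt_ref <- qn$ref; rt_alt <- qn$alt
  }
  files <- character(0)
  files["rt_reference"] <- write_bedgraph(rt_ref,
                                          file.path(out_dir, "rt_reference.bedGraph"))
  files["rt_perturbed"] <- write_bedgraph(rt_alt,
                                          file.path(out_dir, "rt_perturbed.bedGraph"))

  seg <- segment_rt(rt_ref, config$n_states, seed = config$seed)
  files["states"] <- write_intervals(segmentation_to_intervals(seg),
                                     file.path(out_dir, "rt_states.bed"))
  files["state_params"] <- .write_tsv(
    data.frame(state = seq_len(seg$params$n_states),
               mean = seg$params$means, var = seg$params$vars),
    file.path(out_dir, "rt_state_params.tsv"))
  shift <- state_shift_summary(seg, list(reference = rt_ref,
                                         perturbed = rt_alt))
  files["state_shift"] <- .write_tsv(shift$summary,
                                     file.path(out_dir, "rt_state_shift.tsv"))

  comp <- function(contacts, pc1_ref_track) {
    oe <- lapply(contacts, function(cm)
      observed_expected(balance_matrix(cm, config$mask_min_nonzero)))
    pc1 <- compartment_pc1(oe, pc1_ref_track, config$smooth_bp)
    list(oe = oe, pc1 = pc1)
  }
  c_ref <- comp(ds_ref$contacts, rt_ref)
  c_alt <- comp(ds_alt$contacts, rt_ref)
  files["pc1_reference"] <- write_bedgraph(
    c_ref$pc1, file.path(out_dir, "pc1_reference.bedGraph"))
  files["pc1_perturbed"] <- write_bedgraph(
    c_alt$pc1, file.path(out_dir, "pc1_perturbed.bedGraph"))
  s_ref <- saddle(c_ref$oe, c_ref$pc1, config$n_groups, config$min_sep_bp)
  s_alt <- saddle(c_alt$oe, c_ref$pc1, config$n_groups, config$min_sep_bp)
  files["saddle_reference"] <- .write_tsv(
    as.data.frame(s_ref$matrix), file.path(out_dir, "saddle_reference.tsv"),
    col.names = FALSE)
  files["saddle_perturbed"] <- .write_tsv(
    as.data.frame(s_alt$matrix), file.path(out_dir, "saddle_perturbed.tsv"),
    col.names = FALSE)
  files["saddle_fc"] <- .write_tsv(
    as.data.frame(saddle_fold_change(s_alt, s_ref)$matrix),
    file.path(out_dir, "saddle_fold_change.tsv"), col.names = FALSE)
  joint <- pc1_rt_joint(c_ref$pc1, rt_ref)
  files["quadrants"] <- .write_tsv(
    data.frame(quadrant = names(joint$quadrant_fractions),
               fraction = as.numeric(joint$quadrant_fractions)),
    file.path(out_dir, "pc1_rt_quadrants.tsv"))

  origin_stage <- function(ds) {
    cons <- consensus_peaks(ds$is_replicates)
    zones <- cluster_initiation_zones(cons)
    zones
  }
  z_ref <- origin_stage(ds_ref)
  z_alt <- origin_stage(ds_alt)
  merged <- normalize_intervals(GenomicRanges::reduce(
    c(GenomicRanges::granges(z_ref$retained),
      GenomicRanges::granges(z_alt$retained))))
  count_cond <- function(ds) {
    Reduce(`+`, lapply(ds$is_replicates, function(r)
      count_reads_in_peaks(merged, r)))
  }
  tab <- quantify_is(merged, list(reference = count_cond(ds_ref),
                                  perturbed = count_cond(ds_alt)))
  tab <- classify_fold_change(tab, "perturbed", "reference",
                              config$fc_threshold, config$fc_pseudocount)
  tab <- quintile_classes(tab)
  files["is_table"] <- .write_tsv(as.data.frame(tab),
                                  file.path(out_dir, "is_table.tsv"))
  files["zones"] <- write_intervals(z_ref$zones,
                                    file.path(out_dir, "initiation_zones.bed"))
  files["is_fractions"] <- .write_tsv(
    data.frame(class = names(attr(tab, "fractions")),
               fraction = as.numeric(attr(tab, "fractions"))),
    file.path(out_dir, "is_change_fractions.tsv"))
  rt_classes <- class_rt_profile(tab, list(reference = rt_ref,
                                           perturbed = rt_alt))
  files["is_class_rt"] <- .write_tsv(rt_classes$medians,
                                     file.path(out_dir, "is_class_rt.tsv"))

  e_bins <- which(!is.na(seg$class) & seg$class == "E")
  strat_files <- tryCatch({
    grouping <- transcription_groups(e_bins, ds_ref$proseq, config$min_rpm)
    dist <- group_rt_distributions(grouping,
                                   list(reference = rt_ref,
                                        perturbed = rt_alt))
    a <- .write_tsv(grouping$boundaries,
                    file.path(out_dir, "txn_group_boundaries.tsv"))
    b <- .write_tsv(dist$modes, file.path(out_dir, "txn_group_rt_modes.tsv"))
    c(txn_boundaries = a, txn_modes = b)
  }, error = function(e) {
    warning("stratification stage skipped: ", conditionMessage(e))
    character(0)
  })
  files <- c(files, strat_files)

  manifest <- list(
    package = "replitimer",
    version = as.character(utils::packageVersion("replitimer")),
    seed = config$seed,
    scenario = config$scenario,
    parameters = config[setdiff(names(config), "synth")],
    synth = scfg,
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
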