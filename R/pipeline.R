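#' Default pipeline configuration
#'
#' Every fixed constant of the analysis lives here: calling thresholds
#' (0.1 disruption, 0.2 SCNA call, 0.5 focal cutoff), purity floor 0.2,
#' SVM bandwidth sigma = 1, permutation counts and the master seed.
#' `run_pipeline()` merges a user config (YAML file or list) over these
#' defaults and rejects unknown keys.
#'
#' @return nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "results",
    simulate = list(enabled = TRUE, n_east = 100L, n_west = 100L,
                    cin_prevalence_east = 0.51, cin_prevalence_west = 0.59,
                    arm_rate_cin = 0.3, arm_rate_noncin = 0.02,
                    focal_amplitude = 1, marker_noise_sd = 0.05,
                    n_markers = 10000L, n_snps = 2000L, fst = 0.1,
                    cin_labeled_fraction = 0.5),
    inputs = list(seg = NULL, genotypes = NULL, purity = NULL, metadata = NULL,
                  arms = NULL, regions = NULL, genes = NULL),
    correction = list(purity_floor = 0.2),
    calling = list(call_threshold = 0.2, disruption_threshold = 0.1,
                   focal_cutoff = 0.5),
    ancestry = list(enabled = TRUE, n_components = 10L, outlier_k = 3),
    cin = list(sigma = 1, cost_grid = c(0.1, 1, 10, 100)),
    recurrence = list(enabled = FALSE, n_perm = 1000L, alpha = 0.05,
                      noise_floor = 0.1),
    compare = list(n_perm = 49000L, n_bins = 4L, alpha = 0.05,
                   covariate = "focal_disruption")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop_fmt("config validation error: unknown key '%s%s'", path, k)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop_fmt("config validation error: '%s%s' must be a map", path, k)
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the full comparative SCNA pipeline
#'
#' Stages, in dependency order: simulate (or ingest) - ISAR correction -
#' disruption scoring - ancestry PCA and two-cluster assignment - CIN
#' SVM (trained on the labeled subset, predicting the rest) - recurrent
#' regions (G-score scan, or externally supplied region BED) - stratified
#' cohort comparison. All outputs are plain text under `out_dir`,
#' accompanied by `manifest.json` recording the merged configuration,
#' derived per-stage seeds, per-stage sample counts and md5 checksums of
#' every output file; rerunning with the same config is byte-identical.
#'
#' @param config path to a YAML config file, or a nested list (see
#'   [default_pipeline_config()] for keys).
#' @return invisibly, a list with the main in-memory results (`results`,
#'   `regions`, `ancestry`, `cin_calls`, `disruption`, `manifest`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  seed <- as.integer(cfg$seed)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()
  note <- function(stage, n) log_counts[[stage]] <<- n

  # --- inputs -------------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    sim_args <- cfg$simulate
    sim_args$enabled <- NULL
    sim_args$seed <- derive_seed(seed, 1L)
    params <- do.call(simulation_params, sim_args)
    sim <- simulate_cohort(params)
    profiles <- sim$profiles; genotypes <- sim$genotypes
    purity <- sim$purity; metadata <- sim$metadata
    arms <- sim$arms; truth <- sim$truth
    regions_in <- sim$regions
    write_seg(profiles, file.path(out_dir, "profiles.seg"))
    write_genotypes(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_purity_table(purity, file.path(out_dir, "purity.tsv"))
    write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
    write_metadata2 <- utils::write.table
    write_metadata2(truth$samples, file.path(out_dir, "truth_samples.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    inp <- cfg$inputs
    for (need in c("seg", "purity", "metadata", "arms"))
      if (is.null(inp[[need]]))
        stop_fmt("config validation error: simulate disabled but inputs.%s missing", need)
    profiles <- read_seg(inp$seg)
    purity <- read_purity_table(inp$purity)
    metadata <- read_metadata(inp$metadata)
    arms <- read_arm_definitions(inp$arms)
    genotypes <- if (!is.null(inp$genotypes)) read_genotypes(inp$genotypes) else NULL
    regions_in <- if (!is.null(inp$regions)) read_regions_bed(inp$regions) else NULL
    truth <- NULL
  }
  arms <- autosomal_arms(arms)
  note("input", length(unique(profiles$sample)))

  # --- correction and disruption -----------------------------------------
  corrected <- isar_correct(profiles, purity,
                            purity_floor = cfg$correction$purity_floor)
  note("corrected", length(unique(corrected$sample)))
  disruption <- genomic_disruption(corrected, arms,
                                   threshold = cfg$calling$disruption_threshold,
                                   focal_cutoff = cfg$calling$focal_cutoff)
  utils::write.table(disruption, file.path(out_dir, "disruption.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- ancestry -----------------------------------------------------------
  ancestry <- NULL
  if (isTRUE(cfg$ancestry$enabled) && !is.null(genotypes)) {
    pca <- eigenstrat_pca(genotypes, n_components = cfg$ancestry$n_components)
    anchors_df <- metadata[metadata$cohort_label %in% c("EAST", "WEST"), ]
    anchors <- stats::setNames(anchors_df$cohort_label, anchors_df$sample_id)
    ancestry <- classify_two_clusters(pca, outlier_k = cfg$ancestry$outlier_k,
                                      anchors = if (length(anchors)) anchors else NULL)
    utils::write.table(ancestry, file.path(out_dir, "ancestry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("ancestry_classified", sum(ancestry$label != "UNCLASSIFIED"))
    cohort_used <- ancestry$label[match(metadata$sample_id, ancestry$sample_id)]
    metadata$cohort_label <- ifelse(is.na(cohort_used), metadata$cohort_label,
                                    cohort_used)
  }

  # --- CIN classification -------------------------------------------------
  feats <- arm_feature_matrix(corrected, arms)
  labeled <- metadata$sample_id[metadata$subtype_label != "UNKNOWN"]
  labeled <- intersect(labeled, rownames(feats))
  if (length(labeled) < 4L ||
      length(unique(metadata$subtype_label[match(labeled, metadata$sample_id)])) < 2L)
    stop_fmt("pipeline: need labeled CIN and NON_CIN samples to train the classifier")
  model <- train_cin_svm(feats[labeled, , drop = FALSE],
                         metadata$subtype_label[match(labeled, metadata$sample_id)],
                         sigma = cfg$cin$sigma, cost_grid = cfg$cin$cost_grid,
                         seed = derive_seed(seed, 2L))
  cin_calls <- predict_cin(model, feats)
  utils::write.table(
    data.frame(sample_id = names(cin_calls), cin_call = unname(cin_calls)),
    file.path(out_dir, "cin_calls.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_cin_model(model, file.path(out_dir, "cin_model.json"))
  note("cin_positive", sum(cin_calls == "CIN"))

  # --- regions ------------------------------------------------------------
  grid <- marker_grid(arms, cfg$simulate$n_markers %||% 10000L)
  if (isTRUE(cfg$recurrence$enabled)) {
    genes <- if (!is.null(cfg$inputs$genes)) read_gene_bed(cfg$inputs$genes) else NULL
    regions <- detect_recurrent_regions(corrected, arms, grid,
                                        n_perm = cfg$recurrence$n_perm,
                                        seed = derive_seed(seed, 3L),
                                        alpha = cfg$recurrence$alpha,
                                        noise_floor = cfg$recurrence$noise_floor,
                                        focal_cutoff = cfg$calling$focal_cutoff,
                                        genes = genes)
  } else if (!is.null(regions_in)) {
    regions <- regions_in
  } else {
    stop_fmt("pipeline: recurrence disabled and no regions supplied")
  }
  if (nrow(regions) > 0L)
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
  note("regions", nrow(regions))

  # --- cohort comparison --------------------------------------------------
  em <- build_event_matrix(corrected, arms, regions,
                           call_threshold = cfg$calling$call_threshold,
                           focal_cutoff = cfg$calling$focal_cutoff)
  tested <- metadata[metadata$cohort_label %in% c("EAST", "WEST") &
                       metadata$sample_id %in% rownames(em$matrix), ]
  strata <- assign_strata(tested, disruption, n_bins = cfg$compare$n_bins,
                          cin_labels = cin_calls,
                          covariate = cfg$compare$covariate)
  results <- compare_cohorts(em, tested, strata, n_perm = cfg$compare$n_perm,
                             seed = derive_seed(seed, 4L),
                             alpha = cfg$compare$alpha)
  write_results_table(results, file.path(out_dir, "results.tsv"))
  note("tested", nrow(tested))

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "scnacompare",
    config = cfg,
    derived_seeds = list(simulate = derive_seed(seed, 1L),
                         cin = derive_seed(seed, 2L),
                         recurrence = derive_seed(seed, 3L),
                         compare = derive_seed(seed, 4L)),
    stage_counts = log_counts,
    checksums = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$checksums) <- files
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(list(results = results, regions = regions, ancestry = ancestry,
                 cin_calls = cin_calls, disruption = disruption,
                 truth = truth, manifest = manifest))
}
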