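#' Pipeline configuration
#'
#' Builds the nested configuration for an end-to-end run. Defaults are the
#' pipeline's working constants: 512 px tiles with background threshold 220
#' and 128 px downsampling for tumor clustering, 224 px extractor input with
#' ImageNet channel statistics and 2048-dim features, 30 Adam epochs with bag
#' batch 8 (learning rates 1e-4 / 1e-3 for gamma), 70/15/15 patient splits
#' and 1000 bootstrap replicates. The configuration round-trips through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param paths list with `outputs` (and optionally `slides`, `cache`).
#' @param preprocessing,features,model,training,evaluation,simulate,tasks
#'   stage sections; any supplied entries override the defaults.
#' @return Object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(paths = list(outputs = tempfile("wsimil_run_")),
                            preprocessing = list(), features = list(),
                            model = list(), training = list(),
                            evaluation = list(), simulate = list(),
                            tasks = NULL) {
  merge_section <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    paths = merge_section(list(slides = NULL, cache = NULL, outputs = NULL), paths),
    preprocessing = merge_section(
      list(tile_size = 512L, background_threshold = 220, downsample_side = 128L,
           target_mean = c(148, 110, 140), target_std = c(35, 35, 35)),
      preprocessing),
    features = merge_section(
      list(extractor = "projection", dim = 2048L, side = 224L, proj_side = 32L,
           channel_mean = imagenet_mean, channel_std = imagenet_std,
           extractor_seed = 1L),
      features),
    model = merge_section(list(d_attn = 16L, hidden = c(512L, 128L), seed = 1L),
                          model),
    training = merge_section(
      list(epochs = 30L, batch_size = 8L, lr = 1e-4, lr_gamma = 1e-3),
      training),
    evaluation = merge_section(list(ratios = c(0.70, 0.15, 0.15), n_boot = 1000L),
                               evaluation),
    simulate = merge_section(
      list(n_patients = 24L, width_tiles = 10L, height_tiles = 8L,
           tile_size = 16L, tissue_fraction = 0.6, signal_fraction = 0.4,
           gene = "TP53", prevalence = 0.5, seed = 1L),
      simulate),
    tasks = tasks %||% data.frame(name = "TP53_point", type = "gene_point",
                                  target = "TP53", stringsAsFactors = FALSE)
  )
  structure(cfg, class = "pipeline_config")
}

#' A small fully synthetic demonstration configuration
#'
#' Overrides the full-scale defaults with the synthetic demo scale (16
#' simulated slides of 10 x 8 tiles of 16 px, a 32-dim projection extractor,
#' 10 epochs, 200 bootstrap replicates) so the whole pipeline runs in
#' seconds.
#'
#' @param outputs output directory.
#' @param seed seed propagated to every stage.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(outputs = tempfile("wsimil_demo_"), seed = 1L) {
  pipeline_config(
    paths = list(outputs = outputs),
    preprocessing = list(tile_size = 16L, downsample_side = 16L),
    features = list(dim = 32L, side = 16L, proj_side = 8L),
    model = list(hidden = c(64L, 32L), d_attn = 8L, seed = seed),
    training = list(epochs = 10L),
    evaluation = list(n_boot = 200L),
    simulate = list(seed = seed)
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @return `write_config` returns the path invisibly; `read_config` returns
#'   the `pipeline_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$tasks <- as.list(as.data.frame(config$tasks))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  tasks <- if (!is.null(x$tasks)) as.data.frame(x$tasks, stringsAsFactors = FALSE)
  x$tasks <- NULL
  do.call(pipeline_config,
          c(x[intersect(names(x), c("paths", "preprocessing", "features",
                                    "model", "training", "evaluation",
                                    "simulate"))],
            list(tasks = tasks)))
}

#' Validate a pipeline configuration before running
#'
#' @param config a [pipeline_config()].
#' @return Invisibly `TRUE`; errors describe what is missing.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$paths$outputs))
    stop_arg("config$paths$outputs is required")
  if (nrow(config$tasks) < 1L) stop_arg("at least one task is required")
  with(config$preprocessing, {
    stopifnot(tile_size >= 8, background_threshold > 0, downsample_side >= 1)
  })
  stopifnot(config$training$epochs >= 1, config$evaluation$n_boot >= 1)
  invisible(TRUE)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Simulates omics and one slide per patient (signal tiles are planted
#' exactly in the slides of patients positive for the configured gene), runs
#' tiling, background filtering, tumor-tile clustering, colour
#' normalization, feature extraction into a cache, label derivation, a
#' seeded train/validation/test patient split, attention-MIL training,
#' test-set evaluation with bootstrap AUC interval, and a weight-map
#' visualization for the first test patient. All stage outputs land under
#' `config$paths$outputs` and are addressable from the returned manifest.
#'
#' @param config a [pipeline_config()]; see [demo_config()] for a fast one.
#' @return The run manifest (list), invisibly also written as
#'   `manifest.json`: configuration hash, seeds, per-stage counts, metrics
#'   and output checksums.
#' @export
run_pipeline <- function(config = demo_config()) {
  validate_config(config)
  out_dir <- config$paths$outputs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulate
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_arg(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  # --- simulate omics -------------------------------------------------------
  pw_defs <- read_pathway_defs(system.file("extdata", "pathways_default.tsv",
                                           package = "wsimil"))
  omics <- stage("simulate_omics", generate_omics(
    sim$n_patients,
    gene_specs = data.frame(gene = sim$gene, prevalence = sim$prevalence),
    pathway_defs = pw_defs, seed = sim$seed))
  patients <- colnames(omics$mutation$values)
  status <- omics$mutation$values[sim$gene, ]

  # --- simulate slides + preprocessing + features --------------------------
  extractor <- projection_extractor(
    dim = config$features$dim, side = config$features$side,
    proj_side = config$features$proj_side, seed = config$features$extractor_seed,
    channel_mean = config$features$channel_mean,
    channel_std = config$features$channel_std)
  target_stats <- structure(list(mean = config$preprocessing$target_mean,
                                 std = config$preprocessing$target_std,
                                 color_space = "RGB"),
                            class = "slide_color_stats")
  cache <- feature_cache(config$paths$cache %||% file.path(out_dir, "cache"))
  counts <- list()
  slides <- list()
  for (i in seq_along(patients)) {
    sl <- stage("simulate_slide", generate_slide(
      sim$width_tiles, sim$height_tiles, tissue_fraction = sim$tissue_fraction,
      signal_fraction = if (status[i] == 1L) sim$signal_fraction else 0,
      tile_size = sim$tile_size, seed = sim$seed * 1000L + i,
      slide_id = patients[i]))
    pp <- stage("preprocess", preprocess_slide(
      sl, tile_size = config$preprocessing$tile_size,
      background_threshold = config$preprocessing$background_threshold,
      target_stats = target_stats, seed = config$model$seed,
      side = config$preprocessing$downsample_side))
    bag <- stage("featurize", extract_features(pp$tiles, extractor, patients[i]))
    write_cache(cache, bag)
    counts[[patients[i]]] <- pp$counts
    slides[[patients[i]]] <- sl
  }

  # --- labels ---------------------------------------------------------------
  labels_df <- stage("labels", make_label_table(
    mutations = binarize_alterations(omics$mutation),
    cna = binarize_alterations(omics$cna),
    activities_expr = pathway_activity(omics$expression, pw_defs),
    activities_cna = pathway_activity(omics$cna, pw_defs),
    tasks = config$tasks,
    cache_patients = cache_manifest(cache)$patient_id))
  write_label_table(labels_df, file.path(out_dir, "labels.tsv"))

  # --- split ----------------------------------------------------------------
  split <- stage("split", split_patients(
    patients, config$evaluation$ratios, seed = sim$seed,
    names = if (length(config$evaluation$ratios) == 3L)
      c("train", "val", "test") else NULL))
  write_split_tsv(split, file.path(out_dir, "split.tsv"))
  part_of <- stats::setNames(split$assignment$partition, split$assignment$patient_id)

  # --- train + evaluate per task -------------------------------------------
  metrics <- list()
  fits <- list()
  for (k in seq_len(nrow(config$tasks))) {
    task <- config$tasks$name[k]
    y <- stats::setNames(labels_df[[task]], labels_df$patient_id)
    get_bags <- function(part) lapply(names(part_of)[part_of == part],
                                      function(p) read_cache(cache, p))
    tr <- get_bags("train"); va <- get_bags("val"); te <- get_bags("test")
    y_tr <- y[vapply(tr, `[[`, "", "patient_id")]
    y_va <- y[vapply(va, `[[`, "", "patient_id")]
    y_te <- y[vapply(te, `[[`, "", "patient_id")]
    cfg_fit <- mil_config(epochs = config$training$epochs,
                          batch_size = config$training$batch_size,
                          lr = config$training$lr,
                          lr_gamma = config$training$lr_gamma,
                          hidden = config$model$hidden,
                          d_attn = config$model$d_attn,
                          seed = config$model$seed)
    fit <- stage("train", mil_fit(tr, y_tr, va, y_va, config = cfg_fit))
    scores <- predict(fit, te)
    res <- stage("evaluate", evaluate_scores(scores, y_te,
                                             n_boot = config$evaluation$n_boot,
                                             seed = config$model$seed))
    write_eval_json(res, file.path(out_dir, paste0("metrics_", task, ".json")),
                    task = task)
    save_checkpoint(fit, file.path(out_dir, paste0("model_", task)),
                    extractor_id = extractor$id)
    metrics[[task]] <- list(auc = res$auc, ci_low = res$ci_low,
                            ci_high = res$ci_high, n_test = length(y_te))
    fits[[task]] <- fit

    # --- visualize first test patient --------------------------------------
    p1 <- te[[1L]]
    beta <- predict(fit, list(p1), type = "beta")[[1L]]
    wm <- stage("visualize", build_weight_map(
      beta, p1$tile_positions,
      grid_dim = c(sim$height_tiles, sim$width_tiles),
      slide_id = p1$patient_id))
    write_weight_map(wm, file.path(out_dir, paste0("weightmap_", task)))
  }

  # --- manifest -------------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_file)
  # hash the configuration without its paths so identical runs in different
  # directories produce identical manifests
  cfg_nopaths <- config
  cfg_nopaths$paths <- NULL
  hash_file <- tempfile()
  write_config(cfg_nopaths, hash_file)
  cfg_hash <- unname(md5_of_file(hash_file))
  unlink(hash_file)
  outputs <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                     file.path(out_dir, c("manifest.json", "config.yaml")))
  manifest <- list(
    config_hash = cfg_hash,
    seed = sim$seed,
    n_patients = length(patients),
    tile_counts = counts,
    split_sizes = as.list(split$sizes),
    label_positives = as.list(attr(labels_df, "positives")),
    metrics = metrics,
    output_checksums = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                               basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(c(manifest, list(fits = fits)))
}
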