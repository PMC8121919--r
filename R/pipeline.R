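#' Pipeline configuration
#'
#' Collects the instrument constants and analysis parameters used by
#' [run_pipeline()]. `pixel_size_mm` and `seed` have no defaults: the
#' pixel size is instrument-specific and the seed must be stated for
#' reproducibility.
#'
#' @param pixel_size_mm Physical pixel edge length (mm).
#' @param seed Integer seed for all stochastic stages.
#' @param image_volume_L Illuminated volume per image (L, default 1).
#' @param min_object_pixels Minimum object area kept (px, default 80).
#' @param depth_bin_m Depth bin height (m, default 5).
#' @param k Number of morphotypes (default 5).
#' @param n_components PCA components retained (default 4).
#' @param trim_fraction Tail mass trimmed per descriptor (default 0.001).
#' @param binarize_threshold Segmentation grey threshold (default 240).
#' @param n_restarts k-means restarts (default 10).
#' @param log_vars Descriptors to log-transform
#'   (default [default_log_vars()]).
#' @param size_bins_mm Size-spectrum bin edges (default [size_bins()]).
#' @return A list of class `snow_config`.
#' @export
pipeline_config <- function(pixel_size_mm, seed,
                            image_volume_L = 1,
                            min_object_pixels = 80,
                            depth_bin_m = 5,
                            k = 5,
                            n_components = 4,
                            trim_fraction = 0.001,
                            binarize_threshold = 240,
                            n_restarts = 10,
                            log_vars = default_log_vars(),
                            size_bins_mm = size_bins()) {
  stopifnot(
    pixel_size_mm > 0, image_volume_L > 0, min_object_pixels > 0,
    depth_bin_m > 0, k >= 2, n_components >= 1, trim_fraction >= 0
  )
  structure(
    list(
      pixel_size_mm = pixel_size_mm, seed = as.integer(seed),
      image_volume_L = image_volume_L,
      min_object_pixels = min_object_pixels,
      depth_bin_m = depth_bin_m, k = k, n_components = n_components,
      trim_fraction = trim_fraction,
      binarize_threshold = binarize_threshold,
      n_restarts = n_restarts, log_vars = log_vars,
      size_bins_mm = size_bins_mm
    ),
    class = "snow_config"
  )
}

#' Run the full morphotyping pipeline
#'
#' Executes, in order: feature extraction (when vignettes are given) →
#' trimming → log/standardise transform → PCA morphospace → k-means →
#' morphotype naming (at k = 5) → optional depth binning and export
#' metrics when per-object observations are supplied. When `output_dir`
#' is given, writes the morphospace + model serialization, the labelled
#' object table, the profile and metrics tables, and a run manifest
#' (config, seed, package version, file hashes).
#'
#' @param config A [pipeline_config()].
#' @param vignettes List of [snow_vignette()] (alternative to `features`).
#' @param features Pre-extracted descriptor table (skips extraction).
#' @param observations Optional per-object table (`object_id`, `cast`,
#'   `time`, `depth`) merged by `object_id` for profile metrics.
#' @param volumes Sampled volume per (cast, depth_bin), see
#'   [bin_concentrations()]; required with `observations`.
#' @param training_id Identifier recorded in the fitted objects.
#' @param output_dir Optional directory for the artifact bundle.
#' @return List with `features`, `morphospace`, `model`, `labels`
#'   (labelled object tibble), and — when observations were given —
#'   `profiles` and `metrics`.
#' @export
run_pipeline <- function(config, vignettes = NULL, features = NULL,
                         observations = NULL, volumes = NULL,
                         training_id = "run", output_dir = NULL) {
  stopifnot(inherits(config, "snow_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  if (is.null(features)) {
    if (is.null(vignettes)) abort("supply `vignettes` or `features`.")
    features <- stage("features",
      feature_table(vignettes, threshold = config$binarize_threshold))
  }
  features <- features %>% filter(.data$area >= config$min_object_pixels)

  morphospace <- stage("morphospace", fit_morphospace(
    features,
    log_vars = config$log_vars,
    n_components = config$n_components,
    trim_fraction = config$trim_fraction,
    training_id = training_id
  ))
  model <- stage("clustering", fit_morphotypes(
    morphospace$scores,
    k = config$k, seed = config$seed,
    n_restarts = config$n_restarts, training_id = training_id
  ))
  if (config$k == 5) {
    trained_feats <- features %>%
      filter(.data$object_id %in% morphospace$scores$object_id)
    model <- stage("naming",
      name_morphotypes(model, trained_feats, model$cluster))
  }

  scores_all <- stage("projection",
    project_morphospace(features, morphospace))
  labels <- assign_morphotypes(scores_all, model) %>%
    mutate(esd_mm = features$esd * config$pixel_size_mm)

  out <- list(
    features = features, morphospace = morphospace,
    model = model, labels = labels
  )

  if (!is.null(observations)) {
    if (is.null(volumes)) abort("`volumes` is required with `observations`.")
    obj <- observations %>%
      dplyr::inner_join(
        labels %>% select("object_id", "morphotype", "esd_mm"),
        by = "object_id"
      )
    if (nrow(obj) < nrow(observations)) {
      inform(paste0(nrow(observations) - nrow(obj),
                    " observation(s) without a labelled object dropped."))
    }
    out$profiles <- stage("binning",
      bin_concentrations(obj, volumes, bin_height = config$depth_bin_m))
    out$metrics <- stage("metrics", pipeline_metrics(out$profiles, obj,
                                                     config))
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(output_dir, f)
    write_morphospace(morphospace, fp("morphospace.json"), model = model)
    write_tsv_table(labels, fp("labelled_objects.tsv"))
    files <- c("morphospace.json", "labelled_objects.tsv")
    if (!is.null(out$profiles)) {
      write_tsv_table(out$profiles, fp("profiles.tsv"))
      write_tsv_table(out$metrics, fp("metrics.tsv"))
      files <- c(files, "profiles.tsv", "metrics.tsv")
    }
    manifest <- list(
      package = "snowmorph",
      version = as.character(utils::packageVersion("snowmorph")),
      config = unclass(config),
      training_id = training_id,
      n_objects = nrow(features),
      files = as.list(setNames(
        unname(tools::md5sum(vapply(files, fp, character(1)))), files
      ))
    )
    jsonlite::write_json(manifest, fp("manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    out$output_dir <- output_dir
  }
  out
}

# Per (morphotype, time) summary metrics: attenuation fit and diversity;
# plus the size-spectrum slope per time over all morphotypes.
pipeline_metrics <- function(profiles, objects, config) {
  bh <- config$depth_bin_m
  atten <- profiles %>%
    group_by(.data$time, .data$morphotype, .data$depth_bin) %>%
    summarise(
      count = sum(.data$count), volume_L = sum(.data$volume_L),
      .groups = "drop"
    ) %>%
    mutate(
      depth = .data$depth_bin + bh / 2,
      concentration = .data$count / .data$volume_L
    ) %>%
    group_by(.data$time, .data$morphotype) %>%
    summarise(
      fit = list(tryCatch(
        attenuation_exponent(dplyr::pick("depth", "concentration")),
        error = function(e) tibble(n_100 = NA_real_, b = NA_real_,
                                   n_bins_used = NA_integer_)
      )),
      .groups = "drop"
    ) %>%
    tidyr::unnest("fit")
  div <- profiles %>%
    group_by(.data$time, .data$morphotype) %>%
    summarise(total_conc = sum(.data$concentration_per_L),
              .groups = "drop") %>%
    group_by(.data$time) %>%
    summarise(shannon_H = shannon_diversity(.data$total_conc),
              .groups = "drop")
  slope <- objects %>%
    filter(!is.na(.data$esd_mm)) %>%
    group_by(.data$time) %>%
    summarise(
      spectrum = list(tryCatch(
        size_spectrum_slope(.data$esd_mm,
                            volume_L = sum(config$image_volume_L),
                            bins = config$size_bins_mm),
        error = function(e) tibble(slope = NA_real_, intercept = NA_real_,
                                   n_bins_used = NA_integer_,
                                   n_particles = NA_integer_)
      )),
      .groups = "drop"
    ) %>%
    tidyr::unnest("spectrum") %>%
    select("time", spectrum_slope = "slope")
  atten %>%
    left_join(div, by = "time") %>%
    left_join(slope, by = "time")
}

#' Cross-campaign classification agreement
#'
#' The reproducibility check used across campaigns: fit a morphospace and
#' morphotype model on dataset A, another on dataset B, classify the
#' *same* objects with both, and measure agreement (Cohen's kappa) after
#' optimal label alignment.
#'
#' @param features_a,features_b Descriptor tables of the two campaigns.
#' @param config A [pipeline_config()].
#' @param features_test Objects to classify under both models; default
#'   the union of both campaigns.
#' @return List with `agreement` (a `snow_agreement`), and the two fitted
#'   `model_a`/`model_b` bundles.
#' @export
cross_classify <- function(features_a, features_b, config,
                           features_test = NULL) {
  if (is.null(features_test)) {
    features_test <- bind_rows(features_a, features_b)
  }
  fit_one <- function(features, id, seed) {
    ms <- fit_morphospace(features, log_vars = config$log_vars,
                          n_components = config$n_components,
                          trim_fraction = config$trim_fraction,
                          training_id = id)
    km <- fit_morphotypes(ms$scores, k = config$k, seed = seed,
                          n_restarts = config$n_restarts, training_id = id)
    list(morphospace = ms, model = km)
  }
  a <- fit_one(features_a, "campaign_a", config$seed)
  b <- fit_one(features_b, "campaign_b", config$seed + 1L)
  lab_a <- assign_morphotypes(
    project_morphospace(features_test, a$morphospace), a$model)$cluster
  lab_b <- assign_morphotypes(
    project_morphospace(features_test, b$morphospace), b$model)$cluster
  list(
    agreement = agreement_kappa(lab_a, lab_b),
    model_a = a,
    model_b = b
  )
}
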