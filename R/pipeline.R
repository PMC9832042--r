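#' Pipeline configuration
#'
#' Resolves every knob of the end-to-end analysis: where the cohort lives
#' (or that it should be simulated), segmentation area limits, the
#' negative-control quantile fixing the intensity threshold, how many random
#' images per sample enter intensity quantification, the number of PCA
#' contributors to report, and the roughness error metric. The resolved
#' config is written next to every run's outputs and round-trips through
#' YAML unchanged.
#'
#' @param cohort A [cohort_config()] used when `input_dir` is `NULL`
#'   (simulate-first run).
#' @param input_dir Existing cohort directory (with `metadata.csv`), or
#'   `NULL` to simulate into `out_dir/cohort`.
#' @param out_dir Output directory for all result tables and the report.
#' @param seed Integer master seed; per-stage sub-seeds are derived from it.
#' @param min_area,max_area Nucleus segmentation area filter, px^2.
#' @param control_quantile Quantile of the negative-control image used as
#'   the intensity threshold.
#' @param images_per_sample_k Random images per sample entering intensity
#'   quantification (capped at availability).
#' @param pca_k_top Contributors reported per principal component.
#' @param roughness_metric `"mad"` or `"rms"`.
#' @param marker_gain Arbitrary-unit value of marker pixel value 1.0 (used
#'   when reading marker TIFFs; overridden by a simulated cohort's own
#'   config).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            input_dir = NULL,
                            out_dir = tempfile("cartimorph_run_"),
                            seed = 1L,
                            min_area = 50,
                            max_area = 5000,
                            control_quantile = 0.999,
                            images_per_sample_k = 5L,
                            pca_k_top = 10L,
                            roughness_metric = "mad",
                            marker_gain = 65535) {
  cfg <- list(
    cohort = if (is.null(input_dir)) unclass(cohort) else NULL,
    input_dir = input_dir,
    out_dir = out_dir,
    seed = as.integer(seed),
    min_area = as.numeric(min_area),
    max_area = as.numeric(max_area),
    control_quantile = as.numeric(control_quantile),
    images_per_sample_k = as.integer(images_per_sample_k),
    pca_k_top = as.integer(pca_k_top),
    roughness_metric = match.arg(roughness_metric, c("mad", "rms")),
    marker_gain = as.numeric(marker_gain)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save / load a pipeline configuration
#'
#' YAML round-trip: `read_pipeline_config(write_pipeline_config(cfg, f))`
#' reproduces the config exactly.
#'
#' @param config A [pipeline_config()].
#' @param path Destination / source `.yaml` path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the config.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config not found: '%s'", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(raw$cohort)) {
    cohort <- raw$cohort
    class(cohort) <- "cohort_config"
  }
  cfg <- raw
  cfg$cohort <- if (is.null(cohort)) NULL else unclass(cohort)
  class(cfg) <- "pipeline_config"
  cfg
}

collect_warnings <- function(expr, store) {
  withCallingHandlers(expr, warning = function(w) {
    store$messages <- c(store$messages, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (when no `input_dir` is given),
#' surface roughness per sample with its age trend, nuclear segmentation
#' and 53-descriptor morphometry with per-sample averaging, per-cell marker
#' intensity with negative-control thresholding and random image selection,
#' nuclei-level PCA with top-contributor ranking and young-vs-aged
#' separation, and the sample-level regressions (age trends; marker ~ age +
#' eccentricity with partial R-squared). Writes all tables, `regressions.json`,
#' `report.json`, and the resolved config under `out_dir`.
#'
#' The run is a pure function of the config: identical config and seed
#' reproduce `report.json` byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warn <- new.env(); warn$messages <- character(0)
  stage <- function(name, expr) {
    tryCatch(collect_warnings(expr, warn), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- stage: simulate / locate cohort ------------------------------------
  marker_gain <- config$marker_gain
  if (is.null(config$input_dir)) {
    cohort_cfg <- config$cohort
    class(cohort_cfg) <- "cohort_config"
    cohort_dir <- file.path(out_dir, "cohort")
    stage("simulate", generate_cohort(cohort_cfg, cohort_dir))
    marker_gain <- cohort_cfg$marker_gain
  } else {
    cohort_dir <- config$input_dir
  }
  meta_path <- file.path(cohort_dir, "metadata.csv")
  metadata <- stage("metadata", read_table(
    meta_path, required = c("sample_id", "group", "group_code", "image_id",
                            "dapi_path", "marker_path", "mask_path")))

  # -- stage: surface roughness -------------------------------------------
  mask_files <- unique(metadata[, c("sample_id", "mask_path")])
  masks <- stage("roughness", {
    m <- lapply(file.path(cohort_dir, mask_files$mask_path), read_mask)
    names(m) <- mask_files$sample_id
    m
  })
  rough <- stage("roughness",
                 roughness_by_group(masks, metadata,
                                    metric = config$roughness_metric))
  write_table(rough$per_image, file.path(out_dir, "roughness.csv"))
  write_table(rough$per_sample, file.path(out_dir, "roughness_samples.csv"))

  # -- stage: nuclear morphometry -----------------------------------------
  features <- stage("nuclei", {
    rows <- lapply(seq_len(nrow(metadata)), function(i) {
      img <- read_image(file.path(cohort_dir, metadata$dapi_path[i]))
      seg <- segment_nuclei(img, min_area = config$min_area,
                            max_area = config$max_area,
                            image_id = metadata$image_id[i])
      if (seg$n == 0) return(NULL)
      measure_features(seg)
    })
    do.call(rbind, rows)
  })
  write_table(features, file.path(out_dir, "nuclei_features.csv"))
  sample_features <- stage("nuclei",
                           aggregate_nuclei_by_sample(features, metadata))
  write_table(sample_features, file.path(out_dir, "sample_features.csv"))

  # -- stage: marker intensity --------------------------------------------
  control_path <- file.path(cohort_dir, "negative_control_marker.tif")
  threshold <- stage("intensity", {
    if (file.exists(control_path)) {
      threshold_from_negative_control(read_image(control_path) * marker_gain,
                                      q = config$control_quantile)
    } else {
      0
    }
  })
  records <- stage("intensity", {
    rows <- list()
    for (sid in unique(metadata$sample_id)) {
      sm <- metadata[metadata$sample_id == sid, ]
      k <- min(config$images_per_sample_k, nrow(sm))
      chosen <- sample_images(sm$image_id, k,
                              derive_seed(config$seed, match(sid, unique(metadata$sample_id))))
      for (iid in chosen) {
        row <- sm[sm$image_id == iid, ]
        dapi <- read_image(file.path(cohort_dir, row$dapi_path))
        seg <- segment_nuclei(dapi, min_area = config$min_area,
                              max_area = config$max_area, image_id = iid)
        if (seg$n == 0) next
        marker <- read_image(file.path(cohort_dir, row$marker_path)) *
          marker_gain
        rows[[length(rows) + 1L]] <-
          intensity_per_cell(marker, seg, threshold, image_id = iid)
      }
    }
    do.call(rbind, rows)
  })
  write_table(records, file.path(out_dir, "intensity.csv"))
  sample_intensity <- stage("intensity",
                            aggregate_intensity_by_sample(records, metadata))
  write_table(sample_intensity, file.path(out_dir, "sample_intensity.csv"))

  # -- stage: PCA and separation ------------------------------------------
  pca <- stage("pca", {
    zs <- zscore_features(features[, nuclear_feature_names])
    run_pca(zs$x, k_top = config$pca_k_top)
  })
  nuc_groups <- metadata$group[match(features$image_id, metadata$image_id)]
  scores_df <- data.frame(image_id = features$image_id,
                          nucleus_id = features$nucleus_id,
                          group = nuc_groups,
                          pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                     drop = FALSE])
  write_table(scores_df, file.path(out_dir, "pca_scores.csv"))
  load_df <- data.frame(variable = rownames(pca$loadings),
                        pca$loadings[, seq_len(min(5, ncol(pca$loadings))),
                                     drop = FALSE], row.names = NULL)
  write_table(load_df, file.path(out_dir, "pca_loadings.csv"))
  top_df <- do.call(rbind, lapply(names(pca$top_contributors)[1:2],
    function(pc) cbind(component = pc, pca$top_contributors[[pc]])))
  write_table(top_df, file.path(out_dir, "top_contributors.csv"))
  groups <- unique(metadata[, c("group", "group_code")])
  groups <- groups[order(groups$group_code), ]
  extremes <- c(groups$group[1], groups$group[nrow(groups)])
  # separation of animals: PCA on per-sample mean features, silhouette of
  # the youngest vs oldest group on PC1-PC2
  sep <- stage("pca", {
    zs_s <- collect_warnings(
      zscore_features(sample_features[, nuclear_feature_names]), warn)
    pca_s <- run_pca(zs_s$x, k_top = config$pca_k_top)
    sel <- sample_features$group %in% extremes
    collect_warnings(group_separation(pca_s$scores[sel, 1:2],
                                      sample_features$group[sel]), warn)
  })
  sep_nuclei <- stage("pca", {
    sel <- nuc_groups %in% extremes
    collect_warnings(group_separation(pca$scores[sel, 1:2],
                                      nuc_groups[sel]), warn)
  })

  # -- stage: regressions --------------------------------------------------
  samp <- merge(sample_features[, c("sample_id", "group", "group_code",
                                    "eccentricity")],
                sample_intensity[, c("sample_id", "mean_intensity_per_cell")],
                by = "sample_id")
  ecc_trend <- stage("associate",
                     regress_trend(samp$eccentricity, samp$group_code))
  int_trend <- stage("associate",
                     regress_trend(samp$mean_intensity_per_cell,
                                   samp$group_code))
  assoc <- stage("associate",
                 regress_marker_on_morphology(samp$mean_intensity_per_cell,
                                              samp$eccentricity,
                                              samp$group_code))
  young_i <- samp$mean_intensity_per_cell[samp$group == extremes[1]]
  aged_i <- samp$mean_intensity_per_cell[samp$group == extremes[2]]
  ttest <- stats::t.test(young_i, aged_i)

  reg_summary <- function(r) {
    list(coefficients = r$coefficients, r_squared = r$r_squared,
         partial_r2 = as.list(r$partial_r2))
  }
  regressions <- list(
    roughness_age_trend = reg_summary(rough$trend),
    eccentricity_age_trend = reg_summary(ecc_trend),
    intensity_age_trend = reg_summary(int_trend),
    marker_on_age_and_eccentricity = reg_summary(assoc)
  )
  jsonlite::write_json(regressions, file.path(out_dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  cfg_path <- file.path(out_dir, "pipeline_config.yaml")
  write_pipeline_config(config, cfg_path)
  # provenance hash covers the scientific configuration, not run paths
  sci_cfg <- unclass(config)
  sci_cfg$out_dir <- NULL
  sci_cfg$input_dir <- NULL
  hash_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(sci_cfg, hash_path, precision = 15)
  config_md5 <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  slope_of <- function(r, term) {
    r$coefficients$estimate[r$coefficients$term == term]
  }
  p_of <- function(r, term) {
    r$coefficients$p_value[r$coefficients$term == term]
  }
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("cartimorph")),
      seed = config$seed,
      config_md5 = config_md5,
      cohort_dir = basename(cohort_dir)
    ),
    n_samples = nrow(samp),
    n_nuclei = nrow(features),
    intensity_threshold = threshold,
    roughness = list(
      slope = slope_of(rough$trend, "group_code"),
      p_value = p_of(rough$trend, "group_code"),
      per_group_mean = as.list(tapply(rough$per_sample$R,
        metadata$group[match(rough$per_sample$sample_id,
                             metadata$sample_id)], mean))
    ),
    eccentricity = list(
      slope = slope_of(ecc_trend, "group_code"),
      p_value = p_of(ecc_trend, "group_code"),
      pc1_top_contributors = pca$top_contributors$PC1$variable,
      eccentricity_in_pc1_top = "eccentricity" %in%
        pca$top_contributors$PC1$variable,
      pc1_explained_variance = pca$explained_variance[1]
    ),
    separation = list(groups = extremes,
                      silhouette_samples = sep$silhouette,
                      silhouette_nuclei = sep_nuclei$silhouette),
    intensity = list(
      slope = slope_of(int_trend, "group_code"),
      p_value = p_of(int_trend, "group_code"),
      young_vs_aged_p = ttest$p.value,
      group_means = as.list(tapply(samp$mean_intensity_per_cell, samp$group,
                                   mean))
    ),
    association = list(
      eccentricity_coefficient = slope_of(assoc, "eccentricity"),
      age_coefficient = slope_of(assoc, "age"),
      r_squared = assoc$r_squared,
      eccentricity_partial_r2 = unname(assoc$partial_r2["eccentricity"]),
      age_partial_r2 = unname(assoc$partial_r2["age"])
    ),
    warnings = warn$messages
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
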