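#' Per-cell fluorescence intensity of one image
#'
#' Integrated density — the sum of all pixel values strictly above the
#' background threshold, whole image — divided by the number of cells
#' (segmented DAPI nuclei) in the paired counterstain image. A per-object
#' mode (summing only within nuclear masks) is available behind `within_cells`.
#'
#' @param marker Numeric matrix, marker channel (any intensity units).
#' @param nuclei A [segment_nuclei()] result for the paired DAPI image.
#' @param threshold Background threshold in the same units as `marker`
#'   (see [threshold_from_negative_control()]).
#' @param image_id Optional provenance label.
#' @param within_cells If `TRUE`, integrate only over pixels inside nuclear
#'   masks (still above threshold).
#' @return One-row data frame (`CellIntensityRecord`): `image_id`,
#'   `integrated_density`, `cell_count`, `intensity_per_cell`, `threshold`.
#' @export
intensity_per_cell <- function(marker, nuclei, threshold,
                               image_id = NA_character_,
                               within_cells = FALSE) {
  stopifnot(inherits(nuclei, "labeled_nuclei"))
  if (!all(dim(marker) == dim(nuclei$labels))) {
    stop("marker image and nuclei labels must have the same shape",
         call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  if (nuclei$n == 0) stop("no cells in image", call. = FALSE)
  sel <- marker > threshold
  if (within_cells) sel <- sel & nuclei$labels > 0
  dens <- sum(marker[sel])
  data.frame(image_id = image_id %||% nuclei$image_id,
             integrated_density = dens,
             cell_count = nuclei$n,
             intensity_per_cell = dens / nuclei$n,
             threshold = threshold)
}

#' Background threshold from a negative-control image
#'
#' One negative-control slide per staining set (primary antibody omitted)
#' fixes the signal threshold for every image of the experiment: the
#' threshold is a high quantile (default 0.999) of the control image's
#' pixel intensities.
#'
#' @param control Numeric matrix, negative-control image.
#' @param q Quantile in `[0, 1]`; `q = 1` gives the control maximum.
#' @return Scalar threshold in the units of `control`.
#' @export
threshold_from_negative_control <- function(control, q = 0.999) {
  if (length(control) == 0) stop("control image is empty", call. = FALSE)
  as.numeric(stats::quantile(control, probs = q, names = FALSE))
}

#' Seed-deterministic random subset of images
#'
#' Uniform sampling without replacement of `k` images, emulating the
#' random-field selection step (5 or 10 fields per sample depending on
#' magnification). The subset is returned in the original list order.
#'
#' @param images Character vector (or any vector) of image identifiers.
#' @param k Number of images to select.
#' @param seed Integer seed.
#' @return Subset of `images`, order-normalized to the input order.
#' @export
sample_images <- function(images, k, seed) {
  stopifnot_scalar_count(k, "k")
  if (k > length(images)) {
    stop(sprintf("cannot sample %d from %d images", k, length(images)),
         call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(length(images), k))
  images[sort(idx)]
}

#' Average per-cell intensity within samples
#'
#' Per-sample mean of `intensity_per_cell` over the sample's (randomly
#' selected) images; the unit of analysis is the independent sample, so the
#' reported `n` is the number of samples. Samples with no valid record are
#' dropped with a warning.
#'
#' @param records Row-bound [intensity_per_cell()] records.
#' @param metadata Data frame mapping `image_id` to `sample_id` (and
#'   optionally `group`, `group_code`).
#' @return Data frame: `sample_id`, grouping columns if present,
#'   `n_images`, `mean_intensity_per_cell`.
#' @export
aggregate_intensity_by_sample <- function(records, metadata) {
  if (is.null(records) || nrow(records) == 0) {
    warning("no intensity records to aggregate", call. = FALSE)
    return(data.frame())
  }
  map_cols <- intersect(c("sample_id", "group", "group_code"),
                        names(metadata))
  map <- unique(metadata[, c("image_id", map_cols)])
  recs <- merge(records, map, by = "image_id")
  agg <- stats::aggregate(
    list(mean_intensity_per_cell = recs$intensity_per_cell),
    by = recs["sample_id"], FUN = mean)
  n <- stats::aggregate(list(n_images = recs$image_id),
                        by = recs["sample_id"], FUN = length)
  smeta <- unique(metadata[, map_cols, drop = FALSE])
  out <- merge(smeta, merge(agg, n, by = "sample_id"), by = "sample_id")
  dropped <- setdiff(smeta$sample_id, out$sample_id)
  if (length(dropped) > 0) {
    warning(sprintf("sample(s) with no intensity records dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  out[, c(map_cols, "n_images", "mean_intensity_per_cell")]
}
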