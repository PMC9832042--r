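make_labels <- function(n_cells, dim = c(40, 40)) {
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(n_cells)) lab[2 + i * 3, 5:10] <- i
  structure(list(labels = lab, n = n_cells,
                 border_touching = rep(FALSE, n_cells), image_id = "img"),
            class = "labeled_nuclei")
}

test_that("integrated density divides evenly across cells", {
  marker <- matrix(0, 40, 40)
  marker[1:10, 1:10] <- 4  # 100 px x 4 = 400 above threshold 0
  rec <- intensity_per_cell(marker, make_labels(4), threshold = 0)
  expect_equal(rec$integrated_density, 400)
  expect_equal(rec$cell_count, 4)
  expect_equal(rec$intensity_per_cell, 100)
})

test_that("threshold above the image maximum zeroes the record", {
  marker <- matrix(runif(400), 20, 20)
  rec <- intensity_per_cell(marker, make_labels(2, c(20, 20)),
                            threshold = 2)
  expect_equal(rec$integrated_density, 0)
  expect_equal(rec$intensity_per_cell, 0)
})

test_that("zero segmented cells is an error, shape mismatch too", {
  marker <- matrix(1, 20, 20)
  expect_error(intensity_per_cell(marker, make_labels(0, c(20, 20)), 0),
               "no cells")
  expect_error(intensity_per_cell(matrix(1, 10, 10), make_labels(2), 0),
               "same shape")
})

test_that("integrated density is exactly linear in image scale", {
  set.seed(5)
  marker <- matrix(rexp(1600, 1 / 50), 40, 40)
  lab <- make_labels(3)
  r1 <- intensity_per_cell(marker, lab, threshold = 10)
  for (c in c(2, 7.5, 0.25)) {
    r2 <- intensity_per_cell(marker * c, lab, threshold = 10 * c)
    expect_equal(r2$integrated_density, c * r1$integrated_density,
                 tolerance = 1e-12)
    expect_equal(r2$intensity_per_cell, c * r1$intensity_per_cell,
                 tolerance = 1e-12)
  }
})

test_that("integrated density is additive over disjoint tiles", {
  set.seed(6)
  marker <- matrix(rexp(3600, 1 / 30), 60, 60)
  lab1 <- make_labels(1, c(60, 60))
  whole <- intensity_per_cell(marker, lab1, threshold = 5)$integrated_density
  tiles <- list(marker[1:30, 1:30], marker[1:30, 31:60],
                marker[31:60, 1:30], marker[31:60, 31:60])
  parts <- vapply(tiles, function(tl) {
    intensity_per_cell(tl, make_labels(1, c(30, 30)),
                       threshold = 5)$integrated_density
  }, numeric(1))
  expect_equal(sum(parts), whole, tolerance = 1e-10)
})

test_that("negative-control threshold matches a sort-based quantile oracle", {
  expect_equal(threshold_from_negative_control(matrix(10, 5, 5)), 10)
  set.seed(8)
  ctrl <- matrix(pmax(rnorm(1e6, 100, 5), 0), 1000, 1000)
  th <- threshold_from_negative_control(ctrl, q = 0.999)
  srt <- sort(as.numeric(ctrl))
  emp <- srt[ceiling(0.999 * length(srt))]
  expect_lt(abs(th - emp), 1)
  expect_equal(threshold_from_negative_control(ctrl, q = 1), max(ctrl))
})

test_that("image sampling is deterministic, exhaustive at k = n, uniform", {
  imgs <- sprintf("img%02d", 1:20)
  s1 <- sample_images(imgs, 5, seed = 77)
  s2 <- sample_images(imgs, 5, seed = 77)
  expect_identical(s1, s2)
  expect_length(unique(s1), 5)
  expect_identical(sample_images(imgs, 20, seed = 1), imgs)
  expect_error(sample_images(imgs, 21, seed = 1), "cannot sample")
  # uniform inclusion: each of 10 images picked ~ half the time at k = 5
  ten <- sprintf("i%d", 1:10)
  counts <- setNames(numeric(10), ten)
  for (s in 1:1000) {
    sel <- sample_images(ten, 5, seed = s)
    counts[sel] <- counts[sel] + 1
  }
  expect_true(all(abs(counts / 1000 - 0.5) < 0.05))
})

test_that("per-sample aggregation averages records with sample-level n", {
  recs <- data.frame(image_id = c("a", "b", "c"),
                     integrated_density = c(20, 40, 12),
                     cell_count = c(10, 10, 4),
                     intensity_per_cell = c(2, 4, 3),
                     threshold = 1)
  meta <- data.frame(image_id = c("a", "b", "c", "d"),
                     sample_id = c("s1", "s1", "s2", "s3"),
                     group = c("young", "young", "aged", "aged"),
                     group_code = c(0, 0, 2, 2))
  expect_warning(agg <- aggregate_intensity_by_sample(recs, meta), "s3")
  expect_equal(agg$mean_intensity_per_cell[agg$sample_id == "s1"], 3)
  expect_equal(agg$mean_intensity_per_cell[agg$sample_id == "s2"], 3)
  expect_equal(nrow(agg), 2)
})

test_that("image-route intensities recover the programmed marker law", {
  cfg <- cohort_config(n_samples_per_group = 1L, images_per_sample = 2L,
                       intensity_noise_sd = 0, marker_background_sd = 0,
                       marker_intensity_slope_vs_eccentricity = -100,
                       seed = 5L)
  dir <- file.path(tempdir(), "intensity_exact")
  res <- generate_cohort(cfg, dir)
  tr <- res$truth_nuclei
  for (i in seq_len(nrow(res$metadata))) {
    row <- res$metadata[i, ]
    dapi <- read_image(file.path(dir, row$dapi_path))
    seg <- segment_nuclei(dapi, image_id = row$image_id)
    marker <- read_image(file.path(dir, row$marker_path)) * cfg$marker_gain
    rec <- intensity_per_cell(marker, seg, threshold = 0.5)
    tr_img <- tr[tr$image_id == row$image_id, ]
    expect_equal(rec$cell_count, nrow(tr_img))
    expect_equal(rec$integrated_density, sum(tr_img$marker_true),
                 tolerance = 1e-4)
    expect_equal(rec$intensity_per_cell,
                 sum(tr_img$marker_true) / nrow(tr_img), tolerance = 1e-4)
  }
})

test_that("group intensity difference is recovered without material bias", {
  cfg <- cohort_config()
  diffs <- numeric(200)
  for (r in 1:200) {
    sim <- simulate_cohort_truth(cfg, seed = 9000 + r)
    nuc <- sim$nuclei
    per_img <- aggregate(list(ipc = nuc$marker_true),
                         by = nuc[c("image_id", "sample_id", "group")],
                         FUN = mean)
    per_samp <- aggregate(list(m = per_img$ipc),
                          by = per_img[c("sample_id", "group")], FUN = mean)
    diffs[r] <- mean(per_samp$m[per_samp$group == "young"]) -
      mean(per_samp$m[per_samp$group == "aged"])
  }
  slope <- cfg$marker_intensity_slope_vs_eccentricity
  truth_diff <- (cfg$marker_intensity_intercept_by_group[1] +
                   slope * cfg$eccentricity_mean_by_group[1]) -
    (cfg$marker_intensity_intercept_by_group[3] +
       slope * cfg$eccentricity_mean_by_group[3])
  expect_lt(abs(mean(diffs) - truth_diff) / abs(truth_diff), 0.05)
})
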