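test_that("segmentation finds disjoint bright objects and flags empty images", {
  img <- matrix(0.05, 200, 200)
  img[20:40, 20:40] <- 0.8
  img[100:130, 60:90] <- 0.8
  img[150:170, 150:180] <- 0.8
  seg <- segment_nuclei(img)
  expect_equal(seg$n, 3)
  expect_warning(empty <- segment_nuclei(matrix(0.5, 50, 50)), "uniform")
  expect_equal(empty$n, 0)
  # area filter removes too-small and too-large objects
  seg2 <- segment_nuclei(img, min_area = 500, max_area = 900)
  expect_equal(seg2$n, 1)
})

test_that("segmentation recovers generated nuclei and their centroids", {
  ni <- generate_nuclei_image(25, 0.7, 0.05, seed = 3,
                              image_size = c(512L, 512L))
  seg <- segment_nuclei(ni$image, image_id = "gen")
  expect_equal(seg$n, 25)
  f <- measure_features(seg)
  d <- vapply(seq_len(25), function(k) {
    min(sqrt((f$centroid_x - ni$truth$cx[k])^2 +
             (f$centroid_y - ni$truth$cy[k])^2))
  }, numeric(1))
  expect_lt(max(d), 2)
})

test_that("the descriptor vector has exactly 53 named features, all finite", {
  shapes <- list(rasterize_disk(15), rasterize_ellipse(20, 8, 30),
                 rasterize_ellipse(12, 11, -60))
  for (m in shapes) {
    f <- measure_features(as_labels(m))
    vals <- f[, nuclear_feature_names]
    expect_identical(names(vals), nuclear_feature_names)
    expect_length(nuclear_feature_names, 53L)
    expect_true(all(is.finite(as.numeric(vals[1, ]))))
  }
})

test_that("a rasterized disk is round by every descriptor", {
  f <- measure_features(as_labels(rasterize_disk(40)))
  expect_lte(f$eccentricity, 0.08)
  expect_gte(f$solidity, 0.98)
  expect_gte(f$form_factor, 0.92)
  expect_lte(f$form_factor, 1)
  expect_equal(f$euler_number, 1)
  expect_equal(f$area, sum(rasterize_disk(40)))
  expect_equal(f$compactness, 1, tolerance = 0.05)
  expect_equal(f$max_radius, 40, tolerance = 1.5)
})

test_that("a 2:1 rasterized ellipse has the analytic eccentricity", {
  f <- measure_features(as_labels(rasterize_ellipse(40, 20, 37)))
  expect_lt(abs(f$eccentricity - sqrt(3) / 2), 0.02)
  expect_lt(abs(f$orientation - 37), 2)
  expect_equal(f$major_axis_length / f$minor_axis_length, 2, tolerance = 0.05)
})

test_that("moment features match the brute-force per-pixel oracle", {
  set.seed(33)
  shapes <- list(
    rasterize_disk(9),
    rasterize_ellipse(14, 6, 25),
    rasterize_ellipse(10, 9, -80),
    matrix(runif(144) > 0.4, 12, 12)  # amorphous blob
  )
  for (m in shapes) {
    if (sum(m) < 3) next
    ora <- oracle_moment_ellipse(m)
    e <- eccentricity_from_moments(m)
    expect_lt(abs(as.numeric(e) - ora$ecc), 1e-10)
    f <- measure_features(as_labels(m))
    expect_lt(abs(f$centroid_x - ora$cx), 1e-10)
    expect_lt(abs(f$centroid_y - ora$cy), 1e-10)
    expect_lt(abs(f$major_axis_length - ora$major), 1e-10)
    expect_lt(abs(f$minor_axis_length - ora$minor), 1e-10)
  }
})

test_that("eccentricity increases strictly as the axis ratio shrinks", {
  ratios <- c(1.0, 0.8, 0.6, 0.4, 0.2)
  eccs <- vapply(ratios, function(ba) {
    as.numeric(eccentricity_from_moments(
      rasterize_ellipse(40, max(1, round(40 * ba)))))
  }, numeric(1))
  expect_true(all(diff(eccs) > 0))
})

test_that("collinear objects hit the degenerate-eccentricity convention", {
  line <- matrix(FALSE, 10, 10); line[5, 2:9] <- TRUE
  e <- eccentricity_from_moments(line)
  expect_true(attr(e, "degenerate"))
  expect_lt(as.numeric(e), 1)
  expect_gt(as.numeric(e), 0.999)
  f <- measure_features(as_labels(line))
  expect_gt(f$minor_axis_length, 0)
})

test_that("single-pixel objects use finite conventions", {
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_error(eccentricity_from_moments(px), "at least 2")
  f <- measure_features(as_labels(px))
  expect_equal(f$perimeter, 1)
  expect_true(all(is.finite(as.numeric(f[, nuclear_feature_names][1, ]))))
})

test_that("features are invariant under rotation by 90 degrees", {
  m <- rasterize_ellipse(22, 9, 15)
  f1 <- measure_features(as_labels(m))
  f2 <- measure_features(as_labels(t(m)[ncol(m):1, ]))  # 90 deg rotation
  inv <- c("area", "eccentricity", "solidity", "form_factor", "perimeter",
           grep("^zernike", nuclear_feature_names, value = TRUE))
  for (v in inv) {
    expect_lt(abs(f1[[v]] - f2[[v]]) / max(abs(f1[[v]]), 1e-12), 0.02)
  }
})

test_that("non-centroid features are exactly invariant under translation", {
  m <- rasterize_ellipse(15, 7, 40)
  big1 <- matrix(FALSE, 80, 80); big1[3:(2 + nrow(m)), 3:(2 + ncol(m))] <- m
  big2 <- matrix(FALSE, 80, 80); big2[31:(30 + nrow(m)), 40:(39 + ncol(m))] <- m
  f1 <- measure_features(as_labels(big1))
  f2 <- measure_features(as_labels(big2))
  vars <- setdiff(nuclear_feature_names, c("centroid_x", "centroid_y"))
  expect_equal(as.numeric(f1[, vars]), as.numeric(f2[, vars]),
               tolerance = 1e-12)
})

test_that("a ring object has Euler number zero", {
  ring <- rasterize_disk(15) & !rasterize_disk(7, pad = 11)
  f <- measure_features(as_labels(ring))
  expect_equal(f$euler_number, 0)
})

test_that("per-sample aggregation averages images then samples", {
  f1 <- measure_features(as_labels(rasterize_ellipse(20, 10), "imgA"))
  f2 <- measure_features(as_labels(rasterize_ellipse(20, 16), "imgB"))
  feats <- rbind(f1, f2)
  meta <- data.frame(image_id = c("imgA", "imgB"),
                     sample_id = "s1", group = "young", group_code = 0)
  agg <- aggregate_nuclei_by_sample(feats, meta)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$n_nuclei, 2)
  expect_equal(agg$eccentricity,
               mean(c(f1$eccentricity, f2$eccentricity)), tolerance = 1e-12)
  # samples in the metadata without nuclei are dropped with a warning
  meta2 <- rbind(meta, data.frame(image_id = "imgC", sample_id = "s2",
                                  group = "aged", group_code = 2))
  expect_warning(agg2 <- aggregate_nuclei_by_sample(feats, meta2), "s2")
  expect_equal(agg2$sample_id, "s1")
})

test_that("sample-mean eccentricity stays within 2 SE of generator truth", {
  fx <- default_cohort_fixture()
  agg <- aggregate_nuclei_by_sample(fx$features, fx$metadata)
  truth <- fx$truth_nuclei
  for (g in unique(agg$group)) {
    tg <- truth$ecc_true[truth$group == g]
    est <- mean(agg$eccentricity[agg$group == g])
    se <- sd(tg) / sqrt(length(tg))
    expect_lt(abs(est - mean(tg)), 2 * se)
  }
})
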