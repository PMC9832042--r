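test_that("z-scoring standardizes columns and drops constant ones", {
  expect_equal(as.numeric(zscore_features(cbind(v = c(1, 2, 3)))$x),
               c(-1, 0, 1))
  m <- cbind(a = rnorm(20), b = rep(4, 20), c = rnorm(20, 10, 3))
  expect_warning(zs <- zscore_features(m), "b")
  expect_identical(colnames(zs$x), c("a", "c"))
  expect_identical(zs$dropped, "b")
  expect_error(zscore_features(matrix(1, 1, 3)), "at least 2")

  set.seed(10)
  big <- matrix(rnorm(100 * 53), 100, 53,
                dimnames = list(NULL, paste0("f", 1:53)))
  z <- zscore_features(big)$x
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
})

test_that("PCA of a single varying column loads it perfectly", {
  m <- cbind(x = rnorm(30), y = rep(0, 30), z = rep(0, 30))
  p <- run_pca(m, k_top = 3)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  expect_equal(abs(p$loadings["x", 1]), 1, tolerance = 1e-12)
})

test_that("loadings equal brute-force variable-score correlations", {
  set.seed(11)
  m <- matrix(rnorm(60 * 12), 60, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  z <- zscore_features(m)$x
  p <- run_pca(z)
  for (j in 1:5) {
    for (v in colnames(z)) {
      expect_lt(abs(p$loadings[v, j] - cor(m[, v], p$scores[, j])), 1e-10)
    }
  }
  expect_true(all(p$loadings >= -1 - 1e-12 & p$loadings <= 1 + 1e-12))
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-10)
})

test_that("scores and rotation reconstruct the centered matrix", {
  set.seed(12)
  m <- matrix(rnorm(40 * 8), 40, 8)
  p <- run_pca(m)
  centered <- sweep(m, 2, colMeans(m))
  expect_lt(max(abs(centered - p$scores %*% t(p$rotation))), 1e-8)
})

test_that("loadings obey the eigenvalue closed form on z-scored input", {
  set.seed(13)
  m <- matrix(rnorm(50 * 6), 50, 6)
  m[, 2] <- m[, 1] * 0.7 + rnorm(50, 0, 0.4)
  z <- zscore_features(m)$x
  p <- run_pca(z)
  n <- nrow(z)
  sv <- svd(sweep(z, 2, colMeans(z)))
  lam <- sv$d^2 / (n - 1)
  closed <- sweep(sv$v, 2, sqrt(lam), `*`)  # eigvec * sqrt(eigenvalue), sd = 1
  for (j in seq_len(ncol(closed))) {
    diff <- min(max(abs(p$loadings[, j] - closed[, j])),
                max(abs(p$loadings[, j] + closed[, j])))  # sign-free
    expect_lt(diff, 1e-8)
  }
})

test_that("PC sign convention makes the leading loading positive", {
  set.seed(14)
  m <- matrix(rnorm(30 * 5), 30, 5)
  p <- run_pca(m)
  for (j in seq_len(ncol(p$loadings))) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("silhouette is near zero for identical groups, high for split ones", {
  null_ok <- 0
  for (r in 1:100) {
    set.seed(2000 + r)
    sc <- matrix(rnorm(60 * 2), 60, 2)
    g <- rep(c("a", "b"), each = 30)
    s <- group_separation(sc, g)$silhouette
    if (abs(s) < 0.15) null_ok <- null_ok + 1
  }
  expect_gte(null_ok, 90)

  set.seed(15)
  sc2 <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 5), 30, 2))
  s2 <- group_separation(sc2, rep(c("a", "b"), each = 30))$silhouette
  expect_gt(s2, 0.5)
})

test_that("small groups are excluded and singletons leave separation undefined", {
  sc <- matrix(rnorm(22), 11, 2)
  g <- c(rep("a", 8), rep("b", 2), "c")
  expect_warning(out <- group_separation(sc, g), "excluding")
  expect_true(is.na(out$silhouette))
  expect_equal(rownames(out$centroids), "a")
})

test_that("trend regression is exact on a deterministic outcome", {
  code <- rep(0:2, each = 4)
  out <- regress_trend(2 * code + 1, code)
  sl <- out$coefficients
  expect_equal(sl$estimate[sl$term == "group_code"], 2, tolerance = 1e-12)
  expect_equal(out$r_squared, 1, tolerance = 1e-12)
  expect_error(regress_trend(c(1, 2, 3), c(0, 0, 0)), "rank-deficient")
})

test_that("eccentricity age trend is detected at the default effect size", {
  cfg <- cohort_config()
  sim <- simulate_cohort_truth(cfg, seed = 31)
  per_samp <- aggregate(list(e = sim$nuclei$ecc_true),
                        by = sim$nuclei[c("sample_id", "group_code")],
                        FUN = mean)
  out <- regress_trend(per_samp$e, per_samp$group_code)
  sl <- out$coefficients
  expect_gt(sl$estimate[sl$term == "group_code"], 0)
  expect_lt(sl$p_value[sl$term == "group_code"], 0.05)
})

test_that("permuted group labels give null trend coverage", {
  cfg <- cohort_config()
  sim <- simulate_cohort_truth(cfg, seed = 32)
  per_samp <- aggregate(list(e = sim$nuclei$ecc_true),
                        by = sim$nuclei[c("sample_id", "group_code")],
                        FUN = mean)
  covered <- 0
  for (r in 1:100) {
    set.seed(3000 + r)
    perm <- sample(per_samp$group_code)
    ci <- regress_trend(per_samp$e, perm)$coefficients
    lo <- ci$ci_lower[ci$term == "group_code"]
    hi <- ci$ci_upper[ci$term == "group_code"]
    if (lo <= 0 && hi >= 0) covered <- covered + 1
  }
  expect_gte(covered, 90)
})

test_that("marker regression separates exact eccentricity dependence from age", {
  set.seed(16)
  ecc <- runif(12, 0.5, 0.9)
  age <- rep(0:2, each = 4)
  marker <- 10 - 3 * ecc
  out <- regress_marker_on_morphology(marker, ecc, age)
  expect_equal(out$r_squared, 1, tolerance = 1e-10)
  expect_lt(out$partial_r2[["age"]], 1e-10)
  cf <- out$coefficients
  expect_equal(cf$estimate[cf$term == "eccentricity"], -3, tolerance = 1e-8)
})

test_that("partial R2 decomposition is exact and collinearity is refused", {
  set.seed(17)
  age <- rep(0:2, each = 5)
  ecc <- 0.6 + 0.05 * age + rnorm(15, 0, 0.05)
  marker <- 1000 - 150 * age - 300 * ecc + rnorm(15, 0, 30)
  out <- regress_marker_on_morphology(marker, ecc, age)
  r2_age_only <- summary(lm(marker ~ age))$r.squared
  expect_equal(out$partial_r2[["eccentricity"]],
               out$r_squared - r2_age_only, tolerance = 1e-12)
  expect_gte(out$partial_r2[["eccentricity"]], 0)
  expect_lte(out$r_squared, 1)
  expect_error(regress_marker_on_morphology(marker, ecc, ecc), "collinear")
})
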