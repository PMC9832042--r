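#' Z-score a feature matrix by column
#'
#' Per-column standardization `(x - mean) / sd` (denominator `n - 1`),
#' used before PCA because the descriptors mix pixel, squared-pixel and
#' dimensionless units. Zero-variance columns carry no shape information
#' and are dropped with a warning.
#'
#' @param x Numeric matrix or data frame of numeric features (rows =
#'   observations).
#' @return List with `x` (z-scored matrix), `center`, `scale`, and
#'   `dropped` (names of zero-variance columns).
#' @export
zscore_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to z-score", call. = FALSE)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(x)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  list(x = z, center = mu[keep], scale = sdv[keep],
       dropped = colnames(x)[!keep])
}

#' Principal-component analysis with loadings as variable-score correlations
#'
#' PCA by singular value decomposition of the column-centered matrix. The
#' loading matrix is defined as the Pearson correlation between each
#' original variable and each component score, and variables are ranked per
#' component by absolute loading to give the top-`k_top` contributor lists.
#' Each component is oriented so its largest-|loading| variable loads
#' positively (SVD signs are otherwise arbitrary).
#'
#' @param x Z-scored feature matrix (see [zscore_features()]), >= 3 rows.
#' @param k_top Contributors to report per component (default 10).
#' @param n_components Components to retain (default all).
#' @return A `pca_output`: list with `scores`, `rotation` (eigenvector
#'   basis), `loadings` (variables x components, correlations in
#'   `[-1, 1]`), `explained_variance` (fractions, non-increasing),
#'   `top_contributors` (list per component: data frame of variable,
#'   loading, rank), `center` used.
#' @export
run_pca <- function(x, k_top = 10, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 rows for PCA", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  d <- sv$d
  ncomp <- min(n_components %||% length(d), length(d))
  keep <- seq_len(ncomp)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d[keep], ncomp, ncomp)
  rotation <- sv$v[, keep, drop = FALSE]
  evr <- d^2 / sum(d^2)
  # loadings = correlation of raw columns with scores; guard constant scores
  loadings <- matrix(0, ncol(x), ncomp,
                     dimnames = list(colnames(x), paste0("PC", keep)))
  for (j in keep) {
    sj <- scores[, j]
    if (stats::sd(sj) > 0) {
      loadings[, j] <- apply(x, 2, function(col) {
        if (stats::sd(col) == 0) 0 else stats::cor(col, sj)
      })
    }
  }
  # deterministic sign: top-|loading| variable of each PC loads positively
  for (j in keep) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
      rotation[, j] <- -rotation[, j]
    }
  }
  colnames(scores) <- paste0("PC", keep)
  rownames(rotation) <- colnames(x)
  colnames(rotation) <- paste0("PC", keep)
  top <- lapply(keep, function(j) {
    ord <- order(abs(loadings[, j]), decreasing = TRUE)
    k <- min(k_top, length(ord))
    data.frame(variable = rownames(loadings)[ord[seq_len(k)]],
               loading = loadings[ord[seq_len(k)], j],
               rank = seq_len(k), row.names = NULL)
  })
  names(top) <- paste0("PC", keep)
  structure(list(scores = scores, rotation = rotation, loadings = loadings,
                 explained_variance = evr[keep], top_contributors = top,
                 center = ctr),
            class = "pca_output")
}

#' Group separation on the first two principal components
#'
#' Per-group centroids and 95% confidence ellipses on PC1-PC2, summarized
#' by the mean silhouette coefficient of the group labeling under Euclidean
#' distance in the PC1-PC2 plane. Groups with fewer than 3 observations are
#' excluded with a warning; with a single usable group the silhouette is
#' undefined (`NA`).
#'
#' @param scores Score matrix (uses the first two columns).
#' @param labels Group label per row.
#' @return List with `centroids`, `ellipses` (per group: center, covariance,
#'   95% ellipse semi-axes and angle), `silhouette` (mean), `n_per_group`.
#' @export
group_separation <- function(scores, labels) {
  scores <- as.matrix(scores)
  s2 <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small) > 0) {
    warning(sprintf("excluding group(s) with < 3 observations: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
  }
  keep <- !(labels %in% small)
  s2 <- s2[keep, , drop = FALSE]
  labels <- labels[keep]
  groups <- unique(labels)
  cent <- t(vapply(groups, function(g) colMeans(s2[labels == g, , drop = FALSE]),
                   numeric(ncol(s2))))
  rownames(cent) <- groups
  ellipses <- lapply(groups, function(g) {
    pts <- s2[labels == g, , drop = FALSE]
    cv <- stats::cov(pts)
    eg <- eigen(cv, symmetric = TRUE)
    r <- sqrt(stats::qchisq(0.95, df = 2))
    list(center = colMeans(pts), cov = cv,
         semi_axes = r * sqrt(pmax(eg$values, 0)),
         angle_deg = atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi)
  })
  names(ellipses) <- groups
  sil <- NA_real_
  if (length(groups) >= 2) {
    si <- cluster::silhouette(as.integer(factor(labels)), stats::dist(s2))
    sil <- mean(si[, "sil_width"])
  } else {
    warning("separation undefined with a single group", call. = FALSE)
  }
  list(centroids = cent, ellipses = ellipses, silhouette = sil,
       n_per_group = as.list(table(labels)))
}

regression_output <- function(fit, partial_r2 = NULL) {
  sm <- summary(fit)
  ci <- stats::confint(fit)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    se = sm$coefficients[, "Std. Error"],
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    p_value = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL)
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 partial_r2 = partial_r2, fit = fit),
            class = "regression_output")
}

#' Ordinary least-squares age trend
#'
#' Sample-level OLS of an outcome (roughness index, mean eccentricity,
#' per-cell intensity) on the ordinal age-group code (young = 0,
#' middle = 1, aged = 2). Degrees of freedom are sample-level by
#' construction; nuclei are never pooled across samples here.
#'
#' @param outcome Numeric outcome, one value per sample.
#' @param group_code Ordinal group code per sample.
#' @return A `regression_output`: `coefficients` (term, estimate, se, CI,
#'   p), `r_squared`, `fit`. The slope row is `group_code`. When residual
#'   degrees of freedom are zero the CI is degenerate and a warning flags it.
#' @export
regress_trend <- function(outcome, group_code) {
  if (length(outcome) != length(group_code)) {
    stop("`outcome` and `group_code` lengths differ", call. = FALSE)
  }
  if (length(outcome) < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(unique(group_code)) < 2) {
    stop("rank-deficient design: a single group level", call. = FALSE)
  }
  df <- data.frame(outcome = outcome, group_code = as.numeric(group_code))
  fit <- stats::lm(outcome ~ group_code, data = df)
  if (stats::df.residual(fit) == 0) {
    warning("zero residual degrees of freedom: CI and p are degenerate",
            call. = FALSE)
  }
  regression_output(fit)
}

#' Marker expression regressed on age and nuclear morphology
#'
#' Additive two-predictor OLS `marker ~ age + eccentricity` at the sample
#' level, quantifying the contribution of nuclear shape to marker
#' expression beyond chronological age. The independent contribution of
#' each predictor is its partial R-squared, the increment in R-squared when
#' that predictor is added last, so
#' `R2(full) - R2(age only) = partial R2(eccentricity)` exactly.
#'
#' @param marker Marker intensity per sample.
#' @param eccentricity Mean nuclear eccentricity per sample.
#' @param age Age (ordinal code or years/months) per sample.
#' @return A `regression_output` with `partial_r2` (named: age,
#'   eccentricity) alongside coefficients, CIs, p-values and `r_squared`.
#' @export
regress_marker_on_morphology <- function(marker, eccentricity, age) {
  n <- length(marker)
  if (n < 5) stop("need at least 5 samples", call. = FALSE)
  if (length(eccentricity) != n || length(age) != n) {
    stop("predictor lengths differ from outcome", call. = FALSE)
  }
  if (stats::sd(age) == 0 || stats::sd(eccentricity) == 0) {
    stop("constant predictor: design is rank deficient", call. = FALSE)
  }
  if (abs(stats::cor(age, eccentricity)) > 0.99) {
    stop("collinear predictors: |cor(age, eccentricity)| > 0.99",
         call. = FALSE)
  }
  df <- data.frame(marker = marker, age = as.numeric(age),
                   eccentricity = eccentricity)
  full <- stats::lm(marker ~ age + eccentricity, data = df)
  r2_full <- summary(full)$r.squared
  r2_age <- summary(stats::lm(marker ~ age, data = df))$r.squared
  r2_ecc <- summary(stats::lm(marker ~ eccentricity, data = df))$r.squared
  partial <- c(age = r2_full - r2_ecc, eccentricity = r2_full - r2_age)
  regression_output(full, partial_r2 = partial)
}
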