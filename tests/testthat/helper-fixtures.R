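# Shared fixtures and independent oracles. Everything here is built in code
# at test time; oracles are deliberately naive (double loops, raw normal
# equations) and independent of the package's computational paths.

rasterize_disk <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

rasterize_ellipse <- function(a, b, theta_deg = 0, pad = 3) {
  n <- 2 * (a + pad) + 1
  c0 <- a + pad + 1
  th <- theta_deg * pi / 180
  outer(1:n, 1:n, function(i, j) {
    x <- j - c0; y <- i - c0
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

# Wrap a single-object binary mask as a labeled_nuclei object.
as_labels <- function(mask, image_id = "fixture") {
  structure(list(labels = matrix(as.integer(mask), nrow(mask)),
                 n = 1L, border_touching = FALSE, image_id = image_id),
            class = "labeled_nuclei")
}

# Brute-force per-pixel second-central-moment oracle: explicit double loop.
oracle_moment_ellipse <- function(mask) {
  sx <- 0; sy <- 0; n <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) { sx <- sx + j; sy <- sy + i; n <- n + 1 }
    }
  }
  cx <- sx / n; cy <- sy / n
  m20 <- 0; m02 <- 0; m11 <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        m20 <- m20 + (j - cx)^2
        m02 <- m02 + (i - cy)^2
        m11 <- m11 + (j - cx) * (i - cy)
      }
    }
  }
  m20 <- m20 / n; m02 <- m02 / n; m11 <- m11 / n
  tr <- m20 + m02
  disc <- sqrt((m20 - m02)^2 / 4 + m11^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  list(cx = cx, cy = cy, lambda1 = l1, lambda2 = l2,
       ecc = sqrt(1 - l2 / l1),
       major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

# Brute-force quartic least squares on the raw 5-column Vandermonde,
# solved by QR (the raw normal equations overflow double precision
# conditioning for pixel-scale abscissae).
oracle_quartic_fit <- function(x, y) {
  V <- outer(x, 0:4, `^`)
  beta <- qr.coef(qr(V), y)
  fitted <- as.numeric(V %*% beta)
  list(coefficients = as.numeric(beta), fitted = fitted,
       residuals = y - fitted)
}

# Default synthetic cohort (the study conditions), built once per test run
# and cached: images on disk plus measured nuclear features.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_fixture <- function() {
  if (!is.null(.cohort_cache$res)) return(.cohort_cache$res)
  cfg <- cohort_config(seed = 1L)
  dir <- file.path(tempdir(), "cartimorph_default_cohort")
  gen <- generate_cohort(cfg, dir)
  feats <- do.call(rbind, lapply(seq_len(nrow(gen$metadata)), function(i) {
    img <- read_image(file.path(dir, gen$metadata$dapi_path[i]))
    seg <- segment_nuclei(img, image_id = gen$metadata$image_id[i])
    if (seg$n == 0) return(NULL)
    measure_features(seg)
  }))
  res <- list(config = cfg, dir = dir, metadata = gen$metadata,
              truth_nuclei = gen$truth_nuclei,
              truth_surfaces = gen$truth_surfaces, features = feats)
  .cohort_cache$res <- res
  res
}
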