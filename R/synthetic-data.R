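#' Configuration for a synthetic cartilage-imaging cohort
#'
#' Bundles every parameter of the synthetic cohort generator: cohort layout
#' (age groups, samples per group, images per sample), cartilage surface
#' geometry and per-group roughness amplitude, the nuclear eccentricity
#' distribution per group, and the marker-channel intensity model
#' `intensity = intercept(group) + slope * eccentricity + noise`.
#'
#' Age groups are ordered and coded ordinally (young = 0, middle = 1,
#' aged = 2). The defaults encode the study conditions the package is
#' validated under: aged cartilage has a rougher surface (larger perturbation
#' amplitude), more elongated nuclei (higher eccentricity mean, about a
#' 2 pooled-SD young-to-aged shift), and lower marker expression (smaller
#' intercept, negative slope versus eccentricity).
#'
#' @param n_samples_per_group Independent samples (animals) per age group.
#' @param groups Ordered character vector of age-group labels.
#' @param images_per_sample Microscopy fields acquired per sample.
#' @param image_size Height and width of nuclei/marker images, pixels.
#' @param seed Integer seed; an identical config (seed included) regenerates
#'   a bit-identical cohort.
#' @param roughness_amplitude_by_group Mean absolute surface perturbation,
#'   pixels, one value per group.
#' @param eccentricity_mean_by_group Mean nuclear eccentricity per group,
#'   each in `[0, 1)`.
#' @param eccentricity_sd Within-group SD of nuclear eccentricity.
#' @param marker_intensity_slope_vs_eccentricity Arbitrary units of marker
#'   intensity per unit eccentricity (negative by default).
#' @param marker_intensity_intercept_by_group Marker intensity intercept per
#'   group, arbitrary units.
#' @param intensity_noise_sd SD of per-nucleus marker intensity noise, a.u.
#' @param nuclei_per_image Inclusive integer range of nuclei per image.
#' @param min_nucleus_separation Minimum gap between nucleus boundaries, px.
#' @param semi_major_range Range of nucleus semi-major axis lengths, px.
#' @param nucleus_irregularity SD of the zero-mean radial harmonic boundary
#'   perturbation, as a fraction of the local ellipse radius (0 = perfect
#'   ellipses). Real nuclei are not perfect ellipses; a small irregularity
#'   decorrelates contour-sensitive descriptors (form factor, Zernike
#'   magnitudes) from the elongation axis, as in real morphometry data.
#' @param surface_size Height and width of surface masks, pixels.
#' @param surface_baseline Quartic baseline coefficients `c0..c4` of the
#'   smooth articular surface, row units as a function of column index
#'   (`NULL` for a gentle default arc).
#' @param surface_smooth Moving-average window (columns) applied to the
#'   surface perturbation; 1 disables smoothing.
#' @param marker_gain Arbitrary-unit value mapped to pixel value 1.0 in the
#'   stored marker TIFFs.
#' @param marker_background_sd Per-pixel background noise SD in the marker
#'   channel, arbitrary units.
#'
#' @return A named list of class `cohort_config`.
#' @seealso [generate_cohort()], [simulate_cohort_truth()]
#' @export
cohort_config <- function(n_samples_per_group = 5L,
                          groups = c("young", "middle", "aged"),
                          images_per_sample = 5L,
                          image_size = c(256L, 256L),
                          seed = 1L,
                          roughness_amplitude_by_group = c(1, 2, 4),
                          eccentricity_mean_by_group = c(0.625, 0.70, 0.775),
                          eccentricity_sd = 0.075,
                          marker_intensity_slope_vs_eccentricity = -400,
                          marker_intensity_intercept_by_group = c(1200, 1000, 800),
                          intensity_noise_sd = 50,
                          nuclei_per_image = c(6L, 8L),
                          min_nucleus_separation = 6,
                          semi_major_range = c(12, 18),
                          nucleus_irregularity = 0.07,
                          surface_size = c(160L, 360L),
                          surface_baseline = NULL,
                          surface_smooth = 3L,
                          marker_gain = 65535,
                          marker_background_sd = 0.05) {
  stopifnot_scalar_count(n_samples_per_group, "n_samples_per_group")
  stopifnot_scalar_count(images_per_sample, "images_per_sample")
  if (length(groups) < 1L) stop("need at least one group", call. = FALSE)
  ng <- length(groups)
  for (nm in c("roughness_amplitude_by_group", "eccentricity_mean_by_group",
               "marker_intensity_intercept_by_group")) {
    v <- get(nm)
    if (length(v) != ng) {
      stop(sprintf("`%s` must have one value per group", nm), call. = FALSE)
    }
  }
  if (any(eccentricity_mean_by_group < 0 | eccentricity_mean_by_group >= 1)) {
    stop("eccentricity means must lie in [0, 1)", call. = FALSE)
  }
  if (eccentricity_sd <= 0) stop("`eccentricity_sd` must be > 0", call. = FALSE)
  if (any(nuclei_per_image <= 0) || length(nuclei_per_image) != 2L ||
      nuclei_per_image[1] > nuclei_per_image[2]) {
    stop("`nuclei_per_image` must be an increasing positive range", call. = FALSE)
  }
  if (is.null(surface_baseline)) {
    surface_baseline <- default_surface_baseline(surface_size[2])
  }
  if (length(surface_baseline) != 5L) {
    stop("`surface_baseline` must hold 5 quartic coefficients c0..c4",
         call. = FALSE)
  }
  cfg <- list(
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = as.character(groups),
    images_per_sample = as.integer(images_per_sample),
    image_size = as.integer(image_size),
    seed = as.integer(seed),
    roughness_amplitude_by_group = as.numeric(roughness_amplitude_by_group),
    eccentricity_mean_by_group = as.numeric(eccentricity_mean_by_group),
    eccentricity_sd = as.numeric(eccentricity_sd),
    marker_intensity_slope_vs_eccentricity =
      as.numeric(marker_intensity_slope_vs_eccentricity),
    marker_intensity_intercept_by_group =
      as.numeric(marker_intensity_intercept_by_group),
    intensity_noise_sd = as.numeric(intensity_noise_sd),
    nuclei_per_image = as.integer(nuclei_per_image),
    min_nucleus_separation = as.numeric(min_nucleus_separation),
    semi_major_range = as.numeric(semi_major_range),
    nucleus_irregularity = as.numeric(nucleus_irregularity),
    surface_size = as.integer(surface_size),
    surface_baseline = as.numeric(surface_baseline),
    surface_smooth = as.integer(surface_smooth),
    marker_gain = as.numeric(marker_gain),
    marker_background_sd = as.numeric(marker_background_sd)
  )
  class(cfg) <- "cohort_config"
  cfg
}

# Gentle quartic arc spanning the mask width: shallow in the middle, rising
# toward both edges, mimicking the curvature of a tibial plateau section.
default_surface_baseline <- function(width) {
  x0 <- (width + 1) / 2
  s <- width / 2
  # y = 50 + 30 u^2 + 10 u^4 with u = (x - x0)/s, expanded to raw powers of x
  expand <- function(coef_u, k) {
    # coef_u * ((x - x0)/s)^k as raw-coefficient vector of length 5
    p <- 1
    shift <- c(-x0 / s, 1 / s)
    for (i in seq_len(k)) p <- convolve_poly(p, shift)
    out <- numeric(5)
    out[seq_along(p)] <- p * coef_u
    out
  }
  c(50, 0, 0, 0, 0) + expand(30, 2) + expand(10, 4)
}

# Polynomial product by coefficient convolution (ascending powers).
convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

eval_quartic <- function(coef, x) {
  coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3 + coef[5] * x^4
}

#' Generate a binary cartilage surface mask with known roughness
#'
#' Draws a tissue mask whose top surface is a smooth quartic baseline plus a
#' zero-mean Gaussian per-column perturbation. The perturbation SD is scaled
#' so its expected mean absolute value equals `roughness_amplitude`; the
#' realized mean absolute perturbation is stored as ground truth. An optional
#' short moving average gives the perturbation tissue-scale correlation.
#'
#' @param width,height Mask dimensions in pixels (columns, rows).
#' @param baseline Quartic coefficients `c0..c4`; surface row as a function
#'   of column index (1-based), rows increasing downward.
#' @param roughness_amplitude Target mean absolute perturbation, pixels.
#' @param seed Integer seed.
#' @param smooth Moving-average window in columns (1 = white noise).
#' @return A list with `mask` (logical matrix, `TRUE` = tissue, filled below
#'   the surface), `surface_row` (integer row of the surface per column), and
#'   `truth` (one-row data frame with target and realized amplitude).
#' @export
generate_surface_mask <- function(width, height, baseline, roughness_amplitude,
                                  seed, smooth = 1L) {
  stopifnot_scalar_count(width, "width")
  stopifnot_scalar_count(height, "height")
  if (roughness_amplitude < 0) stop("`roughness_amplitude` must be >= 0",
                                    call. = FALSE)
  x <- seq_len(width)
  base_y <- eval_quartic(baseline, x)
  pert <- with_seed(seed, {
    if (roughness_amplitude == 0) {
      numeric(width)
    } else {
      z <- rnorm(width)
      if (smooth > 1L) {
        k <- as.integer(smooth)
        zp <- c(z[(width - k + 2):width], z, z[1:(k - 1)])  # circular pad
        z <- as.numeric(stats::filter(zp, rep(1 / k, k), sides = 2))
        z <- z[k:(width + k - 1L)]
        z <- z * sqrt(k)  # restore unit variance after averaging
      }
      z * roughness_amplitude * sqrt(pi / 2)
    }
  })
  surf <- round(base_y + pert)
  bad <- which(surf < 1 | surf > height)
  if (length(bad) > 0) {
    stop(sprintf("surface leaves image bounds at column %d (row %g)",
                 bad[1], surf[bad[1]]), call. = FALSE)
  }
  mask <- matrix(FALSE, nrow = height, ncol = width)
  rows <- row(mask)
  mask <- rows >= matrix(surf, nrow = height, ncol = width, byrow = TRUE)
  truth <- data.frame(
    amplitude_target = roughness_amplitude,
    amplitude_realized = mean(abs(pert)),
    width = width, height = height
  )
  list(mask = mask, surface_row = as.integer(surf), truth = truth)
}

# Vectorized truncated-normal draw on [lo, hi] by rejection.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo) > 0) {
    draw <- rnorm(length(todo), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal rejection failed", call. = FALSE)
  }
  out
}

# Render a filled rotated ellipse (optionally with a zero-mean radial
# harmonic boundary perturbation) onto an image grid; returns the linear
# pixel indices covered. `amps`/`phases` are the cosine-harmonic amplitudes
# and phases for angular frequencies 3..(length(amps)+2); frequency 2 is
# excluded because it perturbs the second moments (true eccentricity).
ellipse_pixels <- function(nrow_img, ncol_img, cx, cy, a, b, theta_deg,
                           amps = NULL, phases = NULL) {
  th <- theta_deg * pi / 180
  reach <- a * (1 + if (is.null(amps)) 0 else min(sum(abs(amps)), 0.5))
  x0 <- max(1L, floor(cx - reach)); x1 <- min(ncol_img, ceiling(cx + reach))
  y0 <- max(1L, floor(cy - reach)); y1 <- min(nrow_img, ceiling(cy + reach))
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs)) - cy
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  r2 <- (U / a)^2 + (V / b)^2
  if (is.null(amps)) {
    inside <- r2 <= 1
  } else {
    phi <- atan2(V / b, U / a)
    eps <- matrix(0, nrow(phi), ncol(phi))
    for (k in seq_along(amps)) {
      eps <- eps + amps[k] * cos((k + 2) * phi + phases[k])
    }
    inside <- r2 <= (1 + eps)^2
  }
  ri <- matrix(ys, nrow = length(ys), ncol = length(xs))[inside]
  ci <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)[inside]
  (ci - 1L) * nrow_img + ri
}

#' Generate a synthetic DAPI-like nuclei image with known shape truth
#'
#' Places `n_nuclei` non-overlapping filled rotated ellipses on a noisy dark
#' background. Semi-major axes are uniform on `semi_major_range`; analytic
#' eccentricity is drawn from a truncated normal and fixes the semi-minor
#' axis via `b = a * sqrt(1 - e^2)`. Centers are rejection-sampled so nucleus
#' boundaries stay at least `min_separation` pixels apart (conservatively,
#' center distance >= a_i + a_j + min_separation).
#'
#' @param n_nuclei Number of nuclei (0 gives a background-only image).
#' @param eccentricity_mean,eccentricity_sd Truncated-normal parameters of
#'   the analytic eccentricity, truncated to `[0, 0.97]`.
#' @param seed Integer seed.
#' @param image_size Height and width in pixels.
#' @param semi_major_range Range of semi-major axis lengths, px.
#' @param min_separation Minimum boundary gap between nuclei, px.
#' @param irregularity SD of the zero-mean radial harmonic boundary
#'   perturbation relative to the ellipse radius (0 = perfect ellipses).
#' @param fg_level,bg_level,bg_noise_sd Rendering levels on the `[0, 1]`
#'   intensity scale.
#' @return A list with `image` (numeric matrix in `[0, 1]`), `truth`
#'   (data frame: nucleus_id, cx, cy, a, b, theta_deg, ecc_true), and
#'   `pixels` (list of linear pixel-index vectors, one per nucleus, so a
#'   paired channel can be painted on exactly the same footprint).
#' @export
generate_nuclei_image <- function(n_nuclei, eccentricity_mean, eccentricity_sd,
                                  seed,
                                  image_size = c(256L, 256L),
                                  semi_major_range = c(12, 18),
                                  min_separation = 6,
                                  irregularity = 0.07,
                                  fg_level = 0.6, bg_level = 0.03,
                                  bg_noise_sd = 0.01) {
  if (n_nuclei < 0) stop("`n_nuclei` must be >= 0", call. = FALSE)
  h <- image_size[1]; w <- image_size[2]
  with_seed(seed, {
    img <- matrix(pmax(0, bg_level + rnorm(h * w, 0, bg_noise_sd)), h, w)
    truth <- data.frame(nucleus_id = integer(0), cx = numeric(0),
                        cy = numeric(0), a = numeric(0), b = numeric(0),
                        theta_deg = numeric(0), ecc_true = numeric(0))
    if (n_nuclei == 0) {
      return(list(image = img, truth = truth, pixels = list()))
    }
    a <- runif(n_nuclei, semi_major_range[1], semi_major_range[2])
    e <- rtrunc_norm(n_nuclei, eccentricity_mean, eccentricity_sd, 0, 0.97)
    b <- a * sqrt(1 - e^2)
    th <- runif(n_nuclei, -90, 90)
    # conservative reach: boundary perturbation rarely exceeds 3 sd
    reach <- a * (1 + 3 * irregularity)
    cx <- numeric(n_nuclei); cy <- numeric(n_nuclei)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 1000L * n_nuclei
    while (placed < n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(
          "could not place %d nuclei with separation %g after %d attempts",
          n_nuclei, min_separation, max_attempts), call. = FALSE)
      }
      i <- placed + 1L
      px <- runif(1, reach[i] + 2, w - reach[i] - 1)
      py <- runif(1, reach[i] + 2, h - reach[i] - 1)
      if (placed > 0L) {
        d <- sqrt((cx[1:placed] - px)^2 + (cy[1:placed] - py)^2)
        if (any(d < reach[1:placed] + reach[i] + min_separation)) next
      }
      cx[i] <- px; cy[i] <- py
      placed <- i
    }
    pixels <- vector("list", n_nuclei)
    for (i in seq_len(n_nuclei)) {
      if (irregularity > 0) {
        amps <- rnorm(4, 0, irregularity / sqrt(4))
        amps <- pmax(pmin(amps, 0.12), -0.12)
        phases <- runif(4, 0, 2 * pi)
      } else {
        amps <- NULL; phases <- NULL
      }
      idx <- ellipse_pixels(h, w, cx[i], cy[i], a[i], b[i], th[i],
                            amps = amps, phases = phases)
      img[idx] <- pmin(1, fg_level * runif(1, 0.9, 1.1))
      pixels[[i]] <- idx
    }
    truth <- data.frame(nucleus_id = seq_len(n_nuclei), cx = cx, cy = cy,
                        a = a, b = b, theta_deg = th, ecc_true = e)
    list(image = img, truth = truth, pixels = pixels)
  })
}

#' Simulate cohort ground truth without rendering images
#'
#' Draws the tabular statistical structure of a cohort — per-nucleus analytic
#' eccentricity and marker intensity, per-sample group membership — from the
#' same distributional model used by [generate_cohort()], skipping image
#' rendering. Intended for simulation studies (power, parameter-recovery,
#' null calibration) where hundreds of replicate cohorts are needed.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list with `nuclei` (one row per nucleus: sample_id, group,
#'   group_code, image_id, ecc_true, marker_true) and `samples` (one row per
#'   sample: sample_id, group, group_code).
#' @export
simulate_cohort_truth <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    rows <- list()
    samp <- list()
    ng <- length(config$groups)
    for (g in seq_len(ng)) {
      for (s in seq_len(config$n_samples_per_group)) {
        sid <- sprintf("%s_%02d", config$groups[g], s)
        samp[[length(samp) + 1L]] <- data.frame(
          sample_id = sid, group = config$groups[g], group_code = g - 1L)
        for (im in seq_len(config$images_per_sample)) {
          n <- sample(config$nuclei_per_image[1]:config$nuclei_per_image[2], 1)
          e <- rtrunc_norm(n, config$eccentricity_mean_by_group[g],
                           config$eccentricity_sd, 0, 0.97)
          mk <- config$marker_intensity_intercept_by_group[g] +
            config$marker_intensity_slope_vs_eccentricity * e +
            rnorm(n, 0, config$intensity_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = config$groups[g], group_code = g - 1L,
            image_id = sprintf("%s_img%02d", sid, im),
            ecc_true = e, marker_true = mk)
        }
      }
    }
    list(nuclei = do.call(rbind, rows), samples = do.call(rbind, samp))
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Writes, under `out_dir`, one subdirectory per sample containing a binary
#' cartilage surface mask (8-bit PNG) and paired DAPI/marker images (32-bit
#' float TIFF) per field, plus `metadata.csv`, ground-truth tables
#' (`truth_nuclei.csv`, `truth_surfaces.csv`), a marker negative-control
#' image (background noise only), and the resolved `config.yaml`. Per-nucleus
#' marker intensity follows
#' `intercept(group) + slope * eccentricity + noise`; the marker image paints
#' each nucleus uniformly so that its pixel sum (in arbitrary units,
#' `pixel * marker_gain`) equals the programmed intensity.
#'
#' The whole cohort is a pure function of the config: identical config and
#' seed give byte-identical CSVs and pixel-identical images.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `metadata`, `truth_nuclei`,
#'   `truth_surfaces` data frames and the output paths.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  h <- config$image_size[1]; w <- config$image_size[2]
  meta <- list(); tn <- list(); ts <- list()
  counter <- 0L
  for (g in seq_along(config$groups)) {
    for (s in seq_len(config$n_samples_per_group)) {
      counter <- counter + 1L
      sid <- sprintf("%s_%02d", config$groups[g], s)
      sdir <- file.path(out_dir, sid)
      dir.create(sdir, showWarnings = FALSE)
      sex <- if (s %% 2 == 1) "F" else "M"
      sm <- generate_surface_mask(
        width = config$surface_size[2], height = config$surface_size[1],
        baseline = config$surface_baseline,
        roughness_amplitude = config$roughness_amplitude_by_group[g],
        seed = derive_seed(config$seed, counter * 1000L),
        smooth = config$surface_smooth)
      mask_path <- file.path(sdir, "surface_mask.png")
      write_mask(sm$mask, mask_path)
      ts[[length(ts) + 1L]] <- cbind(
        data.frame(sample_id = sid, group = config$groups[g],
                   group_code = g - 1L), sm$truth)
      for (im in seq_len(config$images_per_sample)) {
        img_seed <- derive_seed(config$seed, counter * 1000L + im)
        n <- with_seed(img_seed + 1L, {
          sample(config$nuclei_per_image[1]:config$nuclei_per_image[2], 1)
        })
        ni <- generate_nuclei_image(
          n_nuclei = n,
          eccentricity_mean = config$eccentricity_mean_by_group[g],
          eccentricity_sd = config$eccentricity_sd,
          seed = img_seed,
          image_size = config$image_size,
          semi_major_range = config$semi_major_range,
          min_separation = config$min_nucleus_separation,
          irregularity = config$nucleus_irregularity)
        iid <- sprintf("%s_img%02d", sid, im)
        marker <- with_seed(img_seed + 2L, {
          mimg <- matrix(abs(rnorm(h * w, 0, config$marker_background_sd)) /
                           config$marker_gain, h, w)
          mtruth <- numeric(nrow(ni$truth))
          if (nrow(ni$truth) > 0) {
            for (k in seq_len(nrow(ni$truth))) {
              inten <- config$marker_intensity_intercept_by_group[g] +
                config$marker_intensity_slope_vs_eccentricity *
                  ni$truth$ecc_true[k] +
                rnorm(1, 0, config$intensity_noise_sd)
              inten <- max(inten, 0)
              idx <- ni$pixels[[k]]
              mimg[idx] <- (inten / length(idx)) / config$marker_gain
              mtruth[k] <- inten
            }
          }
          list(image = pmin(mimg, 1), marker_true = mtruth)
        })
        dapi_path <- file.path(sdir, sprintf("img%02d_dapi.tif", im))
        marker_path <- file.path(sdir, sprintf("img%02d_marker.tif", im))
        write_image(ni$image, dapi_path)
        write_image(marker$image, marker_path)
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sid, group = config$groups[g], group_code = g - 1L,
          sex = sex, image_id = iid,
          dapi_path = file.path(sid, basename(dapi_path)),
          marker_path = file.path(sid, basename(marker_path)),
          mask_path = file.path(sid, "surface_mask.png"))
        if (nrow(ni$truth) > 0) {
          tn[[length(tn) + 1L]] <- cbind(
            data.frame(sample_id = sid, group = config$groups[g],
                       group_code = g - 1L, image_id = iid),
            ni$truth, marker_true = marker$marker_true)
        }
      }
    }
  }
  control <- with_seed(derive_seed(config$seed, 999983L), {
    matrix(abs(rnorm(h * w, 0, config$marker_background_sd)) /
             config$marker_gain, h, w)
  })
  write_image(control, file.path(out_dir, "negative_control_marker.tif"))
  metadata <- do.call(rbind, meta)
  truth_nuclei <- do.call(rbind, tn)
  truth_surfaces <- do.call(rbind, ts)
  write_table(metadata, file.path(out_dir, "metadata.csv"))
  write_table(truth_nuclei, file.path(out_dir, "truth_nuclei.csv"))
  write_table(truth_surfaces, file.path(out_dir, "truth_surfaces.csv"))
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"),
                   precision = 15)
  invisible(list(metadata = metadata, truth_nuclei = truth_nuclei,
                 truth_surfaces = truth_surfaces, path = out_dir))
}
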