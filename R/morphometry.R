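#' Names of the 53 nuclear shape descriptors
#'
#' The fixed feature roster: 23 geometry descriptors followed by 30 Zernike
#' moment magnitudes (orders n = 0..9, all valid repetitions m, computed on
#' the object mapped to the unit disk circumscribing its bounding box).
#' Column order is frozen; every feature table produced by
#' [measure_features()] carries exactly these 53 columns.
#'
#' @format Character vector of length 53.
#' @export
nuclear_feature_names <- local({
  geom <- c("area", "perimeter", "form_factor", "solidity", "extent",
            "euler_number", "eccentricity", "major_axis_length",
            "minor_axis_length", "orientation", "compactness",
            "equivalent_diameter", "max_radius", "mean_radius",
            "median_radius", "min_feret_diameter", "max_feret_diameter",
            "bbox_area", "bbox_aspect_ratio", "centroid_x", "centroid_y",
            "convex_area", "circularity_complement")
  zk <- character(0)
  for (n in 0:9) {
    for (m in seq(if (n %% 2 == 0) 0 else 1, n, by = 2)) {
      zk <- c(zk, sprintf("zernike_%d_%d", n, m))
    }
  }
  c(geom, zk)
})

#' Segment nuclei from a grayscale image
#'
#' Primary-object identification: global Otsu threshold, hole filling,
#' connected-component labeling, and an area filter. Border-touching objects
#' are flagged but retained.
#'
#' @param image Numeric matrix, values in `[0, 1]`.
#' @param min_area,max_area Retained object area range, px^2.
#' @param image_id Optional provenance label.
#' @return A `labeled_nuclei`: list with `labels` (integer matrix,
#'   0 = background, objects labeled 1..n), `n`, `border_touching` (logical
#'   per object), `image_id`.
#' @export
segment_nuclei <- function(image, min_area = 50, max_area = 5000,
                           image_id = NA_character_) {
  if (!is.matrix(image) || length(image) == 0) {
    stop("`image` must be a non-empty matrix", call. = FALSE)
  }
  if (min_area >= max_area) stop("`min_area` must be < `max_area`",
                                 call. = FALSE)
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("uniform image: no objects segmented", call. = FALSE)
    return(empty_labels(image, image_id))
  }
  th <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  mask <- image > th
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(EBImage::bwlabel(filled))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area & sizes <= max_area)
  if (length(keep) == 0) {
    warning("no objects within the area filter", call. = FALSE)
    return(empty_labels(image, image_id))
  }
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(image), ncol(image))
  pos <- lab > 0
  out[pos] <- relab[lab[pos]]
  border <- vapply(seq_along(keep), function(i) {
    any(out[1, ] == i) || any(out[nrow(out), ] == i) ||
      any(out[, 1] == i) || any(out[, ncol(out)] == i)
  }, logical(1))
  structure(list(labels = out, n = length(keep), border_touching = border,
                 image_id = image_id), class = "labeled_nuclei")
}

empty_labels <- function(image, image_id) {
  structure(list(labels = matrix(0L, nrow(image), ncol(image)), n = 0L,
                 border_touching = logical(0), image_id = image_id),
            class = "labeled_nuclei")
}

# --- second-central-moment machinery -------------------------------------

# Central moments and moment-ellipse quantities of a pixel list.
# Degenerate (collinear) objects get e = 1 - 1e-9 and a floored minor axis.
moment_shape <- function(xs, ys) {
  n <- length(xs)
  cx <- mean(xs); cy <- mean(ys)
  dx <- xs - cx; dy <- ys - cy
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max((mu20 - mu02)^2 / 4 + mu11^2, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  degenerate <- l1 <= 0 || l2 / l1 < 1e-12
  ecc <- if (degenerate) 1 - 1e-9 else sqrt(1 - l2 / l1)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  list(cx = cx, cy = cy, mu20 = mu20, mu02 = mu02, mu11 = mu11,
       lambda1 = l1, lambda2 = l2, eccentricity = ecc,
       major_axis_length = 4 * sqrt(l1),
       minor_axis_length = max(4 * sqrt(l2), 1e-6),
       orientation = theta, degenerate = degenerate, det = det)
}

#' Moments eccentricity of a binary object
#'
#' Eccentricity of the ellipse with the same second central moments as the
#' object: with covariance eigenvalues `lambda_max >= lambda_min`,
#' `e = sqrt(1 - lambda_min / lambda_max)`. 0 for a circle, approaching 1
#' for a line. Degenerate (collinear) objects return `1 - 1e-9` with
#' attribute `degenerate = TRUE`.
#'
#' @param object Logical/binary matrix, or a two-column matrix/data frame of
#'   pixel coordinates (columns `x`, `y`).
#' @return Eccentricity in `[0, 1)`, with attribute `degenerate`.
#' @export
eccentricity_from_moments <- function(object) {
  if (is.matrix(object) && (is.logical(object) ||
      (ncol(object) != 2 && is.numeric(object)))) {
    obj <- as_binary_matrix(object)
    ys <- row(obj)[obj]; xs <- col(obj)[obj]
  } else {
    object <- as.data.frame(object)
    names(object)[1:2] <- c("x", "y")
    xs <- object$x; ys <- object$y
  }
  if (length(xs) < 2) stop("object must have at least 2 pixels", call. = FALSE)
  ms <- moment_shape(xs, ys)
  structure(ms$eccentricity, degenerate = ms$degenerate)
}

# --- perimeter (Crofton, 4 directions) -----------------------------------

# Weighted 2x2 pixel-configuration estimate of the boundary length of the
# continuous region underlying the pixel set (Cauchy-Crofton with
# horizontal, vertical and both diagonal line families).
crofton_coefs <- local({
  s2 <- sqrt(2)
  c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
    pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2, pi / (4 * s2),
    pi / (4 * s2), pi / 4, pi / 2, 0, 0)
})

crofton_perimeter <- function(obj) {
  p <- matrix(0L, nrow(obj) + 2L, ncol(obj) + 2L)
  p[2:(nrow(obj) + 1L), 2:(ncol(obj) + 1L)] <- obj * 1L
  nr <- nrow(p); nc <- ncol(p)
  a <- p[-nr, -nc]   # (i, j)
  b <- p[-nr, -1]    # (i, j+1)
  d <- p[-1, -nc]    # (i+1, j)
  e <- p[-1, -1]     # (i+1, j+1)
  code <- 8L * a + 2L * b + 4L * d + e
  h <- tabulate(code + 1L, nbins = 16L)
  sum(crofton_coefs * h)
}

# --- convex hull helpers -------------------------------------------------

# Number of pixel centers inside or on the convex hull of the object's
# pixel centers (guarantees solidity = area / convex_area <= 1).
convex_pixel_count <- function(xs, ys) {
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) <= 2) return(nrow(pts))
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  if (length(hull) <= 2) return(nrow(pts))  # collinear
  total <- 0L
  eps <- 1e-9
  for (yy in seq(min(ys), max(ys))) {
    xs_cross <- numeric(0)
    nh <- length(hx)
    for (i in seq_len(nh)) {
      j <- if (i == nh) 1L else i + 1L
      y1 <- hy[i]; y2 <- hy[j]
      if (abs(y1 - y2) < eps) {
        if (abs(yy - y1) < eps) xs_cross <- c(xs_cross, hx[i], hx[j])
      } else if ((yy >= min(y1, y2) - eps) && (yy <= max(y1, y2) + eps)) {
        t <- (yy - y1) / (y2 - y1)
        xs_cross <- c(xs_cross, hx[i] + t * (hx[j] - hx[i]))
      }
    }
    if (length(xs_cross) == 0) next
    lo <- ceiling(min(xs_cross) - eps)
    hi <- floor(max(xs_cross) + eps)
    if (hi >= lo) total <- total + (hi - lo + 1L)
  }
  max(total, nrow(pts))
}

# Feret diameters from hull points (pixel centers + 1 px extent).
feret_diameters <- function(xs, ys) {
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) == 1) return(c(min = 1, max = 1))
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  dmax <- 0
  nh <- length(hx)
  for (i in seq_len(nh)) {
    d <- sqrt((hx - hx[i])^2 + (hy - hy[i])^2)
    dmax <- max(dmax, max(d))
  }
  ang <- seq(0, pi, length.out = 181)[-181]
  widths <- vapply(ang, function(a) {
    pr <- hx * cos(a) + hy * sin(a)
    max(pr) - min(pr)
  }, numeric(1))
  c(min = min(widths) + 1, max = dmax + 1)
}

# --- Zernike moments -----------------------------------------------------

zernike_radial <- function(n, m, rho) {
  out <- numeric(length(rho))
  for (s in 0:((n - m) / 2)) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

# Magnitudes of Zernike moments (orders 0..9) of a binary pixel set mapped
# to the unit disk circumscribing its bounding box.
zernike_magnitudes <- function(xs, ys) {
  xmin <- min(xs); xmax <- max(xs); ymin <- min(ys); ymax <- max(ys)
  cx <- (xmin + xmax) / 2; cy <- (ymin + ymax) / 2
  bw <- xmax - xmin + 1; bh <- ymax - ymin + 1
  radius <- sqrt(bw^2 + bh^2) / 2
  dx <- (xs - cx) / radius; dy <- (ys - cy) / radius
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  out <- numeric(30)
  k <- 0L
  for (n in 0:9) {
    for (m in seq(if (n %% 2 == 0) 0 else 1, n, by = 2)) {
      k <- k + 1L
      rad <- zernike_radial(n, m, rho)
      re <- sum(rad * cos(m * theta))
      im <- -sum(rad * sin(m * theta))
      out[k] <- (n + 1) / pi * sqrt(re^2 + im^2) / radius^2
    }
  }
  out
}

# Euler number (objects minus holes) of one object's submask.
euler_number_of <- function(obj) {
  pad <- matrix(0, nrow(obj) + 2, ncol(obj) + 2)
  pad[2:(nrow(obj) + 1), 2:(ncol(obj) + 1)] <- obj * 1
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(pad)))
  holes <- EBImage::imageData(EBImage::bwlabel(
    EBImage::Image((filled > 0) * (pad == 0) * 1)))
  1L - max(holes)
}

# --- the 53-descriptor vector --------------------------------------------

measure_one_object <- function(obj_mask) {
  ys <- row(obj_mask)[obj_mask]
  xs <- col(obj_mask)[obj_mask]
  area <- length(xs)
  ms <- moment_shape(xs, ys)
  xmin <- min(xs); xmax <- max(xs); ymin <- min(ys); ymax <- max(ys)
  bw <- xmax - xmin + 1; bh <- ymax - ymin + 1
  sub <- obj_mask[ymin:ymax, xmin:xmax, drop = FALSE]
  perim <- if (area == 1) 1 else max(crofton_perimeter(sub), 1)
  ff <- min(4 * pi * area / perim^2, 1)
  conv <- convex_pixel_count(xs, ys)
  pad <- matrix(0, bh + 2, bw + 2)
  pad[2:(bh + 1), 2:(bw + 1)] <- sub * 1
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(pad)))
  radii <- dm[pad > 0]
  fer <- feret_diameters(xs, ys)
  compact <- 2 * pi * sum((xs - ms$cx)^2 + (ys - ms$cy)^2) / area^2
  geom <- c(
    area = area,
    perimeter = perim,
    form_factor = ff,
    solidity = area / conv,
    extent = area / (bw * bh),
    euler_number = euler_number_of(sub),
    eccentricity = as.numeric(ms$eccentricity),
    major_axis_length = ms$major_axis_length,
    minor_axis_length = ms$minor_axis_length,
    orientation = ms$orientation,
    compactness = compact,
    equivalent_diameter = 2 * sqrt(area / pi),
    max_radius = max(radii),
    mean_radius = mean(radii),
    median_radius = stats::median(radii),
    min_feret_diameter = fer[["min"]],
    max_feret_diameter = fer[["max"]],
    bbox_area = bw * bh,
    bbox_aspect_ratio = max(bw, bh) / min(bw, bh),
    centroid_x = ms$cx,
    centroid_y = ms$cy,
    convex_area = conv,
    circularity_complement = 1 - ff
  )
  zk <- zernike_magnitudes(xs, ys)
  out <- c(geom, zk)
  names(out) <- nuclear_feature_names
  out
}

#' Measure the 53-descriptor shape vector for every labeled nucleus
#'
#' Computes, per object, 23 geometry descriptors (area, Crofton perimeter,
#' form factor `4*pi*A/P^2` clamped to 1, solidity, extent, Euler number,
#' moments eccentricity, moment-ellipse axes and orientation, compactness,
#' equivalent diameter, distance-map radii, Feret diameters, bounding-box
#' descriptors, centroid, convex area, circularity complement) and 30
#' Zernike moment magnitudes. All values are finite on every valid object;
#' single-pixel objects use the convention perimeter = 1.
#'
#' @param labels A [segment_nuclei()] result.
#' @return Data frame: `image_id`, `nucleus_id`, `border_touching`, then the
#'   53 feature columns named by [nuclear_feature_names] in frozen order.
#' @export
measure_features <- function(labels) {
  stopifnot(inherits(labels, "labeled_nuclei"))
  if (labels$n == 0) stop("no labeled objects to measure", call. = FALSE)
  rows <- lapply(seq_len(labels$n), function(i) {
    measure_one_object(labels$labels == i)
  })
  feat <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(image_id = labels$image_id,
                   nucleus_id = seq_len(labels$n),
                   border_touching = labels$border_touching),
        feat)
}

#' Average nuclear features within samples
#'
#' Per-image mean of each descriptor over the image's nuclei, then
#' per-sample mean over the sample's images — the averaging rule used for
#' all sample-level inference. Samples contributing zero nuclei are dropped
#' with a warning.
#'
#' @param features Row-bound [measure_features()] tables.
#' @param metadata Data frame mapping `image_id` to `sample_id` (and
#'   optionally `group`, `group_code`).
#' @return Data frame: one row per sample with `sample_id`, grouping columns
#'   if present, `n_nuclei`, `n_images`, and the 53 mean feature columns.
#' @export
aggregate_nuclei_by_sample <- function(features, metadata) {
  if (is.null(features) || nrow(features) == 0) {
    warning("no nuclei to aggregate", call. = FALSE)
    return(data.frame())
  }
  map_cols <- intersect(c("sample_id", "group", "group_code"),
                        names(metadata))
  map <- unique(metadata[, c("image_id", map_cols)])
  feats <- merge(features, map, by = "image_id")
  unmapped <- setdiff(features$image_id, map$image_id)
  if (length(unmapped) > 0) {
    stop(sprintf("images missing from metadata: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  fcols <- nuclear_feature_names
  per_image <- stats::aggregate(feats[fcols],
                                by = feats[c("image_id", "sample_id")],
                                FUN = mean)
  counts <- stats::aggregate(list(n_nuclei = feats$nucleus_id),
                             by = feats["sample_id"], FUN = length)
  per_sample <- stats::aggregate(per_image[fcols],
                                 by = per_image["sample_id"], FUN = mean)
  n_images <- stats::aggregate(list(n_images = per_image$image_id),
                               by = per_image["sample_id"], FUN = length)
  out <- merge(merge(per_sample, counts, by = "sample_id"),
               n_images, by = "sample_id")
  smeta <- unique(metadata[, map_cols, drop = FALSE])
  out <- merge(smeta, out, by = "sample_id")
  dropped <- setdiff(smeta$sample_id, out$sample_id)
  if (length(dropped) > 0) {
    warning(sprintf("sample(s) with zero nuclei dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  out[, c(map_cols, "n_nuclei", "n_images", fcols)]
}
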