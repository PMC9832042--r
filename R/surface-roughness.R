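#' Extract the articular surface contour from a tissue mask
#'
#' The articular surface faces the joint space at the top of the image, so
#' the contour is the topmost foreground pixel of the largest connected
#' tissue component in each column of that component's horizontal span.
#' Columns inside the span with no component pixel (torn tissue) are
#' excluded from the contour rather than interpolated, and reported.
#'
#' @param mask Binary matrix (`TRUE`/nonzero = tissue), rows = y increasing
#'   downward, columns = x.
#' @param image_id Optional provenance label.
#' @return A `surface_contour`: list with `x` (strictly increasing column
#'   indices), `y` (surface row per column), `excluded_columns`, `image_id`.
#' @export
extract_surface_contour <- function(mask, image_id = NA_character_) {
  m <- as_binary_matrix(mask)
  if (!any(m)) stop("no tissue: mask has no foreground pixels", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  comp <- lab == keep
  col_any <- which(colSums(comp) > 0)
  span <- seq(min(col_any), max(col_any))
  y <- vapply(span, function(j) {
    rows <- which(comp[, j])
    if (length(rows) == 0) NA_integer_ else min(rows)
  }, integer(1))
  excluded <- span[is.na(y)]
  usable <- !is.na(y)
  if (sum(usable) < 6L) {
    stop("contour too short: fewer than 6 usable columns", call. = FALSE)
  }
  structure(list(x = as.numeric(span[usable]), y = as.numeric(y[usable]),
                 excluded_columns = excluded, image_id = image_id),
            class = "surface_contour")
}

validate_contour <- function(contour) {
  if (!inherits(contour, "surface_contour")) {
    if (is.list(contour) && all(c("x", "y") %in% names(contour))) {
      contour <- structure(list(x = as.numeric(contour$x),
                                y = as.numeric(contour$y),
                                excluded_columns = integer(0),
                                image_id = contour$image_id %||% NA_character_),
                           class = "surface_contour")
    } else {
      stop("`contour` must be a surface_contour or a list with x and y",
           call. = FALSE)
    }
  }
  if (length(contour$x) != length(contour$y)) {
    stop("contour x and y must have equal length", call. = FALSE)
  }
  if (length(contour$x) < 6L) {
    stop("contour too short: need at least 6 points to fit a quartic",
         call. = FALSE)
  }
  if (any(diff(contour$x) <= 0)) {
    stop("contour x must be strictly increasing", call. = FALSE)
  }
  contour
}

#' Least-squares quartic fit of a surface contour
#'
#' Fits a polynomial of degree exactly 4 to `y` as a function of `x` by
#' ordinary least squares. The abscissa is centred and scaled internally
#' (the raw degree-4 Vandermonde on pixel columns is ill-conditioned) and
#' the coefficients are mapped back to the original pixel domain.
#'
#' @param contour A [extract_surface_contour()] result, or a list with
#'   numeric `x` and `y`.
#' @return List with `coefficients` (`c0..c4`, original domain), `fitted`,
#'   and `residuals` (`y - fitted`).
#' @export
fit_quartic <- function(contour) {
  contour <- validate_contour(contour)
  x <- contour$x; y <- contour$y
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) stop("degenerate contour: all x identical", call. = FALSE)
  t <- (x - m) / s
  V <- outer(t, 0:4, `^`)
  fit <- stats::lm.fit(V, y)
  ct <- fit$coefficients
  ct[is.na(ct)] <- 0
  # back-transform: p(t) with t = (x - m)/s, expanded in powers of x
  shift <- c(-m / s, 1 / s)
  coef_x <- c(ct[1], 0, 0, 0, 0)
  p <- 1
  for (k in 1:4) {
    p <- convolve_poly(p, shift)
    term <- numeric(5)
    term[seq_along(p)] <- p * ct[k + 1]
    coef_x <- coef_x + term
  }
  names(coef_x) <- paste0("c", 0:4)
  fitted <- as.numeric(V %*% ct)
  list(coefficients = coef_x, fitted = fitted, residuals = y - fitted)
}

#' Cartilage surface-roughness index
#'
#' The roughness statistic: fit a quartic to the surface contour, take the
#' error `E` as the mean discrepancy between contour and fitted curve
#' (mean absolute residual by default, root-mean-square behind the `metric`
#' flag), and normalise by the cartilage length `L`, the Euclidean distance
#' between the two contour endpoints (the edges of the measured plateau).
#' The index `R = E / L` is dimensionless and invariant under uniform
#' rescaling of the image.
#'
#' @inheritParams fit_quartic
#' @param metric `"mad"` (mean absolute deviation, default) or `"rms"`.
#' @return A `roughness_result`: list with `coefficients`, `error` (E, px),
#'   `length` (L, px), `roughness` (R = E/L), `metric`, `n_points`,
#'   `image_id`.
#' @export
compute_roughness <- function(contour, metric = c("mad", "rms")) {
  metric <- match.arg(metric)
  contour <- validate_contour(contour)
  fit <- fit_quartic(contour)
  E <- if (metric == "mad") {
    mean(abs(fit$residuals))
  } else {
    sqrt(mean(fit$residuals^2))
  }
  n <- length(contour$x)
  L <- sqrt((contour$x[n] - contour$x[1])^2 + (contour$y[n] - contour$y[1])^2)
  if (L == 0) stop("cartilage length is zero: cannot normalise", call. = FALSE)
  structure(list(coefficients = fit$coefficients, error = E, length = L,
                 roughness = E / L, metric = metric, n_points = n,
                 image_id = contour$image_id),
            class = "roughness_result")
}

#' Per-sample roughness table and age-group trend
#'
#' Computes the roughness index for every surface mask of a cohort, averages
#' within sample, and regresses the per-sample index on the ordinal age-group
#' code (young = 0, middle = 1, aged = 2) by OLS.
#'
#' @param masks Named list of binary mask matrices; names are sample ids, or
#'   a data frame mapping is supplied via `metadata`.
#' @param metadata Data frame with columns `sample_id`, `group_code` (one
#'   row per sample or per image; deduplicated by sample).
#' @param metric Passed to [compute_roughness()].
#' @return List with `per_image` (sample_id, image_id, E_px, L_px, R),
#'   `per_sample` (sample_id, group_code, R mean), and `trend`
#'   (a [regress_trend()] result), plus `failed` mask names.
#' @export
roughness_by_group <- function(masks, metadata, metric = "mad") {
  stopifnot(is.list(masks), length(masks) > 0)
  meta <- unique(metadata[, c("sample_id", "group_code")])
  rows <- list(); failed <- character(0)
  for (nm in names(masks)) {
    res <- tryCatch(
      compute_roughness(extract_surface_contour(masks[[nm]], image_id = nm),
                        metric = metric),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, nm)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sub("::.*$", "", nm), image_id = nm,
      E_px = res$error, L_px = res$length, R = res$roughness)
  }
  if (length(failed) > 0) {
    warning(sprintf("roughness failed for %d mask(s): %s", length(failed),
                    paste(failed, collapse = ", ")), call. = FALSE)
  }
  per_image <- do.call(rbind, rows)
  if (is.null(per_image)) stop("all masks failed roughness extraction",
                               call. = FALSE)
  agg <- stats::aggregate(R ~ sample_id, data = per_image, FUN = mean)
  per_sample <- merge(agg, meta, by = "sample_id")
  trend <- regress_trend(per_sample$R, per_sample$group_code)
  list(per_image = per_image, per_sample = per_sample, trend = trend,
       failed = failed)
}
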