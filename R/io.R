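#' Read a grayscale image (TIFF or PNG) as a numeric matrix
#'
#' Returns a plain numeric matrix with rows = image rows (y, increasing
#' downward) and columns = image columns (x), values on the `[0, 1]` scale
#' of the file. Multi-channel files are reduced to their first channel.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (!is.matrix(img)) stop(sprintf("corrupt image: '%s'", path), call. = FALSE)
  img
}

#' Write a grayscale image
#'
#' TIFF output is 32-bit float (lossless for values in `[0, 1]`); PNG output
#' is 8-bit. Used for the synthetic DAPI and marker channels.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path Destination `.tif`/`.tiff` or `.png` path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 32L),
    png = png::writePNG(img, path),
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
         call. = FALSE)
  )
  invisible(path)
}

# Binary mask helpers: stored as 8-bit PNG with values {0, 255}.
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path Path to an 8-bit mask PNG (`0` = background).
#' @return Logical matrix, `TRUE` = foreground.
#' @export
read_mask <- function(path) {
  read_image(path) > 0.5
}

#' Write / read pipeline tables
#'
#' CSV writers used throughout the pipeline: stable column order, no row
#' names, full double precision (15 significant digits) so written tables
#' round-trip value-identically.
#'
#' @param df A data frame.
#' @param path Destination `.csv` path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @param required Character vector of column names that must be present.
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("table not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop(sprintf("'%s' is missing required column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df
}
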