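#' @title Color extraction from images and measurement reproducibility
#' @name imaging
#' @description
#' Replaces the manual image-editor readout of herb color with a
#' reproducible operation: the per-channel arithmetic mean of an 8-bit RGB
#' image over a rectangular region of interest, rounded half up to integer
#' channels. Reproducibility of repeated color measurements is summarized by
#' the relative standard deviation (RSD) of each channel.
NULL

#' Rectangular region of interest
#'
#' @param x0,y0 Top-left pixel of the region, 0-based.
#' @param width,height Region size in pixels, both at least 1.
#' @return A `roi` object.
#' @export
roi <- function(x0, y0, width, height) {
  stopifnot(x0 >= 0, y0 >= 0, width >= 1, height >= 1)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

# Accepts an H x W x 3 numeric array (values in [0,1] or [0,255]) or a path
# to a PNG/JPEG file; returns an H x W x 3 array on the 0-255 scale.
read_image_rgb <- function(image) {
  if (is.character(image)) {
    if (!file.exists(image)) stop("image file not found: ", image, call. = FALSE)
    if (grepl("\\.png$", image, ignore.case = TRUE)) {
      image <- png::readPNG(image)
    } else if (grepl("\\.jpe?g$", image, ignore.case = TRUE)) {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG requires the EBImage package", call. = FALSE)
      img <- EBImage::readImage(image)
      image <- aperm(EBImage::imageData(img), c(2, 1, 3))
    } else stop("unsupported image format: ", image, call. = FALSE)
  }
  if (!is.array(image) || length(dim(image)) < 3L || dim(image)[3] < 3L)
    stop("image must have three color channels", call. = FALSE)
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) <= 1) image <- image * 255
  image
}

#' Mean RGB over a region of interest
#'
#' Per-channel arithmetic mean of all pixels inside the region, rounded half
#' up to integers on the 0--255 scale.
#'
#' @param image An H x W x 3 numeric array (values in `[0,1]` or `[0,255]`)
#'   or a path to an 8-bit PNG/JPEG file.
#' @param region A [roi()] object lying fully inside the image.
#' @return Integer RGB triple named R, G, B.
#' @export
extract_mean_rgb <- function(image, region) {
  img <- read_image_rgb(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (region$x0 + region$width > w || region$y0 + region$height > h)
    stop("region of interest extends outside the image", call. = FALSE)
  rows <- (region$y0 + 1):(region$y0 + region$height)
  cols <- (region$x0 + 1):(region$x0 + region$width)
  m <- vapply(1:3, function(k) mean(img[rows, cols, k]), numeric(1))
  out <- as.integer(pmin(255, pmax(0, round_half_up(m))))
  names(out) <- c("R", "G", "B")
  out
}

#' Repeated RGB measurements of one object
#'
#' @param readings An n x 3 matrix of RGB readings (n >= 2, channels in
#'   0--255) in measurement order.
#' @param condition Label of the lighting condition, e.g. `"natural_light"`
#'   or `"lightbox"`.
#' @return A `repeat_measurements` object.
#' @export
repeat_measurements <- function(readings, condition = "lightbox") {
  readings <- as.matrix(readings)
  if (nrow(readings) < 2L)
    stop("at least 2 readings are required", call. = FALSE)
  if (ncol(readings) != 3L)
    stop("readings must have three columns (R, G, B)", call. = FALSE)
  if (anyNA(readings) || any(readings < 0) || any(readings > 255))
    stop("all channels must lie in [0, 255]", call. = FALSE)
  colnames(readings) <- c("R", "G", "B")
  structure(list(condition = condition, readings = readings),
            class = "repeat_measurements")
}

#' Relative standard deviation (percent)
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation. The n-1 convention is fixed: it is the convention under which
#' the packaged repeat-measurement readings reproduce their published
#' per-channel RSDs.
#'
#' @param values Numeric vector of at least 2 values with non-zero mean.
#' @return RSD as a percentage (not rounded).
#' @export
rsd <- function(values) {
  if (length(values) < 2L)
    stop("rsd needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("rsd is undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Per-channel reproducibility report
#'
#' Applies [rsd()] to each channel of a repeat-measurement set.
#'
#' @param mset A [repeat_measurements()] object.
#' @param digits Decimal places for half-up rounding of the report
#'   (default 2); use `NULL` for unrounded values.
#' @return Named numeric triple of per-channel RSDs in percent, ordered
#'   R, G, B.
#' @export
reproducibility_report <- function(mset, digits = 2) {
  stopifnot(inherits(mset, "repeat_measurements"))
  out <- apply(mset$readings, 2, rsd)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}
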