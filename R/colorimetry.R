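#' @title RGB to CIE 1931 chromaticity conversion
#' @name colorimetry
#' @description
#' Converts 8-bit RGB colors to CIE 1931 tristimulus values (X, Y, Z) and
#' chromaticity coordinates x = X/(X+Y+Z), y = Y/(X+Y+Z), and back (for
#' rendering scale-card colors). The conversion convention -- the 3x3
#' RGB-to-XYZ matrix, an optional per-channel transfer (gamma) function and
#' the reference white -- is configurable; the default treats the channels
#' as linear under the sRGB/D65 primaries.
NULL

# sRGB (IEC 61966-2-1) linear RGB -> XYZ, D65 white
SRGB_M <- matrix(c(0.4124, 0.3576, 0.1805,
                   0.2126, 0.7152, 0.0722,
                   0.0193, 0.1192, 0.9505),
                 nrow = 3, byrow = TRUE)

# CIE 1931 RGB primaries -> XYZ, equal-energy white
CIE_RGB_M <- matrix(c(0.49, 0.31, 0.20,
                      0.17697, 0.81240, 0.01063,
                      0.00, 0.01, 0.99),
                    nrow = 3, byrow = TRUE) / 0.17697

srgb_decode <- function(c) ifelse(c <= 0.04045, c / 12.92,
                                  ((c + 0.055) / 1.055)^2.4)
srgb_encode <- function(c) ifelse(c <= 0.0031308, 12.92 * c,
                                  1.055 * c^(1 / 2.4) - 0.055)

#' Conversion conventions
#'
#' `"srgb_linear"` (default): sRGB/D65 primaries with the channels treated
#' as linear after division by 255. `"srgb_gamma"`: the same primaries with
#' the sRGB transfer function decoded before the matrix. `"cie_rgb"`: the
#' CIE 1931 RGB primaries with equal-energy white, linear channels.
#'
#' @param name Convention name, or an existing convention object (returned
#'   unchanged).
#' @param matrix Optional custom 3x3 RGB-to-XYZ matrix (rows X, Y, Z).
#' @param decode,encode Optional custom per-channel transfer function
#'   (encoded -> linear) and its inverse; both or neither.
#' @return A `color_convention` object with the matrix, its inverse, the
#'   transfer pair and the reference-white chromaticity.
#' @export
color_convention <- function(name = c("srgb_linear", "srgb_gamma", "cie_rgb"),
                             matrix = NULL, decode = NULL, encode = NULL) {
  if (inherits(name, "color_convention")) return(name)
  name <- match.arg(name)
  M <- switch(name, srgb_linear = SRGB_M, srgb_gamma = SRGB_M,
              cie_rgb = CIE_RGB_M)
  if (!is.null(matrix)) {
    stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)))
    M <- matrix
  }
  if (xor(is.null(decode), is.null(encode)))
    stop("decode and encode must be supplied together", call. = FALSE)
  if (is.null(decode) && name == "srgb_gamma") {
    decode <- srgb_decode; encode <- srgb_encode
  }
  white_xyz <- drop(M %*% rep(1, 3))
  structure(list(name = name, M = M, M_inv = solve(M),
                 decode = decode, encode = encode,
                 white = white_xyz[1:2] / sum(white_xyz)),
            class = "color_convention")
}

#' RGB to tristimulus values
#'
#' Scales the 8-bit channels to `[0, 1]`, applies the convention's transfer
#' function if it has one, and multiplies by the RGB-to-XYZ matrix.
#'
#' @param rgb RGB triple with channels in 0--255.
#' @param conv A [color_convention()] or its name.
#' @return Numeric triple `c(X, Y, Z)`, all non-negative.
#' @export
rgb_to_tristimulus <- function(rgb, conv = "srgb_linear") {
  conv <- color_convention(conv)
  check_rgb(rgb)
  v <- as.numeric(rgb) / 255
  if (!is.null(conv$decode)) v <- conv$decode(v)
  out <- drop(conv$M %*% v)
  names(out) <- c("X", "Y", "Z")
  out
}

#' Tristimulus values to chromaticity
#'
#' `x = X / (X + Y + Z)` and `y = Y / (X + Y + Z)`; the implied
#' `z = 1 - x - y` completes the unit-sum normalization.
#'
#' @param xyz Numeric triple `c(X, Y, Z)` with positive sum.
#' @return Chromaticity point `c(x, y)`.
#' @export
tristimulus_to_chromaticity <- function(xyz) {
  if (any(xyz < 0)) stop("tristimulus values must be non-negative", call. = FALSE)
  s <- sum(xyz)
  if (s <= 0)
    stop("degenerate color: tristimulus values sum to zero", call. = FALSE)
  c(x = xyz[[1]] / s, y = xyz[[2]] / s)
}

#' RGB directly to chromaticity
#'
#' @inheritParams rgb_to_tristimulus
#' @return Chromaticity point `c(x, y)`.
#' @export
rgb_to_chromaticity <- function(rgb, conv = "srgb_linear") {
  tristimulus_to_chromaticity(rgb_to_tristimulus(rgb, conv))
}

#' Chromaticity (plus luminance) back to RGB
#'
#' Reconstructs `(X, Y, Z)` from `(x, y)` and the luminance `Y`, inverts
#' the convention's matrix and transfer function, clips to the displayable
#' range and scales to 8-bit integers (rounding half up). When clipping
#' occurs (the point lies outside the RGB gamut at that luminance) a
#' warning is emitted and the result carries attribute
#' `gamut_clipped = TRUE`.
#'
#' @param p Chromaticity point `c(x, y)` with `x, y >= 0`, `x + y <= 1`,
#'   `y > 0`.
#' @param luminance_Y Luminance in `(0, 1]`.
#' @param conv A [color_convention()] or its name.
#' @return Integer RGB triple with attribute `gamut_clipped`.
#' @export
chromaticity_to_rgb <- function(p, luminance_Y = 0.35, conv = "srgb_linear") {
  conv <- color_convention(conv)
  x <- p[[1]]; y <- p[[2]]
  if (y <= 0) stop("degenerate chromaticity: y must be positive", call. = FALSE)
  if (x < 0 || x + y > 1 + 1e-12)
    stop("invalid chromaticity point", call. = FALSE)
  if (luminance_Y <= 0 || luminance_Y > 1)
    stop("luminance_Y must lie in (0, 1]", call. = FALSE)
  xyz <- c(x * luminance_Y / y, luminance_Y, (1 - x - y) * luminance_Y / y)
  lin <- drop(conv$M_inv %*% xyz)
  clipped <- any(lin < -1e-9) || any(lin > 1 + 1e-9)
  lin <- pmin(1, pmax(0, lin))
  v <- if (!is.null(conv$encode)) conv$encode(lin) else lin
  out <- as.integer(round_half_up(v * 255))
  names(out) <- c("R", "G", "B")
  if (clipped)
    warning("chromaticity point outside the RGB gamut; channels clipped",
            call. = FALSE)
  attr(out, "gamut_clipped") <- clipped
  out
}
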