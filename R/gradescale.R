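#' @title Colorimetric grading scale
#' @name gradescale
#' @description
#' The grading scale summarizes how the quality grades separate in the
#' CIE 1931 xy chromaticity plane: each grade gets an expectation point O_i
#' (the mean chromaticity of its representative samples), and the centroid
#' D of O_1, O_2, O_3 is the division point from which the grades fan out
#' in three directions. An unknown color is graded by which direction from
#' D it falls in, and the D and O colors can be rendered as a printable
#' comparison card, used like pH indicator paper.
NULL

#' Mean chromaticity (expectation point) of a set of points
#'
#' @param points An m x 2 matrix (or single point) of chromaticity
#'   coordinates.
#' @return Component-wise mean `c(x, y)`.
#' @export
expectation_point <- function(points) {
  if (is.null(points) || length(points) == 0L)
    stop("expectation_point needs at least one point", call. = FALSE)
  m <- if (is.matrix(points)) points else matrix(points, ncol = 2, byrow = TRUE)
  p <- colMeans(m)
  c(x = p[[1]], y = p[[2]])
}

#' Division point of the grading scale
#'
#' The centroid of the three per-grade expectation points: the arithmetic
#' mean of their coordinates.
#'
#' @param o1,o2,o3 Chromaticity points `c(x, y)` of grades 1--3.
#' @return Chromaticity point `c(x, y)`.
#' @export
division_point <- function(o1, o2, o3) {
  expectation_point(rbind(o1, o2, o3))
}

#' The 16 published representative sample ids, by grade
#'
#' The representatives are the samples with the least overlap between grade
#' clusters in the chromaticity diagram (spread roughly 80% of the maximum
#' distance from each grade's center).
#'
#' @return Named list of integer id vectors for grades 1--3.
#' @export
reference_representatives <- function() {
  list(`1` = c(12L, 15L, 19L, 31L),
       `2` = c(1L, 3L, 4L, 24L, 26L, 28L, 32L),
       `3` = c(9L, 10L, 14L, 33L, 34L))
}

#' Build a grading scale from labeled samples
#'
#' Converts each representative sample's RGB (for the chosen color source)
#' to chromaticity, averages per grade into the expectation points, and
#' places the division point at their centroid.
#'
#' @param samples A `herb_samples` data frame.
#' @param representative_ids Named list (names `"1"`, `"2"`, `"3"`) of
#'   sample ids per grade; defaults to the 16 published representatives.
#' @param color_source One of [color_sources()] (default
#'   `"powder_colored"`, the most discriminative source).
#' @param conv A [color_convention()] or its name.
#' @param rule Classification geometry: `"angle"` (smallest angle between
#'   the rays D->O_i and D->p) or `"nearest"` (smallest Euclidean distance
#'   to O_i).
#' @param luminance_Y Luminance used when rendering the scale colors.
#' @return A `grading_scale` object.
#' @export
build_scale <- function(samples,
                        representative_ids = reference_representatives(),
                        color_source = "powder_colored",
                        conv = "srgb_linear",
                        rule = c("angle", "nearest"),
                        luminance_Y = 0.35) {
  rule <- match.arg(rule)
  conv <- color_convention(conv)
  if (!all(c("1", "2", "3") %in% names(representative_ids)))
    stop("representative_ids must name grades 1, 2 and 3", call. = FALSE)
  X <- rgb_matrix(samples, color_source)
  O <- matrix(NA_real_, 3, 2, dimnames = list(1:3, c("x", "y")))
  for (g in 1:3) {
    ids <- representative_ids[[as.character(g)]]
    if (length(ids) == 0L)
      stop("grade ", g, " has no representative sample", call. = FALSE)
    missing <- setdiff(ids, samples$sample_id)
    if (length(missing))
      stop("sample id(s) missing from dataset: ",
           paste(missing, collapse = ", "), call. = FALSE)
    pts <- t(vapply(ids, function(id)
      rgb_to_chromaticity(X[as.character(id), ], conv), numeric(2)))
    O[g, ] <- expectation_point(pts)
  }
  structure(list(expectation_points = O,
                 division_point = division_point(O[1, ], O[2, ], O[3, ]),
                 representative_ids = representative_ids,
                 color_source = color_source,
                 convention = conv$name, rule = rule,
                 luminance_Y = luminance_Y),
            class = "grading_scale")
}

#' Classify a chromaticity point against a grading scale
#'
#' With the `"angle"` rule (default) the point is assigned to the grade
#' whose ray D -> O_i makes the smallest angle with the ray D -> p; with
#' `"nearest"`, to the grade whose expectation point is closest in
#' Euclidean distance. Ties -- including p = D under the angle rule -- are
#' broken toward the smaller grade number.
#'
#' @param p Chromaticity point `c(x, y)`.
#' @param scale A `grading_scale` from [build_scale()].
#' @return Integer grade label in 1:3.
#' @export
classify_point <- function(p, scale) {
  stopifnot(inherits(scale, "grading_scale"))
  O <- scale$expectation_points
  D <- scale$division_point
  rays <- sweep(O, 2, D)
  lens <- sqrt(rowSums(rays^2))
  if (sum(lens < 1e-15) >= 2L)
    stop("degenerate scale: two expectation points coincide with the division point",
         call. = FALSE)
  if (scale$rule == "nearest") {
    d <- sqrt(rowSums(sweep(O, 2, as.numeric(p))^2))
    return(as.integer(which.min(d)))  # which.min takes the first (smallest grade) on ties
  }
  v <- as.numeric(p) - D
  vl <- sqrt(sum(v^2))
  if (vl < 1e-15) return(1L)  # p = D: tie broken toward grade 1
  ang <- acos(pmin(1, pmax(-1, (rays %*% v) / (lens * vl))))
  as.integer(which.min(ang))
}

#' Classify an RGB color against a grading scale
#'
#' Convenience wrapper converting the RGB triple under the scale's own
#' convention before calling [classify_point()].
#'
#' @param rgb RGB triple (0--255).
#' @param scale A `grading_scale`.
#' @return Integer grade label in 1:3.
#' @export
classify_rgb <- function(rgb, scale) {
  classify_point(rgb_to_chromaticity(rgb, scale$convention), scale)
}

#' Colors of the scale card
#'
#' The division-point color and the three expectation-point colors,
#' reconstructed at the scale's rendering luminance.
#'
#' @param scale A `grading_scale`.
#' @return A 4 x 3 integer RGB matrix with rows D, O1, O2, O3 and a
#'   logical attribute `gamut_clipped` per row.
#' @export
scale_colors <- function(scale) {
  pts <- rbind(D = scale$division_point,
               O1 = scale$expectation_points[1, ],
               O2 = scale$expectation_points[2, ],
               O3 = scale$expectation_points[3, ])
  clipped <- logical(4)
  out <- matrix(0L, 4, 3, dimnames = list(rownames(pts), c("R", "G", "B")))
  for (i in 1:4) {
    rgb <- withCallingHandlers(
      chromaticity_to_rgb(pts[i, ], scale$luminance_Y, scale$convention),
      warning = function(w) invokeRestart("muffleWarning"))
    out[i, ] <- rgb
    clipped[i] <- isTRUE(attr(rgb, "gamut_clipped"))
  }
  attr(out, "gamut_clipped") <- clipped
  out
}

#' Render the grading-scale card
#'
#' A raster of four solid square tiles -- the division point D followed by
#' the expectation points O1, O2, O3 -- separated by 1-pixel white rules.
#' Pixel content is deterministic for fixed inputs.
#'
#' @param scale A `grading_scale`.
#' @param tile_px Side length of each tile in pixels (>= 1).
#' @return An H x W x 3 numeric array in `[0, 1]`, with attributes `labels`
#'   (tile names, left to right) and `gamut_clipped` (per tile).
#' @seealso [write_scale_card()] to save it as a PNG file.
#' @export
render_scale_card <- function(scale, tile_px = 64) {
  stopifnot(inherits(scale, "grading_scale"), tile_px >= 1)
  cols <- scale_colors(scale)
  w <- 4 * tile_px + 3
  img <- array(1, dim = c(tile_px, w, 3))
  for (i in 1:4) {
    xs <- (i - 1) * (tile_px + 1) + seq_len(tile_px)
    for (k in 1:3) img[, xs, k] <- cols[i, k] / 255
  }
  attr(img, "labels") <- rownames(cols)
  attr(img, "gamut_clipped") <- attr(cols, "gamut_clipped")
  img
}

#' @rdname render_scale_card
#' @param path Output PNG path.
#' @export
write_scale_card <- function(scale, path, tile_px = 64) {
  png::writePNG(render_scale_card(scale, tile_px), path)
  invisible(path)
}

#' Save / load a grading scale
#'
#' Serializes the expectation points, division point, representative ids,
#' convention name, classification rule and rendering luminance to JSON.
#'
#' @param scale A `grading_scale`.
#' @param path JSON file path.
#' @return `scale_save` returns `path` invisibly; `scale_load` the scale.
#' @export
scale_save <- function(scale, path) {
  stopifnot(inherits(scale, "grading_scale"))
  payload <- unclass(scale)
  payload$expectation_points <- lapply(1:3, function(g)
    as.list(scale$expectation_points[g, ]))
  payload$division_point <- as.list(scale$division_point)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname scale_save
#' @export
scale_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- p$expectation_points
  O <- if (is.data.frame(ep)) as.matrix(ep) else do.call(rbind, lapply(ep, unlist))
  dimnames(O) <- list(1:3, c("x", "y"))
  structure(list(expectation_points = O,
                 division_point = c(x = p$division_point[["x"]],
                                    y = p$division_point[["y"]]),
                 representative_ids = lapply(p$representative_ids, as.integer),
                 color_source = p$color_source,
                 convention = p$convention, rule = p$rule,
                 luminance_Y = p$luminance_Y),
            class = "grading_scale")
}
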