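#' @title Graded herb color samples: data model and I/O
#' @name samples_io
#' @description
#' A graded color dataset is a data frame with one row per herb sample:
#' an integer `sample_id`, a free-text `origin`, an integer quality `grade`
#' (1 = best, 2, 3), and an RGB triple (integers 0--255) for each of five
#' color sources -- the outside surface, the fracture surface with and
#' without alkaline color development, and the powder with and without
#' development. An optional `haq_total` column carries the total
#' hydroxyanthraquinone content in mg/g, the chemical ground truth behind
#' the grade labels.
NULL

#' Color-source keys
#'
#' The five parts/preparations of the herb from which RGB color is measured.
#'
#' @return Character vector of the five color-source keys.
#' @export
color_sources <- function() {
  c("surface", "fracture", "fracture_colored", "powder", "powder_colored")
}

sample_schema <- function() {
  c("sample_id", "origin", "grade",
    as.vector(t(outer(color_sources(), c("R", "G", "B"), paste, sep = "_"))))
}

validate_samples <- function(df) {
  rgb_cols <- setdiff(sample_schema(), c("sample_id", "origin", "grade"))
  for (col in rgb_cols) {
    v <- df[[col]]
    if (anyNA(v) || any(v != as.integer(v)))
      stop(sprintf("column '%s' must contain integers", col), call. = FALSE)
    bad <- which(v < 0 | v > 255)
    if (length(bad))
      stop(sprintf("RGB channel out of [0,255] in column '%s', sample id %s",
                   col, df$sample_id[bad[1]]), call. = FALSE)
  }
  if (any(df$sample_id <= 0) || anyDuplicated(df$sample_id))
    stop("sample_id must be positive and unique", call. = FALSE)
  if (!all(df$grade %in% 1:3))
    stop("grade must be 1, 2 or 3", call. = FALSE)
  if (!is.null(df$haq_total) && !all(is.na(df$haq_total))) {
    ok <- is.na(df$haq_total) | df$haq_total >= 0
    if (!all(ok)) stop("haq_total must be non-negative", call. = FALSE)
  }
  class(df) <- c("herb_samples", "data.frame")
  df
}

#' Read a graded color dataset from CSV
#'
#' Reads a comma-separated file with a fixed column layout: `sample_id`,
#' `origin`, `grade`, then `R`/`G`/`B` columns for each color source in the
#' order surface, fracture, fracture_colored, powder, powder_colored, and
#' optionally a trailing `haq_total` column.
#'
#' @param path Path to a CSV file.
#' @return A `herb_samples` data frame, one row per sample in file order.
#' @seealso [write_samples()], [herb_table1()]
#' @export
load_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- sample_schema()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c(need, "haq_total"))
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "), call. = FALSE)
  df <- df[, c(need, intersect("haq_total", names(df)))]
  if (nrow(df) == 0L) {
    class(df) <- c("herb_samples", "data.frame")
    return(df)
  }
  validate_samples(df)
}

#' Write a graded color dataset to CSV
#'
#' Inverse of [load_samples()]: writes the same fixed column layout so that
#' a load/write round trip reproduces the file cell for cell.
#'
#' @param samples A `herb_samples` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = 2L, na = "")
  invisible(path)
}

#' Packaged reference datasets
#'
#' `herb_table1()` returns the packaged 34-sample rhubarb dataset (RGB values
#' for the five color sources plus grade labels). `herb_table2()` returns the
#' packaged repeat-measurement readings (15 replicate RGB measurements of one
#' object under natural light and in a standard lightbox) as a list of two
#' [repeat_measurements()] sets.
#'
#' @return For `herb_table1()` a `herb_samples` data frame with 34 rows; for
#'   `herb_table2()` a named list with elements `natural_light` and
#'   `lightbox`.
#' @export
herb_table1 <- function() {
  load_samples(system.file("extdata", "rhubarb_table1.csv",
                           package = "herbgrade", mustWork = TRUE))
}

#' @rdname herb_table1
#' @export
herb_table2 <- function() {
  path <- system.file("extdata", "rhubarb_table2.csv",
                      package = "herbgrade", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$condition), function(d) {
    d <- d[order(d$replicate), ]
    repeat_measurements(as.matrix(d[, c("R", "G", "B")]), d$condition[1])
  })
  out[c("natural_light", "lightbox")]
}

#' Extract the RGB matrix for one color source
#'
#' @param samples A `herb_samples` data frame.
#' @param source One of [color_sources()].
#' @return An n x 3 integer matrix with columns R, G, B and `sample_id`
#'   row names.
#' @export
rgb_matrix <- function(samples, source) {
  if (!source %in% color_sources())
    stop("unknown color source '", source, "'; expected one of: ",
         paste(color_sources(), collapse = ", "), call. = FALSE)
  m <- as.matrix(samples[, paste(source, c("R", "G", "B"), sep = "_")])
  dimnames(m) <- list(samples$sample_id, c("R", "G", "B"))
  m
}

#' Grade thresholds on total hydroxyanthraquinone content
#'
#' Quality grades are defined by the total content of the five
#' hydroxyanthraquinones (T_HAQs, mg/g): grade 1 at or above `upper`,
#' grade 3 at or below `lower`, grade 2 strictly between.
#'
#' @param upper Upper threshold in mg/g (default 40).
#' @param lower Lower threshold in mg/g (default 25).
#' @return A `grade_thresholds` object.
#' @export
grade_thresholds <- function(upper = 40, lower = 25) {
  if (!(lower > 0 && upper > lower))
    stop("thresholds must satisfy 0 < lower < upper", call. = FALSE)
  structure(list(upper = upper, lower = lower), class = "grade_thresholds")
}

#' Assign a quality grade from total HAQ content
#'
#' Grade 1 when `t_haqs >= upper`, grade 3 when `t_haqs <= lower`,
#' grade 2 otherwise; the boundary values 40.00 and 25.00 mg/g map to
#' grades 1 and 3 respectively.
#'
#' @param t_haqs Non-negative total HAQ content(s) in mg/g (vectorized).
#' @param thresholds A [grade_thresholds()] object.
#' @return Integer grade label(s) in 1:3.
#' @export
assign_grade <- function(t_haqs, thresholds = grade_thresholds()) {
  if (anyNA(t_haqs) || any(t_haqs < 0))
    stop("t_haqs must be non-negative", call. = FALSE)
  ifelse(t_haqs >= thresholds$upper, 1L,
         ifelse(t_haqs <= thresholds$lower, 3L, 2L))
}

# the 21 published training-sample ids, 7 per grade
reference_training_ids <- function() {
  list(`1` = c(6L, 7L, 12L, 15L, 19L, 20L, 21L),
       `2` = c(1L, 2L, 3L, 4L, 8L, 11L, 17L),
       `3` = c(5L, 9L, 10L, 14L, 16L, 27L, 30L))
}

#' Reference train/test split
#'
#' The canonical calibration split: 21 listed training samples (7 per grade)
#' drawn from the middle of each grade's content range, with the remaining
#' samples held out as the test set (13 for the packaged dataset).
#'
#' @param samples A `herb_samples` data frame containing all 21 training ids.
#' @return A list with integer vectors `training_ids` and `test_ids`.
#' @export
reference_split <- function(samples) {
  train <- unlist(reference_training_ids(), use.names = FALSE)
  missing <- setdiff(train, samples$sample_id)
  if (length(missing))
    stop("sample id(s) missing from dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  list(training_ids = train,
       test_ids = setdiff(samples$sample_id, train))
}

#' Train/test split by proximity to the grade thresholds
#'
#' Selects as training candidates the samples whose total HAQ content lies
#' within a relative band around the grade's defining threshold(s): within
#' `fraction * threshold` of the upper threshold for grade 1, of either
#' threshold for grade 2, and of the lower threshold for grade 3. This is a
#' documented, configurable approximation of a threshold-relative selection
#' rule; [reference_split()] is the canonical split for the packaged dataset.
#'
#' @param samples A `herb_samples` data frame with a complete `haq_total`
#'   column.
#' @param fraction Relative half-width of the selection band (default 0.20).
#' @param thresholds A [grade_thresholds()] object.
#' @return A list with integer vectors `training_ids` and `test_ids`.
#' @export
intermediate_band_split <- function(samples, fraction = 0.20,
                                    thresholds = grade_thresholds()) {
  if (is.null(samples$haq_total) || anyNA(samples$haq_total))
    stop("every sample must carry haq_total", call. = FALSE)
  if (fraction < 0) stop("fraction must be non-negative", call. = FALSE)
  refs <- list(`1` = thresholds$upper,
               `2` = c(thresholds$lower, thresholds$upper),
               `3` = thresholds$lower)
  in_band <- vapply(seq_len(nrow(samples)), function(i) {
    r <- refs[[as.character(samples$grade[i])]]
    any(abs(samples$haq_total[i] - r) <= fraction * r)
  }, logical(1))
  list(training_ids = samples$sample_id[in_band],
       test_ids = samples$sample_id[!in_band])
}
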