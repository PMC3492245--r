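#' @title Synthetic graded color datasets
#' @name synthetic
#' @description
#' Generates datasets with the statistical structure the grading pipeline
#' assumes: per-grade Gaussian RGB clusters (channels independent,
#' truncated to 0--255 by rejection and rounded to integers) and per-grade
#' total-HAQ contents consistent with the grade thresholds. Every draw is
#' reproducible from the configuration seed.
NULL

# truncated normal by rejection sampling; keeps interior-cluster means unbiased
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Synthetic dataset configuration
#'
#' Defaults emulate three alkaline-developed rhubarb powder clusters of
#' realistic location and spread: per-grade channel means near the observed
#' cluster centers with a common within-grade standard deviation of 8
#' channel units, 20 samples per grade, and per-grade HAQ contents placed
#' centrally inside each grade's threshold band.
#'
#' @param means 3 x 3 matrix of per-grade RGB means (rows = grades 1--3).
#' @param sds Per-grade within-cluster channel standard deviation(s),
#'   recycled to length 3.
#' @param n_per_grade Samples per grade.
#' @param haq_means,haq_sds Per-grade mean and SD of the total HAQ content
#'   (mg/g); each mean must lie inside its grade's threshold band and the
#'   means must decrease with grade number.
#' @param thresholds A [grade_thresholds()] object.
#' @param seed Integer seed.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(means = rbind(c(150, 65, 45),
                                           c(195, 85, 40),
                                           c(210, 135, 70)),
                             sds = 8, n_per_grade = 20L,
                             haq_means = c(45, 32.5, 18),
                             haq_sds = c(3, 3, 3),
                             thresholds = grade_thresholds(),
                             seed = 1L) {
  means <- as.matrix(means)
  stopifnot(all(dim(means) == c(3, 3)), n_per_grade >= 1)
  sds <- rep_len(sds, 3)
  haq_sds <- rep_len(haq_sds, 3)
  if (any(sds < 0) || any(haq_sds < 0))
    stop("standard deviations must be non-negative", call. = FALSE)
  if (any(means < 0) || any(means > 255))
    stop("channel means must lie in [0, 255]", call. = FALSE)
  if (!(haq_means[1] > haq_means[2] && haq_means[2] > haq_means[3]))
    stop("haq_means must decrease from grade 1 to grade 3", call. = FALSE)
  if (any(assign_grade(haq_means, thresholds) != 1:3))
    stop("each haq mean must lie inside its grade's threshold band",
         call. = FALSE)
  structure(list(means = means, sds = sds,
                 n_per_grade = as.integer(n_per_grade),
                 haq_means = haq_means, haq_sds = haq_sds,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "synthetic_config")
}

# per-grade HAQ band under the thresholds (grade bands are half-open at
# the interior boundaries; a wide outer range stands in for infinity)
haq_band <- function(grade, thresholds) {
  switch(grade,
         c(thresholds$upper, thresholds$upper * 4),
         c(thresholds$lower + 1e-9, thresholds$upper - 1e-9),
         c(0, thresholds$lower))
}

#' Generate a synthetic graded color dataset
#'
#' Draws `n_per_grade` samples per grade. Every color source of a sample
#' receives an independent draw from the grade's truncated-normal channel
#' distribution; the total HAQ content is drawn from the grade's normal
#' truncated to the grade's threshold band, so each label agrees with
#' [assign_grade()] of its content.
#'
#' @param cfg A [synthetic_config()].
#' @return A `herb_samples` data frame with `haq_total`.
#' @export
generate_samples <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    rows <- list()
    id <- 0L
    for (g in 1:3) {
      band <- haq_band(g, cfg$thresholds)
      for (i in seq_len(cfg$n_per_grade)) {
        id <- id + 1L
        row <- list(sample_id = id, origin = sprintf("synthetic grade %d", g),
                    grade = g)
        for (src in color_sources()) {
          ch <- vapply(1:3, function(k)
            rtruncnorm(1, cfg$means[g, k], cfg$sds[g], 0, 255), numeric(1))
          ch <- as.integer(pmin(255, pmax(0, round_half_up(ch))))
          row[paste(src, c("R", "G", "B"), sep = "_")] <- as.list(ch)
        }
        row$haq_total <- rtruncnorm(1, cfg$haq_means[g], cfg$haq_sds[g],
                                    band[1], band[2])
        rows[[id]] <- as.data.frame(row)
      }
    }
    validate_samples(do.call(rbind, rows))
  })
}

#' Generate a synthetic repeat-measurement set
#'
#' Emulates repeated RGB readings of one object: Gaussian channel noise
#' around a base color, truncated to 0--255 and rounded to integers.
#'
#' @param base Base RGB triple (0--255).
#' @param sd Per-channel noise SD, recycled to length 3.
#' @param n Number of readings (>= 2).
#' @param seed Integer seed.
#' @param condition Condition label passed to [repeat_measurements()].
#' @return A `repeat_measurements` object.
#' @export
generate_repeats <- function(base, sd, n, seed = 1L, condition = "synthetic") {
  check_rgb(base, "base")
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  sd <- rep_len(sd, 3)
  with_seed(seed, {
    readings <- vapply(1:3, function(k)
      round_half_up(rtruncnorm(n, base[k], sd[k], 0, 255)), numeric(n))
  })
  repeat_measurements(readings, condition)
}
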