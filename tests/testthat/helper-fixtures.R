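# shared helpers: tiny in-code fixtures and independent oracles

# a minimal valid dataset of n samples with the given grades
make_samples <- function(grades, haq = NULL, rgb = NULL) {
  n <- length(grades)
  df <- data.frame(sample_id = seq_len(n), origin = "test", grade = grades)
  for (src in color_sources()) {
    m <- if (is.null(rgb)) matrix(100L + seq_len(n) %% 50, n, 3) else rgb
    df[paste(src, c("R", "G", "B"), sep = "_")] <- m
  }
  if (!is.null(haq)) df$haq_total <- haq
  herbgrade:::validate_samples(df)
}

# well-separated synthetic study conditions (cluster separation >= 5x SD)
separated_config <- function(seed = 1L, n_per_grade = 20L, sds = 8) {
  synthetic_config(seed = seed, n_per_grade = n_per_grade, sds = sds)
}

# three clusters pushed apart by d channel units in distinct chromatic
# directions (hue changes, not just brightness), so the separation survives
# the luminance-normalizing chromaticity projection
directional_config <- function(d, sd = 6, seed = 1L, n_per_grade = 20L) {
  centre <- c(180, 90, 45)
  synthetic_config(means = rbind(centre + d * c(1, -1, 0),
                                 centre + d * c(0, 1, -1),
                                 centre + d * c(-1, 0, 1)),
                   sds = sd, n_per_grade = n_per_grade, seed = seed)
}

# independent angular classifier: recomputes the three ray angles with atan2
brute_classify <- function(p, O, D) {
  a <- atan2(p[2] - D[2], p[1] - D[1])
  ang <- sapply(1:3, function(g) {
    b <- atan2(O[g, 2] - D[2], O[g, 1] - D[1])
    d <- abs(a - b) %% (2 * pi)
    min(d, 2 * pi - d)
  })
  which.min(ang)
}
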