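test_that("expectation and division points are arithmetic means", {
  p <- c(0.41, 0.33)
  expect_equal(unname(expectation_point(p)), p)
  pts <- rbind(c(0.40, 0.30), c(0.46, 0.36), c(0.43, 0.33))
  expect_equal(expectation_point(pts), expectation_point(pts[c(3, 1, 2), ]))
  expect_error(expectation_point(NULL), "at least one")

  # the published expectation points give the published division point
  d <- division_point(c(0.4315, 0.3031), c(0.4819, 0.3408), c(0.4277, 0.3677))
  expect_equal(unname(round(d, 4)), c(0.4470, 0.3372))
  # centroid of three identical points is that point, in any input order
  expect_equal(unname(division_point(p, p, p)), p)
  expect_equal(division_point(c(0.4, 0.3), c(0.46, 0.36), c(0.43, 0.33)),
               division_point(c(0.43, 0.33), c(0.4, 0.3), c(0.46, 0.36)))
})

test_that("a built scale is internally consistent and matches brute force", {
  s <- herb_table1()
  scale <- build_scale(s)
  expect_equal(unname(scale$division_point),
               unname(colMeans(scale$expectation_points)), tolerance = 1e-12)
  expect_equal(scale$representative_ids, reference_representatives())

  # expectation points equal an independent per-grade mean of chromaticities
  X <- rgb_matrix(s, "powder_colored")
  for (g in 1:3) {
    ids <- reference_representatives()[[g]]
    pts <- t(sapply(ids, function(id) {
      v <- X[as.character(id), ] / 255
      xyz <- c(0.4124 * v[1] + 0.3576 * v[2] + 0.1805 * v[3],
               0.2126 * v[1] + 0.7152 * v[2] + 0.0722 * v[3],
               0.0193 * v[1] + 0.1192 * v[2] + 0.9505 * v[3])
      xyz[1:2] / sum(xyz)
    }))
    expect_equal(unname(scale$expectation_points[g, ]), unname(colMeans(pts)),
                 tolerance = 1e-12)
  }

  # random representative subsets agree with the brute-force mean too
  set.seed(21)
  for (rep in 1:5) {
    ids <- lapply(split(s$sample_id, s$grade), function(v)
      sample(v, sample(2:4, 1)))
    names(ids) <- 1:3
    sc <- build_scale(s, representative_ids = ids)
    for (g in 1:3) {
      pts <- t(sapply(ids[[g]], function(id)
        rgb_to_chromaticity(X[as.character(id), ])))
      expect_equal(unname(sc$expectation_points[g, ]), unname(colMeans(pts)))
    }
  }

  expect_error(build_scale(s, representative_ids = list(`1` = 99L, `2` = 1L,
                                                        `3` = 5L)), "99")
  expect_error(build_scale(s, representative_ids = list(`1` = integer(0),
                                                        `2` = 1L, `3` = 5L)),
               "no representative")
})

test_that("sector classification agrees with an independent angular oracle", {
  scale <- build_scale(herb_table1())
  O <- scale$expectation_points
  D <- scale$division_point

  # each expectation point classifies as its own grade
  for (g in 1:3) expect_equal(classify_point(O[g, ], scale), g)
  # the division point itself falls to grade 1 by the tie rule
  expect_equal(classify_point(D, scale), 1L)

  set.seed(33)
  pts <- cbind(runif(1000, 0.25, 0.65), runif(1000, 0.2, 0.45))
  got <- apply(pts, 1, classify_point, scale = scale)
  want <- apply(pts, 1, brute_classify, O = O, D = D)
  expect_equal(got, want)

  # classification depends only on the direction from D, not the distance
  for (i in 1:50) {
    p <- pts[i, ]
    for (f in c(0.05, 0.5, 3)) {
      q <- D + f * (p - D)
      expect_equal(classify_point(q, scale), got[i])
    }
  }

  degen <- scale
  degen$expectation_points[1, ] <- D
  degen$expectation_points[2, ] <- D
  expect_error(classify_point(c(0.4, 0.33), degen), "degenerate")
})

test_that("the nearest-expectation rule is available as an alternative", {
  scale <- build_scale(herb_table1(), rule = "nearest")
  O <- scale$expectation_points
  set.seed(4)
  pts <- cbind(runif(200, 0.25, 0.65), runif(200, 0.2, 0.45))
  got <- apply(pts, 1, classify_point, scale = scale)
  want <- apply(pts, 1, function(p)
    which.min(colSums((t(O) - p)^2)))
  expect_equal(got, want)
})

test_that("the rendered scale card is deterministic with distinct tiles", {
  scale <- build_scale(herb_table1())
  img <- render_scale_card(scale, tile_px = 8)
  expect_equal(dim(img), c(8, 4 * 8 + 3, 3))
  expect_equal(attr(img, "labels"), c("D", "O1", "O2", "O3"))
  tiles <- unique(apply(scale_colors(scale), 1, paste, collapse = ","))
  expect_length(tiles, 4L)
  expect_identical(img, render_scale_card(scale, tile_px = 8))

  # degenerate scale: all expectation points at D -> identical tiles
  degen <- scale
  degen$expectation_points[1, ] <- scale$division_point
  degen$expectation_points[2, ] <- scale$division_point
  degen$expectation_points[3, ] <- scale$division_point
  degen$division_point <- scale$division_point
  cols <- scale_colors(degen)
  expect_equal(nrow(unique(cols)), 1L)

  # written card is byte-identical across renders
  t1 <- withr::local_tempfile(fileext = ".png")
  t2 <- withr::local_tempfile(fileext = ".png")
  write_scale_card(scale, t1, tile_px = 8)
  write_scale_card(scale, t2, tile_px = 8)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
})

test_that("a saved scale reloads equal and classifies identically", {
  scale <- build_scale(herb_table1())
  tmp <- withr::local_tempfile(fileext = ".json")
  scale_save(scale, tmp)
  s2 <- scale_load(tmp)
  expect_equal(s2$expectation_points, scale$expectation_points, tolerance = 0)
  expect_equal(s2$division_point, scale$division_point, tolerance = 0)
  expect_equal(classify_rgb(c(180, 90, 45), s2),
               classify_rgb(c(180, 90, 45), scale))
})
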