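test_that("standardization gives zero-mean unit-SD columns and round trips", {
  set.seed(5)
  X <- matrix(runif(60, 0, 255), 20, 3)
  y <- sample(1:3, 20, replace = TRUE)
  std <- standardize(X, y)
  expect_true(all(abs(colMeans(std$features)) < 1e-12))
  expect_equal(unname(apply(std$features, 2, sd)), rep(1, 3), tolerance = 1e-12)
  back <- sweep(sweep(std$features, 2, std$stats$x_sd, "*"), 2,
                std$stats$x_mean, "+")
  expect_equal(back, X, tolerance = 1e-10)
  expect_equal(std$targets * std$stats$y_sd + std$stats$y_mean, y,
               tolerance = 1e-10)
  X[, 2] <- 10
  expect_error(standardize(X, y), "zero-variance")
})

test_that("initialization is seeded, dimensioned by config, and validated", {
  m1 <- init_network(bp_config(seed = 1))
  m2 <- init_network(bp_config(seed = 1))
  expect_identical(m1, m2)
  expect_equal(dim(m1$W1), c(7L, 3L))  # 2N+1 hidden units for N = 3 inputs
  expect_length(m1$W2, 7L)
  expect_true(all(abs(c(m1$W1, m1$W2)) <= 0.5))
  expect_equal(m1$b1, rep(0, 7))
  expect_false(identical(m1$W1, init_network(bp_config(seed = 2))$W1))
  expect_error(bp_config(n_hidden = 0), "layer sizes")
  expect_error(bp_config(momentum = 1), "momentum")
})

test_that("forward pass matches an independently hand-coded evaluation", {
  m <- init_network(bp_config(seed = 9, n_hidden = 4))
  m$b1 <- c(0.1, -0.2, 0.3, 0)
  m$b2 <- 0.25
  m$stats <- list(x_mean = c(150, 90, 45), x_sd = c(30, 20, 10),
                  y_mean = 2, y_sd = 0.8)
  rgb <- c(170, 64, 51)
  # explicit scalar re-evaluation of the two-layer algebra
  xs <- (rgb - m$stats$x_mean) / m$stats$x_sd
  acc <- m$b2
  for (j in 1:4) {
    z <- m$b1[j]
    for (k in 1:3) z <- z + m$W1[j, k] * xs[k]
    acc <- acc + m$W2[j] * tanh(z)
  }
  expect_equal(bp_forward(m, rgb), acc * m$stats$y_sd + m$stats$y_mean,
               tolerance = 1e-12)

  # zero weights force the de-standardized target mean
  z <- m
  z$W1[] <- 0; z$W2[] <- 0; z$b1[] <- 0; z$b2 <- 0
  expect_equal(bp_forward(z, c(10, 200, 99)), 2)

  # bounded hidden units keep every output finite
  set.seed(2)
  probe <- matrix(sample(0:255, 60, replace = TRUE), 20, 3)
  expect_true(all(is.finite(bp_forward(m, probe))))
})

test_that("analytic gradients match central finite differences", {
  set.seed(17)
  X <- matrix(runif(30, -2, 2), 10, 3)
  y <- runif(10, -1.5, 1.5)
  for (seed in c(1, 7, 23)) {
    m <- init_network(bp_config(seed = seed, n_hidden = 5))
    m$b1 <- runif(5, -0.3, 0.3); m$b2 <- runif(1, -0.3, 0.3)
    pars <- m[c("W1", "b1", "W2", "b2")]
    g <- herbgrade:::bp_gradient(pars, X, y)
    h <- 1e-6
    for (nm in names(pars)) {
      for (i in seq_along(pars[[nm]])) {
        up <- pars; up[[nm]][i] <- up[[nm]][i] + h
        dn <- pars; dn[[nm]][i] <- dn[[nm]][i] - h
        fd <- (herbgrade:::mse_of(up, X, y) - herbgrade:::mse_of(dn, X, y)) / (2 * h)
        expect_equal(g[[nm]][i], fd, tolerance = 1e-6)
      }
    }
  }
})

test_that("training is deterministic, monotone, and fits separable clusters", {
  cfg <- separated_config(seed = 7)
  cfg$sds <- rep(2, 3)  # tight clusters
  s <- generate_samples(cfg)
  X <- rgb_matrix(s, "powder_colored")
  m1 <- bp_train(init_network(bp_config(seed = 7)), X, s$grade)
  m2 <- bp_train(init_network(bp_config(seed = 7)), X, s$grade)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$training_record, m2$training_record)
  # uphill steps are rejected, so the recorded MSE never increases
  expect_true(all(diff(m1$training_record) <= 0))
  ev <- bp_evaluate(m1, s, "powder_colored")
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$n_correct, nrow(s))
  expect_error(bp_evaluate(m1, s, "nonsense"), "unknown color source")
})

test_that("training runs to the epoch cap when the goal cannot trigger", {
  s <- generate_samples(separated_config(seed = 3, n_per_grade = 4L))
  X <- rgb_matrix(s, "powder_colored")
  m <- bp_train(init_network(bp_config(seed = 1, max_epochs = 37L,
                                       goal_mse = 0)), X, s$grade)
  expect_length(m$training_record, 37L)
})

test_that("output binning reproduces the published grade intervals", {
  # full sweep at 2-decimal resolution against an explicit interval table
  v <- seq(0L, 400L) / 100
  want <- rep(NA_integer_, length(v))
  want[v >= 0.51 & v <= 1.50] <- 1L
  want[v >= 1.51 & v <= 2.50] <- 2L
  want[v >= 2.51 & v <= 3.50] <- 3L
  expect_equal(bin_output(v), want)
  # published endpoints
  expect_equal(bin_output(1.2), 1L)
  expect_equal(bin_output(c(1.50, 2.50, 3.50)), c(1L, 2L, 3L))
  expect_equal(bin_output(2.51), 3L)
  expect_true(is.na(bin_output(3.6)))
  expect_true(is.na(bin_output(0.4)))
  expect_error(bin_output(NaN), "finite")
  expect_error(bin_output(Inf), "finite")
})

test_that("a saved model reloads bit for bit and predicts identically", {
  s <- generate_samples(separated_config(seed = 2, n_per_grade = 5L))
  X <- rgb_matrix(s, "powder_colored")
  m <- bp_train(init_network(bp_config(seed = 4, max_epochs = 200L)),
                X, s$grade)
  tmp <- withr::local_tempfile(fileext = ".json")
  bp_save(m, tmp)
  m2 <- bp_load(tmp)
  expect_equal(m2$W1, m$W1, tolerance = 0)
  expect_equal(m2$stats$x_mean, m$stats$x_mean, tolerance = 0)
  expect_equal(bp_forward(m2, c(150, 65, 45)), bp_forward(m, c(150, 65, 45)),
               tolerance = 0)
})
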