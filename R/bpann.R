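#' @title Three-layer back-propagation network for grade prediction
#' @name bpann
#' @description
#' A fully connected feed-forward network with 3 inputs (the R, G, B
#' channels), one hidden layer of hyperbolic-tangent units (default 7,
#' i.e. 2N+1 for N = 3 inputs) and a single linear output unit that
#' regresses the grade number. Inputs and targets are z-scored before
#' training; training is full-batch gradient descent on the mean squared
#' error with momentum and an adaptive learning rate (increase after an
#' epoch that lowers the error, decrease and reset momentum after a
#' rejected uphill step). The continuous output is mapped back to a grade
#' label by [bin_output()].
NULL

#' Network configuration
#'
#' Defaults follow the published training setup: 7 hidden nodes (2N+1),
#' learning rate 0.05, at most 4500 epochs, goal mean squared error 1e-6.
#' Momentum 0.9 and adaptive factors 1.05 / 0.7 are the conventional
#' defaults of gradient descent with momentum and adaptive learning rate.
#'
#' @param n_hidden Number of hidden units (default 7; 21 mirrors an
#'   alternative published layer size).
#' @param max_epochs Maximum training epochs.
#' @param goal_mse Stop when the standardized-target MSE falls to this.
#' @param learning_rate Initial learning rate.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param lr_increase,lr_decrease Multiplicative learning-rate adaptation
#'   factors applied after downhill / uphill epochs.
#' @param seed Integer seed for weight initialization.
#' @param n_input,n_output Layer sizes; fixed at 3 and 1 for this pipeline
#'   but configurable for testing.
#' @return A `bp_config` object.
#' @export
bp_config <- function(n_hidden = 7L, max_epochs = 4500L, goal_mse = 1e-6,
                      learning_rate = 0.05, momentum = 0.9,
                      lr_increase = 1.05, lr_decrease = 0.7,
                      seed = 1L, n_input = 3L, n_output = 1L) {
  if (n_hidden < 1L || n_input < 1L || n_output != 1L)
    stop("invalid layer sizes: need n_input >= 1, n_hidden >= 1, n_output = 1",
         call. = FALSE)
  if (momentum < 0 || momentum >= 1)
    stop("momentum must lie in [0, 1)", call. = FALSE)
  if (learning_rate <= 0 || lr_increase <= 0 || lr_decrease <= 0)
    stop("learning rate and adaptation factors must be positive", call. = FALSE)
  structure(list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
                 n_output = 1L, max_epochs = as.integer(max_epochs),
                 goal_mse = goal_mse, learning_rate = learning_rate,
                 momentum = momentum, lr_increase = lr_increase,
                 lr_decrease = lr_decrease, seed = as.integer(seed)),
            class = "bp_config")
}

#' Z-score standardization of features and targets
#'
#' Each feature column and the target are shifted and scaled to mean 0 and
#' sample standard deviation 1; the statistics are returned for inverse
#' transforms and for standardizing new inputs.
#'
#' @param features An n x p numeric matrix (n >= 2, no constant column).
#' @param targets Numeric vector of length n.
#' @return List with `features` (standardized matrix), `targets`
#'   (standardized vector) and `stats` (means and sds).
#' @export
standardize <- function(features, targets) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 samples", call. = FALSE)
  x_mean <- colMeans(features)
  x_sd <- apply(features, 2, stats::sd)
  if (any(x_sd == 0))
    stop("zero-variance feature column: ",
         paste(which(x_sd == 0), collapse = ", "), call. = FALSE)
  y_mean <- mean(targets)
  y_sd <- stats::sd(targets)
  if (y_sd == 0) stop("zero-variance targets", call. = FALSE)
  list(features = sweep(sweep(features, 2, x_mean), 2, x_sd, "/"),
       targets = (targets - y_mean) / y_sd,
       stats = list(x_mean = unname(x_mean), x_sd = unname(x_sd),
                    y_mean = y_mean, y_sd = y_sd))
}

apply_stats <- function(features, stats) {
  sweep(sweep(as.matrix(features), 2, stats$x_mean), 2, stats$x_sd, "/")
}

#' Initialize a network
#'
#' Weights are drawn uniformly from `[-0.5, 0.5]` with the configured seed
#' (input-to-hidden matrix first, then hidden-to-output vector); biases
#' start at zero. The same seed always yields identical weights.
#'
#' @param config A [bp_config()] object.
#' @return An untrained `bp_model` (standardization statistics are attached
#'   by [bp_train()]).
#' @export
init_network <- function(config = bp_config()) {
  stopifnot(inherits(config, "bp_config"))
  with_seed(config$seed, {
    W1 <- matrix(stats::runif(config$n_hidden * config$n_input, -0.5, 0.5),
                 nrow = config$n_hidden, ncol = config$n_input)
    W2 <- stats::runif(config$n_hidden, -0.5, 0.5)
  })
  structure(list(W1 = W1, b1 = numeric(config$n_hidden),
                 W2 = W2, b2 = 0,
                 stats = NULL, config = config,
                 training_record = numeric(0)),
            class = "bp_model")
}

# forward pass in standardized space; Xs is n x p
forward_std <- function(pars, Xs) {
  Z1 <- tcrossprod(Xs, pars$W1)          # n x h
  Z1 <- sweep(Z1, 2, pars$b1, "+")
  H <- tanh(Z1)
  out <- drop(H %*% pars$W2) + pars$b2
  list(H = H, out = out)
}

mse_of <- function(pars, Xs, ys) {
  mean((forward_std(pars, Xs)$out - ys)^2)
}

# analytic gradient of the standardized-target MSE
bp_gradient <- function(pars, Xs, ys) {
  fw <- forward_std(pars, Xs)
  n <- length(ys)
  dout <- 2 * (fw$out - ys) / n          # n
  gW2 <- drop(crossprod(fw$H, dout))     # h
  gb2 <- sum(dout)
  dZ1 <- (outer(dout, pars$W2)) * (1 - fw$H^2)  # n x h
  gW1 <- crossprod(dZ1, Xs)              # h x p
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Evaluate the network on an RGB input
#'
#' Standardizes the input with the statistics stored at training time,
#' propagates it through the tanh hidden layer and the linear output unit,
#' and de-standardizes the result onto the grade scale.
#'
#' @param model A trained `bp_model`.
#' @param rgb An RGB triple (0--255) or an n x 3 matrix of triples.
#' @return Continuous grade value(s).
#' @seealso [bin_output()] to map values to grade labels.
#' @export
bp_forward <- function(model, rgb) {
  stopifnot(inherits(model, "bp_model"))
  if (is.null(model$stats))
    stop("model has no standardization statistics; train it first",
         call. = FALSE)
  X <- if (is.matrix(rgb)) rgb else matrix(rgb, nrow = 1)
  if (ncol(X) != model$config$n_input)
    stop("input must have ", model$config$n_input, " columns", call. = FALSE)
  apply(X, 1, check_rgb)
  out <- forward_std(model, apply_stats(X, model$stats))$out
  out * model$stats$y_sd + model$stats$y_mean
}

#' Train the network
#'
#' Full-batch gradient descent on the mean squared error of the z-scored
#' targets, with momentum and adaptive learning rate: a candidate step is
#' rejected when it would increase the error (the learning rate is then
#' multiplied by `lr_decrease` and the momentum buffer reset), otherwise
#' accepted with the learning rate multiplied by `lr_increase`. Training
#' stops when the error reaches `goal_mse` or after `max_epochs` epochs.
#' Deterministic given the data and the configuration seed.
#'
#' @param model A `bp_model` from [init_network()].
#' @param features An n x 3 matrix of RGB triples (n >= 2).
#' @param grades Numeric grade targets of length n (used as continuous
#'   regression targets).
#' @return The trained `bp_model` with `stats` and a per-epoch
#'   `training_record` of the standardized MSE.
#' @export
bp_train <- function(model, features, grades) {
  stopifnot(inherits(model, "bp_model"))
  features <- as.matrix(features)
  if (nrow(features) < 2L || nrow(features) != length(grades))
    stop("need >= 2 training samples with one grade each", call. = FALSE)
  std <- standardize(features, grades)
  Xs <- std$features; ys <- std$targets
  cfg <- model$config
  pars <- model[c("W1", "b1", "W2", "b2")]
  vel <- list(W1 = pars$W1 * 0, b1 = pars$b1 * 0, W2 = pars$W2 * 0, b2 = 0)
  lr <- cfg$learning_rate
  mc <- cfg$momentum
  cur <- mse_of(pars, Xs, ys)
  record <- numeric(cfg$max_epochs)
  epoch <- 0L
  while (epoch < cfg$max_epochs && cur > cfg$goal_mse) {
    epoch <- epoch + 1L
    g <- bp_gradient(pars, Xs, ys)
    cand_vel <- lapply(names(vel), function(k) mc * vel[[k]] + (1 - mc) * lr * g[[k]])
    names(cand_vel) <- names(vel)
    cand <- lapply(names(pars), function(k) pars[[k]] - cand_vel[[k]])
    names(cand) <- names(pars)
    new <- mse_of(cand, Xs, ys)
    if (!is.finite(new))
      stop("training diverged (non-finite MSE) at epoch ", epoch, call. = FALSE)
    if (new > cur) {
      # reject uphill step
      lr <- lr * cfg$lr_decrease
      vel <- lapply(vel, function(v) v * 0)
    } else {
      if (new < cur) lr <- lr * cfg$lr_increase
      pars <- cand
      vel <- cand_vel
      cur <- new
    }
    record[epoch] <- cur
  }
  model$W1 <- unname(pars$W1); model$b1 <- unname(pars$b1)
  model$W2 <- unname(pars$W2); model$b2 <- unname(pars$b2)
  model$stats <- std$stats
  model$training_record <- record[seq_len(epoch)]
  model
}

#' Bin a continuous grade value into a grade label
#'
#' Values in (0.51--1.50] map to grade 1, (1.51--2.50] to grade 2,
#' (2.51--3.50] to grade 3; nearest-integer rounding (halves down) closes
#' the 0.01-wide gaps between the printed intervals. Values below 0.51 or
#' above 3.50 are invalid predictions and return `NA`.
#'
#' @param value Finite numeric value(s).
#' @return Integer grade label(s); `NA` for invalid predictions.
#' @export
bin_output <- function(value) {
  if (any(!is.finite(value)))
    stop("bin_output requires finite values", call. = FALSE)
  g <- as.integer(ceiling(value - 0.5))
  g[value < 0.51 | value > 3.50] <- NA_integer_
  g
}

#' Accuracy of a trained network on labeled samples
#'
#' Predicts each sample's grade from the chosen color source, bins the
#' continuous outputs, and scores a prediction as correct only when the
#' binned grade equals the label (invalid outputs are always incorrect).
#'
#' @param model A trained `bp_model`.
#' @param samples A `herb_samples` data frame.
#' @param color_source One of [color_sources()].
#' @return List with `accuracy` (percent, rounded half up to 1 dp),
#'   `n_correct`, `n`, and a per-sample `predictions` data frame.
#' @export
bp_evaluate <- function(model, samples, color_source) {
  X <- rgb_matrix(samples, color_source)
  out <- bp_forward(model, X)
  pred <- bin_output(out)
  correct <- !is.na(pred) & pred == samples$grade
  list(accuracy = round_half_up(100 * mean(correct), 1),
       n_correct = sum(correct), n = nrow(samples),
       predictions = data.frame(sample_id = samples$sample_id,
                                grade = samples$grade,
                                output = out, predicted = pred,
                                correct = correct))
}

#' Save / load a trained network
#'
#' Serializes weights, biases, standardization statistics and configuration
#' to a JSON file with full double precision, so that a save/load round
#' trip reproduces the model bit for bit.
#'
#' @param model A `bp_model`.
#' @param path JSON file path.
#' @return `bp_save` returns `path` invisibly; `bp_load` returns the model.
#' @export
bp_save <- function(model, path) {
  stopifnot(inherits(model, "bp_model"))
  payload <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
                  stats = model$stats,
                  config = unclass(model$config),
                  training_record = model$training_record)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname bp_save
#' @export
bp_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(bp_config, p$config)
  stats <- if (is.null(p$stats)) NULL else p$stats
  W1 <- p$W1
  if (!is.matrix(W1))
    W1 <- matrix(unlist(W1), nrow = cfg$n_hidden, ncol = cfg$n_input,
                 byrow = TRUE)
  structure(list(W1 = unname(W1),
                 b1 = as.numeric(p$b1),
                 W2 = as.numeric(p$W2), b2 = as.numeric(p$b2),
                 stats = stats, config = cfg,
                 training_record = as.numeric(p$training_record)),
            class = "bp_model")
}
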