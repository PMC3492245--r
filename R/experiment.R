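#' @title Grade-prediction experiment harness
#' @name experiment
#' @description
#' Wires the pipeline end to end: train the back-propagation network on the
#' reference split for a chosen color source, evaluate on the held-out test
#' samples and on the full dataset, and summarize over several random weight
#' initializations by the modal correct count. Because training is
#' stochastic in its initialization, the modal result over seeds is the
#' stable summary.
NULL

#' Run the grade-prediction experiment for one color source
#'
#' For each seed: initialize the network, train it on the RGB values of the
#' training samples only (test labels are never seen during training),
#' predict all samples, bin the outputs, and count correct predictions on
#' the test set and over the whole dataset. Accuracies are percentages
#' rounded half up to 1 decimal place; the summary is the modal correct
#' count over seeds.
#'
#' @param source One of [color_sources()].
#' @param seeds Integer vector of initialization seeds (default 1:10).
#' @param samples A `herb_samples` data frame (default the packaged
#'   34-sample dataset).
#' @param split A list with `training_ids` and `test_ids` (default the
#'   reference split).
#' @param config A [bp_config()]; its `seed` field is overridden per run.
#' @param predictor Optional function `(train_X, train_y, all_X) ->
#'   continuous outputs` replacing the network (a harness hook for oracle
#'   checks).
#' @return List with `per_seed` (data frame of per-seed counts and
#'   accuracies), `modal_test_correct`, `modal_test_accuracy`,
#'   `modal_overall_correct`, `modal_overall_accuracy`, `n_test`, `n_total`,
#'   and `predictions` (per-sample table from the first seed attaining the
#'   modal test count).
#' @export
run_grade_experiment <- function(source, seeds = 1:10,
                                 samples = herb_table1(),
                                 split = reference_split(samples),
                                 config = bp_config(),
                                 predictor = NULL) {
  X <- rgb_matrix(samples, source)
  train_idx <- match(split$training_ids, samples$sample_id)
  test_idx <- match(split$test_ids, samples$sample_id)
  stopifnot(!anyNA(train_idx), !anyNA(test_idx))
  train_X <- X[train_idx, , drop = FALSE]
  train_y <- samples$grade[train_idx]

  per_seed <- data.frame(seed = seeds, test_correct = NA_integer_,
                         test_accuracy = NA_real_,
                         overall_correct = NA_integer_,
                         overall_accuracy = NA_real_)
  pred_tables <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    out <- if (is.null(predictor)) {
      cfg <- config; cfg$seed <- as.integer(seeds[i])
      model <- bp_train(init_network(cfg), train_X, train_y)
      bp_forward(model, X)
    } else {
      predictor(train_X, train_y, X)
    }
    pred <- bin_output(out)
    correct <- !is.na(pred) & pred == samples$grade
    per_seed$test_correct[i] <- sum(correct[test_idx])
    per_seed$overall_correct[i] <- sum(correct)
    pred_tables[[i]] <- data.frame(sample_id = samples$sample_id,
                                   grade = samples$grade, output = out,
                                   predicted = pred, correct = correct,
                                   in_test = seq_len(nrow(samples)) %in% test_idx)
  }
  n_test <- length(test_idx); n_total <- nrow(samples)
  per_seed$test_accuracy <- round_half_up(100 * per_seed$test_correct / n_test, 1)
  per_seed$overall_accuracy <- round_half_up(100 * per_seed$overall_correct / n_total, 1)
  modal_test <- modal_count(per_seed$test_correct)
  modal_overall <- modal_count(per_seed$overall_correct)
  list(source = source, per_seed = per_seed,
       modal_test_correct = as.integer(modal_test),
       modal_test_accuracy = round_half_up(100 * modal_test / n_test, 1),
       modal_overall_correct = as.integer(modal_overall),
       modal_overall_accuracy = round_half_up(100 * modal_overall / n_total, 1),
       n_test = n_test, n_total = n_total,
       predictions = pred_tables[[match(modal_test, per_seed$test_correct)]])
}

#' Run configuration for scripted pipelines
#'
#' Validates a flat list of run options; unknown keys are rejected so that
#' configuration typos fail loudly.
#'
#' @param ... Named options among: `convention`, `color_source`, `split`
#'   (`"reference"`, `"band"` or `"custom"`), `seed`, `seeds`, `n_hidden`,
#'   `max_epochs`, `goal_mse`, `learning_rate`, `momentum`, `lr_increase`,
#'   `lr_decrease`, `out`, `verbose`.
#' @return A named list of the resolved options with class `run_config`.
#' @export
run_config <- function(...) {
  opts <- list(...)
  allowed <- c("convention", "color_source", "split", "seed", "seeds",
               "n_hidden", "max_epochs", "goal_mse", "learning_rate",
               "momentum", "lr_increase", "lr_decrease", "out", "verbose")
  unknown <- setdiff(names(opts), allowed)
  if (length(unknown) || (length(opts) && any(names(opts) == "")))
    stop("unknown run option(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults <- list(convention = "srgb_linear", color_source = "powder_colored",
                   split = "reference", seed = 1L, verbose = FALSE)
  structure(utils::modifyList(defaults, opts), class = "run_config")
}
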