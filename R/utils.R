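# internal helpers shared across modules

#' @keywords internal
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' @keywords internal
check_rgb <- function(rgb, what = "rgb") {
  if (!is.numeric(rgb) || length(rgb) != 3L || anyNA(rgb))
    stop(sprintf("%s must be a numeric triple without NAs", what), call. = FALSE)
  if (any(rgb < 0) || any(rgb > 255))
    stop(sprintf("%s channels must lie in [0, 255]", what), call. = FALSE)
  invisible(rgb)
}

# statistical mode of integer counts; ties broken toward the value closest to
# the median, then toward the smaller count (deterministic)
#' @keywords internal
modal_count <- function(counts) {
  stopifnot(length(counts) >= 1L, !anyNA(counts))
  tab <- table(counts)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  if (length(cand) > 1L) {
    d <- abs(cand - stats::median(counts))
    cand <- cand[d == min(d)]
  }
  min(cand)
}
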