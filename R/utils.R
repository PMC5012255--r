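# internal helpers shared across modules

# DFT sample frequencies in cycles per sample, numpy-style ordering
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) / n
}

# run `expr` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# strictly increasing check with a helpful message
check_strictly_increasing <- function(x, name) {
  if (length(x) > 1L && any(diff(x) <= 0))
    abort(sprintf("`%s` must be strictly increasing.", name))
  invisible(x)
}

# median sampling interval; warns when sampling is visibly non-uniform
sampling_interval <- function(t) {
  dt <- diff(t)
  dtm <- median(dt)
  if (max(abs(dt - dtm)) > 0.05 * dtm)
    warn("Sampling is non-uniform; derivative estimates assume the median interval.")
  dtm
}
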