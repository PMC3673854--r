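## internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## row-wise maximum, vectorized over columns (much faster than apply)
row_max <- function(x) {
  m <- x[, 1L]
  if (ncol(x) > 1L) for (j in 2:ncol(x)) m <- pmax(m, x[, j])
  m
}

## row-wise log(sum(exp(x))) without overflow
logsumexp_rows <- function(x) {
  m <- row_max(x)
  m + log(rowSums(exp(x - m)))
}

## softmax over rows of a matrix of logits
softmax_rows <- function(x) {
  e <- exp(x - row_max(x))
  e / rowSums(e)
}

## derive a vector of sub-seeds from a master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## clamp probabilities away from 0/1
clamp_prob <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

## stop() with a stage tag so the pipeline can map failures to exit codes
stage_stop <- function(stage, msg) {
  cond <- structure(
    class = c("fallclass_stage_error", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = NULL, stage = stage)
  )
  stop(cond)
}

is_binary01 <- function(x) all(x %in% c(0, 1))

## truncated-normal draws with a hard floor (inverse-CDF method)
rtruncnorm_floor <- function(n, mean, sd, floor) {
  lo <- pnorm((floor - mean) / sd)
  qnorm(runif(n, lo, 1)) * sd + mean
}
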