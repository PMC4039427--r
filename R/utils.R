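# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  x
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  ok_lo <- if (closed_lower) x >= lower else x > lower
  ok_hi <- if (closed_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi)
    stopf("'%s' = %g is outside its valid range [%g, %g]", name, x, lower, upper)
  x
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stopf("'%s' must be an integer, got %g", name, x)
  as.integer(x)
}

#' Derive reproducible stage seeds from one global seed
#'
#' A single user-facing seed deterministically spawns one sub-seed per
#' pipeline stage, so any stage can be re-run in isolation with the same
#' stream it saw inside the full pipeline. Seeds stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`.
#' @export
spawn_seeds <- function(seed, n = 1L) {
  seed <- check_count(seed, "seed")
  n <- check_count(n, "n", lower = 1L)
  m <- 2147483647 # 2^31 - 1, Lehmer modulus
  s <- as.double(seed %% m)
  out <- integer(n)
  for (i in seq_len(n)) {
    # minimal-standard LCG step; double precision is exact below 2^53
    s <- (s * 48271 + 11) %% m
    out[i] <- as.integer(s)
  }
  out
}

# run expr under a local RNG state restored on exit
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
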