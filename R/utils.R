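#' Circular distance between genome positions
#'
#' Shortest arc distance between two 1-based positions on a circular
#' sequence of length `len`.
#'
#' @param a,b Positions (numeric vectors, recycled).
#' @param len Sequence length in bp.
#' @return Numeric vector of distances in bp, in `[0, len/2]`.
#' @export
circular_distance <- function(a, b, len) {
  d <- abs(a - b) %% len
  pmin(d, len - d)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## internal: scalar validators used by all entry points
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

## internal: seed handling -- simulators take an explicit seed so that the
## same spec always yields the same data; the caller's RNG stream resumes
## untouched afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_number(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
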