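#' @importFrom rlang %||% .data abort inform warn
#' @importFrom stats complete.cases cor dnorm median optim pnorm quantile
#'   rlnorm rnorm runif sd setNames t.test
#' @importFrom utils capture.output head packageVersion read.delim str
#'   write.csv
NULL

# round-half-up at a given number of digits (presentation-layer rounding;
# base round() uses banker's rounding which surprises in report tables)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic RNG scope: runs code with a local seed without disturbing
# the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stream-specific child seed below 2^31
child_seed <- function(seed, stream) {
  (seed * 48271 + str_hash(stream)) %% 2147483629
}
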