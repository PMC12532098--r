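#' Independent seeded random streams
#'
#' Training and sampling draw from several logically independent sources of
#' randomness (time-step draws, forward noise, sampler noise, data order).
#' Each stream wraps its own saved copy of R's Mersenne-Twister state so the
#' streams do not perturb each other or the caller's RNG. A stream is derived
#' from `(master_seed, label)` deterministically, so one master seed fixes the
#' whole run.
#'
#' @param seed integer master seed.
#' @param label character tag naming the stream.
#' @return an environment with functions `runif`, `rnorm`, `sample_int`.
#' @keywords internal
rng_stream <- function(seed, label = "") {
  # Fold the label into the seed with a small string hash, kept below 2^31.
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647L
  sub_seed <- as.integer((as.numeric(seed) %% 2147483647 * 2654435 + h) %% 2147483647)

  st <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(sub_seed, kind = "Mersenne-Twister")
  st$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())

  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", st$state, globalenv())
    on.exit({
      st$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  st$runif <- function(n, min = 0, max = 1) with_state(stats::runif(n, min, max))
  st$rnorm <- function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd))
  st$sample_int <- function(n, size, replace = FALSE) with_state(sample.int(n, size, replace = replace))
  st
}
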