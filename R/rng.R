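# Named RNG substreams: every randomised step derives its own stream from
# the one user-supplied seed plus a stage name, so individual stages can be
# regenerated independently and no stage perturbs another's draws. Streams
# carry their own .Random.seed state and never touch the caller's RNG.

string_hash <- function(name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

#' Create a named RNG substream
#'
#' @param seed master integer seed.
#' @param name substream name (a stage label).
#' @return an opaque stream object usable with [rng_eval()].
#' @export
substream_rng <- function(seed, name) {
  sub_seed <- as.integer((as.numeric(seed) * 48271 + string_hash(name)) %%
                           2147483647)
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(sub_seed)
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "cocoamap_rng"
  e
}

#' Evaluate an expression under a substream's RNG state
#'
#' @param rng a stream from [substream_rng()].
#' @param expr expression drawing random numbers.
#' @return the expression's value; the stream state advances.
#' @export
rng_eval <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

sample_int <- function(rng, n, k) {
  rng_eval(rng, sample.int(n, k))
}
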