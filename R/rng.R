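# Reproducible per-trajectory random streams.
#
# One xoshiro256++ generator per trajectory, seeded by splitmix64 from
# (master seed, global trajectory index). The same C++ generator backs
# both the R-level reference simulator and the batch engine, so the two
# consume identical variates.

#' Create a reproducible uniform random stream
#'
#' Streams for distinct `(seed, index)` pairs are independent and
#' reproducible; [run_simulation()] drives trajectory `i` with the stream
#' `rng_stream(seed, i)` regardless of the worker partition.
#'
#' @param seed non-negative integer master seed.
#' @param index non-negative integer substream index (global trajectory
#'   index).
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed, index = 0) {
  structure(
    list(ptr = .rng_new(as.numeric(seed), as.numeric(index)),
         seed = seed, index = index),
    class = "rng_stream"
  )
}

#' Draw uniforms from a stream
#'
#' @param rng an `rng_stream`.
#' @param k number of variates.
#' @return `k` doubles strictly inside (0, 1).
#' @export
rng_uniform <- function(rng, k = 1) {
  .rng_uniform(rng$ptr, as.integer(k))
}

# coerce the rng argument of the step functions: accepts an rng_stream
# or any function(k) -> k uniforms (used by tests with preset variates)
as_uniform_fun <- function(rng) {
  if (inherits(rng, "rng_stream")) {
    function(k) .rng_uniform(rng$ptr, as.integer(k))
  } else if (is.function(rng)) {
    rng
  } else {
    stop("rng must be an rng_stream or a function(k)")
  }
}
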