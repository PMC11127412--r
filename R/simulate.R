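# Gillespie trajectory simulation.
#
# simulate_trajectory() is the R reference path; run_simulation() drives
# the C++ batch engine. Both consume identical random substreams and
# produce identical trajectories (the R arithmetic deliberately mirrors
# the C++ accumulation order, including sequential double-precision
# summation of the rate vector).

#' One Gillespie iteration on the Boolean state space
#'
#' Draws the exponential waiting time from the total exit rate and picks
#' the flipping node proportionally to its rate: with uniforms `u1`,
#' `u2`, the jump lands at `t - log(u1)/total` and flips the smallest `j`
#' whose cumulative rate exceeds `u2 * total` (zero-rate nodes can never
#' be selected). A state with zero total rate is a fixed point and
#' returns `NULL`.
#'
#' @param rates transition-rate vector for `state` (see
#'   [transition_rates()]).
#' @param state current packed state.
#' @param t current time.
#' @param rng an [rng_stream()], or a `function(k)` returning `k`
#'   uniforms in (0, 1) (useful for hand-driven checks).
#' @return `NULL` when `state` is a fixed point, otherwise
#'   `list(state =, time =, node =)` with `node` the 0-based flipped
#'   index.
#' @export
gillespie_step <- function(rates, state, t, rng) {
  total <- 0
  for (r in rates) total <- total + r
  if (total == 0) {
    return(NULL)
  }
  u <- as_uniform_fun(rng)(2)
  tnew <- t - log(u[1]) / total
  target <- u[2] * total
  acc <- 0
  j <- length(rates) - 1L
  for (i in seq_along(rates)) {
    acc <- acc + rates[i]
    if (acc > target) {
      j <- i - 1L
      break
    }
  }
  list(state = bit_flip(state, j), time = tnew, node = j)
}

#' Draw an initial network state
#'
#' Each node starts active independently with its configured
#' initial-state probability.
#'
#' @param network a `boolean_network` (or `compiled_model`).
#' @param rng an [rng_stream()] or `function(k)`.
#' @return packed state bitmask.
#' @export
sample_initial_state <- function(network, rng) {
  if (inherits(network, "compiled_model")) {
    istate <- network$istate
  } else {
    istate <- vapply(network$nodes, `[[`, numeric(1), "istate")
  }
  ufun <- as_uniform_fun(rng)
  state <- 0
  for (i in seq_along(istate)) {
    if (ufun(1) < istate[i]) state <- state + 2^(i - 1)
  }
  state
}

#' Simulate one stochastic trajectory
#'
#' Iterates [gillespie_step()] from `s0` until the first jump that would
#' land beyond `max_time` (end reason `TIMEOUT`; the pre-step state then
#' occupies the rest of the horizon), until a zero-total-rate state
#' (`FIXED_POINT`), or until `max_steps` transitions (`STEP_CAP`, with a
#' warning). Consecutive states always differ in exactly one bit.
#'
#' @param model a `compiled_model` (or `boolean_network`, compiled on the
#'   fly).
#' @param s0 initial packed state.
#' @param config a [simulation_config()].
#' @param rng an [rng_stream()] or `function(k)`.
#' @return a `trajectory` object: `states`, `times` (with `times[1] = 0`),
#'   `end_reason` in `TIMEOUT` / `FIXED_POINT` / `STEP_CAP`, and
#'   `fixed_state` when absorbed.
#' @export
simulate_trajectory <- function(model, s0, config, rng) {
  if (inherits(model, "boolean_network")) model <- compile_model(model)
  evaluate <- model$evaluate
  states <- s0
  times <- 0
  state <- s0
  t <- 0
  end_reason <- "TIMEOUT"
  k <- 0
  repeat {
    if (k >= config$max_steps) {
      end_reason <- "STEP_CAP"
      warning("trajectory hit the max_steps cap before max_time")
      break
    }
    res <- gillespie_step(evaluate(state), state, t, rng)
    if (is.null(res)) {
      end_reason <- "FIXED_POINT"
      break
    }
    if (res$time > config$max_time) break
    state <- res$state
    t <- res$time
    states[length(states) + 1] <- state
    times[length(times) + 1] <- t
    k <- k + 1
  }
  structure(
    list(
      states = states, times = times, end_reason = end_reason,
      fixed_state = if (end_reason == "FIXED_POINT") state else NA_real_
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d transitions, ends by %s at t = %g\n",
    length(x$states) - 1L, x$end_reason, x$times[length(x$times)]
  ))
  invisible(x)
}

#' Even worker partition of the trajectory set
#'
#' Contiguous split of `sample_count` trajectories over `workers`
#' workers; the remainder goes to the first workers one trajectory each
#' (7 over 3 gives loads 3, 2, 2).
#'
#' @param sample_count number of trajectories.
#' @param workers number of workers.
#' @return integer vector of per-worker loads summing to `sample_count`.
#' @export
worker_partition <- function(sample_count, workers) {
  base <- sample_count %/% workers
  rem <- sample_count %% workers
  as.integer(base + (seq_len(workers) <= rem))
}

#' Run a full stochastic simulation
#'
#' Simulates `sample_count` trajectories (trajectory `i` driven by the
#' substream for `(seed, i)`), accumulates the three compound statistics
#' over non-internal nodes — time-windowed state probabilities,
#' final-state distribution, fixed-point distribution — and normalizes
#' them. Per-worker statistics are privatized and merged through a
#' reduction whose tree shape depends only on `sample_count`, so the
#' result is bit-identical for every `workers` value.
#'
#' @param network a `boolean_network` with resolved rates.
#' @param config a [simulation_config()]; when `NULL` it is built from
#'   `...`.
#' @param ... arguments forwarded to [simulation_config()] (or overriding
#'   fields of `config`).
#' @param backend `"auto"` (histogram when at most
#'   `histogram_threshold` nodes are non-internal, hashmap otherwise),
#'   `"histogram"` or `"hashmap"`. Both backends give identical results.
#' @param histogram_threshold dense/sparse crossover width (default 16
#'   non-internal nodes, i.e. 65536 dense slots).
#' @return a `simulation_result`; see [probtraj_table()],
#'   [final_states()], [fixed_points()].
#' @export
run_simulation <- function(network, config = NULL, ...,
                           backend = c("auto", "histogram", "hashmap"),
                           histogram_threshold = 16) {
  backend <- match.arg(backend)
  dots <- list(...)
  if (is.null(config)) {
    config <- do.call(simulation_config, dots)
  } else if (length(dots)) {
    config <- do.call(simulation_config, modifyList(unclass(config), dots))
  }
  model <- compile_model(network)
  mask <- projection_mask(network)
  use_dense <- choose_backend(mask, histogram_threshold) == "histogram"
  if (backend == "histogram") use_dense <- TRUE
  if (backend == "hashmap") use_dense <- FALSE
  if (use_dense && mask$width > 24) {
    stop("histogram backend infeasible for ", mask$width,
         " non-internal nodes; use backend = 'hashmap'")
  }
  t0 <- proc.time()[["elapsed"]]
  raw <- .engine_run(
    model$programs, model$rate_up, model$rate_down, model$istate,
    as.integer(mask$external),
    config$max_time, config$time_tick, config$sample_count,
    config$seed, config$workers,
    if (is.finite(config$max_steps)) config$max_steps else 0,
    use_dense
  )
  elapsed <- proc.time()[["elapsed"]] - t0
  if (raw$n_stepcap > 0) {
    warning(raw$n_stepcap, " trajectories hit the max_steps cap")
  }
  build_simulation_result(
    raw, network, config, mask,
    backend = if (use_dense) "histogram" else "hashmap",
    elapsed = elapsed
  )
}
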