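# Statistics over projected (non-internal) states.
#
# The C++ engine accumulates these structures during batch runs; the
# functions here are the reference implementation used for verification
# (partition invariance, backend equivalence) and for working with
# individual trajectories from R.

#' Projection onto non-internal nodes
#'
#' @param network a `boolean_network`.
#' @return a `projection_mask`: `external` (0-based indices of
#'   non-internal nodes, increasing), `width` (their count) and `names`.
#' @export
projection_mask <- function(network) {
  internal <- vapply(network$nodes, `[[`, logical(1), "is_internal")
  idx <- which(!internal) - 1L
  structure(
    list(
      external = idx, width = length(idx),
      names = node_names(network)[idx + 1L],
      n = network$n
    ),
    class = "projection_mask"
  )
}

#' Project a full state onto the non-internal nodes
#'
#' Bit `j` of the result is the value of the `j`-th non-internal node.
#' With no non-internal nodes every state projects to 0 (the single
#' `<nil>` state).
#'
#' @param state packed full state.
#' @param mask a [projection_mask()].
#' @return packed projected state of `mask$width` bits.
#' @export
project_state <- function(state, mask) {
  if (mask$width == 0) {
    return(0)
  }
  sum(vapply(seq_len(mask$width), function(j) {
    bit_get(state, mask$external[j]) * 2^(j - 1)
  }, numeric(1)))
}

#' Choose the statistics backend for a projection width
#'
#' Dense histograms (one slot per projected state) win while the number
#' of non-internal nodes stays small; beyond the threshold the sparse
#' hashmap takes over.
#'
#' @param mask a [projection_mask()].
#' @param threshold dense/sparse crossover (default 16 bits).
#' @return `"histogram"` or `"hashmap"`.
#' @export
choose_backend <- function(mask, threshold = 16) {
  if (mask$width <= threshold) "histogram" else "hashmap"
}

#' Human-readable label of a projected state
#'
#' Names of the active nodes joined by `" -- "`; the all-inactive state
#' is labeled `"<nil>"`.
#'
#' @param key packed projected state.
#' @param names node names, one per bit of `key`.
#' @return character label.
#' @export
state_label <- function(key, names) {
  active <- names[vapply(seq_along(names), function(j) {
    bit_get(key, j - 1L) == 1L
  }, logical(1))]
  if (length(active) == 0) "<nil>" else paste(active, collapse = " -- ")
}

window_count <- function(max_time, time_tick) {
  max(1L, as.integer(ceiling(max_time / time_tick - 1e-9)))
}

window_length <- function(w, time_tick, max_time) {
  # window w (1-based here) covers [ (w-1)*tick, min(w*tick, max_time) )
  min(w * time_tick, max_time) - (w - 1) * time_tick
}

#' Empty statistics accumulator
#'
#' @param mask a [projection_mask()].
#' @param config a [simulation_config()] (fixes the window layout).
#' @param backend `"hashmap"` (named weight vectors) or `"histogram"`
#'   (dense `2^width` vectors).
#' @return a `stat_acc` with zero weight everywhere.
#' @export
empty_stats <- function(mask, config, backend = "hashmap") {
  W <- window_count(config$max_time, config$time_tick)
  windows <- if (backend == "histogram") {
    replicate(W, numeric(2^mask$width), simplify = FALSE)
  } else {
    replicate(W, setNames(numeric(0), character(0)), simplify = FALSE)
  }
  structure(
    list(
      backend = backend, mask = mask, W = W,
      time_tick = config$time_tick, max_time = config$max_time,
      windows = windows,
      final = setNames(numeric(0), character(0)),
      fixed = setNames(numeric(0), character(0)),
      n_traj = 0
    ),
    class = "stat_acc"
  )
}

map_add <- function(map, key, value) {
  key <- as.character(key)
  if (is.null(names(map)) || !key %in% names(map)) {
    map[key] <- value
  } else {
    map[key] <- map[[key]] + value
  }
  map
}

#' Fold one trajectory into a statistics accumulator
#'
#' Every stay of the trajectory in a state (the last one extended to
#' `max_time`: a trajectory absorbed in a fixed point keeps occupying it)
#' adds its overlap with each time window to that window's weight for the
#' projected state. The state occupied at `max_time` counts once into the
#' final-state distribution; a `FIXED_POINT` trajectory counts its full,
#' unprojected absorbing state into the fixed-point distribution.
#'
#' @param stats a `stat_acc` from [empty_stats()].
#' @param traj a `trajectory` from [simulate_trajectory()].
#' @return the updated `stat_acc`.
#' @export
accumulate_trajectory <- function(stats, traj) {
  tick <- stats$time_tick
  max_time <- stats$max_time
  k <- length(traj$states)
  add_stay <- function(a, b, key) {
    if (b <= a) {
      return(invisible())
    }
    w0 <- min(floor(a / tick), stats$W - 1L)
    for (w in seq.int(w0, stats$W - 1L)) {
      lo <- w * tick
      hi <- min((w + 1) * tick, max_time)
      if (lo >= b) break
      d <- min(b, hi) - max(a, lo)
      if (d > 0) {
        if (stats$backend == "histogram") {
          stats$windows[[w + 1L]][key + 1L] <<-
            stats$windows[[w + 1L]][key + 1L] + d
        } else {
          stats$windows[[w + 1L]] <<- map_add(stats$windows[[w + 1L]], key, d)
        }
      }
    }
  }
  for (j in seq_len(k)) {
    a <- traj$times[j]
    b <- if (j < k) traj$times[j + 1] else max_time
    add_stay(a, b, project_state(traj$states[j], stats$mask))
  }
  last <- traj$states[k]
  stats$final <- map_add(stats$final, project_state(last, stats$mask), 1)
  if (traj$end_reason == "FIXED_POINT") {
    stats$fixed <- map_add(stats$fixed, last, 1)
  }
  stats$n_traj <- stats$n_traj + 1
  stats
}

#' Merge two statistics accumulators
#'
#' Element-wise weight sums on every structure; commutative and (up to
#' floating-point rounding of the weights) associative, with
#' [empty_stats()] as the identity.
#'
#' @param a,b `stat_acc` objects with the same mask, backend and window
#'   layout.
#' @return the merged `stat_acc`.
#' @export
merge_stats <- function(a, b) {
  if (!identical(a$backend, b$backend) || a$W != b$W ||
      !identical(a$mask$external, b$mask$external) ||
      a$time_tick != b$time_tick || a$max_time != b$max_time) {
    stop("incompatible statistics layouts")
  }
  merge_map <- function(x, y) {
    for (key in names(y)) x <- map_add(x, key, y[[key]])
    x
  }
  for (w in seq_len(a$W)) {
    if (a$backend == "histogram") {
      a$windows[[w]] <- a$windows[[w]] + b$windows[[w]]
    } else {
      a$windows[[w]] <- merge_map(a$windows[[w]], b$windows[[w]])
    }
  }
  a$final <- merge_map(a$final, b$final)
  a$fixed <- merge_map(a$fixed, b$fixed)
  a$n_traj <- a$n_traj + b$n_traj
  a
}

#' Normalize accumulated statistics into probabilities
#'
#' Window weights divide by `sample_count` times the true window length
#' (the last window is truncated when `max_time` is not a multiple of
#' `time_tick`), so every window is a probability distribution. Final
#' counts divide by `sample_count`; fixed-point counts are reported raw
#' and as fractions of all trajectories and of absorbed trajectories.
#'
#' @param stats a `stat_acc`.
#' @param sample_count number of trajectories accumulated (defaults to
#'   the accumulator's own count).
#' @return list with `windows` (per-window probability vectors, dense or
#'   named by projected-state key), `final`, `fixed_counts`,
#'   `fixed_fraction`, `fixed_fraction_of_absorbed`.
#' @export
normalize_stats <- function(stats, sample_count = stats$n_traj) {
  windows <- lapply(seq_len(stats$W), function(w) {
    len <- window_length(w, stats$time_tick, stats$max_time)
    stats$windows[[w]] / (sample_count * len)
  })
  n_absorbed <- sum(stats$fixed)
  list(
    windows = windows,
    final = stats$final / sample_count,
    fixed_counts = stats$fixed,
    fixed_fraction = stats$fixed / sample_count,
    fixed_fraction_of_absorbed =
      if (n_absorbed > 0) stats$fixed / n_absorbed else stats$fixed
  )
}
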