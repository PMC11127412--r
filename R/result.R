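# SimulationResult container and tabular views.

build_simulation_result <- function(raw, network, config, mask, backend,
                                    elapsed) {
  W <- raw$n_windows
  c_ <- config$sample_count
  tick <- config$time_tick
  max_time <- config$max_time

  # union of observed projected states, in lexicographic label order
  keys <- sort(unique(c(
    unlist(lapply(raw$windows, `[[`, "key")), raw$final$key
  )))
  labels <- vapply(keys, state_label, "", names = mask$names)
  ord <- order(labels, method = "radix")
  keys <- keys[ord]
  labels <- labels[ord]

  probtraj <- matrix(0, nrow = W, ncol = length(keys),
                     dimnames = list(NULL, labels))
  windows_raw <- vector("list", W)
  for (w in seq_len(W)) {
    win <- raw$windows[[w]]
    len <- window_length(w, tick, max_time)
    idx <- match(win$key, keys)
    probtraj[w, idx] <- win$weight / (c_ * len)
    windows_raw[[w]] <- setNames(win$weight, as.character(win$key))
  }
  probtraj_df <- data.frame(
    Time = (seq_len(W) - 1) * tick, probtraj, check.names = FALSE
  )

  fidx <- match(raw$final$key, keys)
  final_df <- data.frame(
    state = labels[fidx], count = raw$final$count,
    probability = raw$final$count / c_,
    stringsAsFactors = FALSE
  )
  final_df <- final_df[order(final_df$state, method = "radix"), ,
                       drop = FALSE]
  rownames(final_df) <- NULL

  all_names <- node_names(network)
  fixed_labels <- vapply(raw$fixed$key, state_label, "", names = all_names)
  fixed_df <- data.frame(
    state = fixed_labels, count = raw$fixed$count,
    fraction = raw$fixed$count / c_,
    fraction_of_absorbed = if (raw$n_fixed > 0) {
      raw$fixed$count / raw$n_fixed
    } else {
      raw$fixed$count
    },
    stringsAsFactors = FALSE
  )
  fixed_df <- fixed_df[order(fixed_df$state, method = "radix"), ,
                       drop = FALSE]
  rownames(fixed_df) <- NULL

  structure(
    list(
      probtraj = probtraj_df,
      final_states = final_df,
      fixed_points = fixed_df,
      state_keys = setNames(keys, labels),
      mask = mask,
      config = config,
      backend = backend,
      n_windows = W,
      sample_count = c_,
      n_fixed = raw$n_fixed,
      n_timeout = raw$n_timeout,
      n_stepcap = raw$n_stepcap,
      mean_trajectory_length = raw$total_steps / c_,
      windows_raw = windows_raw,
      final_raw = setNames(raw$final$count, as.character(raw$final$key)),
      fixed_raw = setNames(raw$fixed$count, as.character(raw$fixed$key)),
      elapsed = elapsed
    ),
    class = "simulation_result"
  )
}

#' Windowed state-probability table
#'
#' One row per time window (`Time` = window start), one probability
#' column per observed projected state, labeled by the active
#' non-internal nodes (`" -- "`-joined, `"<nil>"` when none are active),
#' in lexicographic order. Row probabilities sum to 1.
#'
#' @param result a `simulation_result` from [run_simulation()].
#' @return a data.frame.
#' @export
probtraj_table <- function(result) result$probtraj

#' Final-state distribution
#'
#' Distribution of the projected states occupied at `max_time`.
#'
#' @param result a `simulation_result`.
#' @return data.frame with `state`, `count`, `probability`.
#' @export
final_states <- function(result) result$final_states

#' Fixed-point distribution
#'
#' Absorbing states reached before `max_time`, keyed by the full
#' (unprojected) state — distinct attractors are never merged by the
#' projection. Fractions are reported both over all trajectories and
#' over absorbed trajectories only.
#'
#' @param result a `simulation_result`.
#' @return data.frame with `state`, `count`, `fraction`,
#'   `fraction_of_absorbed`.
#' @export
fixed_points <- function(result) result$fixed_points

#' Per-node activation probabilities over time windows
#'
#' Marginalizes the windowed state probabilities: for each non-internal
#' node, the probability that it is active in each window (the quantity
#' drawn as one line per node in the classic trajectory line chart).
#'
#' @param result a `simulation_result`.
#' @return data.frame with `Time` (window start) and one column per
#'   non-internal node.
#' @export
node_activation <- function(result) {
  keys <- result$state_keys
  mat <- as.matrix(result$probtraj[, -1, drop = FALSE])
  out <- data.frame(Time = result$probtraj$Time)
  for (j in seq_len(result$mask$width)) {
    active <- vapply(keys, function(k) bit_get(k, j - 1L) == 1L, logical(1))
    out[[result$mask$names[j]]] <- if (any(active)) {
      rowSums(mat[, active, drop = FALSE])
    } else {
      rep(0, nrow(mat))
    }
  }
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Boolean network simulation: %g trajectories, %d windows of %g ",
      "(%s backend)\n  end reasons: %g timeout, %g fixed point, ",
      "%g step cap\n  mean trajectory length: %.2f transitions\n"
    ),
    x$sample_count, x$n_windows, x$config$time_tick, x$backend,
    x$n_timeout, x$n_fixed, x$n_stepcap, x$mean_trajectory_length
  ))
  if (nrow(x$final_states)) {
    cat("  final states:\n")
    top <- head(x$final_states[order(-x$final_states$probability), ], 8)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-40s %.4f\n", top$state[i], top$probability[i]))
    }
  }
  if (nrow(x$fixed_points)) {
    cat(sprintf("  fixed points reached by %.1f%% of trajectories\n",
                100 * x$n_fixed / x$sample_count))
  }
  invisible(x)
}
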