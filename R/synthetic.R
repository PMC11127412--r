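# Synthetic benchmark models with predictable trajectory length and no
# stable states.
#
# Construction: node i gets the always-enabled toggle logic
#     f_i = (!S_i) XOR (g_i & !g_i)
# where g_i is a random sub-formula over other nodes. The tautological
# padding g & !g is identically 0, so f_i(S) = !S_i for every state:
# every node can always flip, every state has exactly n outgoing
# transitions, and with rate r the total exit rate is n*r everywhere.
# The transition count on [0, T] is therefore Poisson(n*r*T); choosing
# max_time = L / (n*r) pins the expected trajectory length to exactly L.
# The padding is structural only — the compiler does no simplification,
# so generated formula/program size still tracks formula_size.

#' Specification of a synthetic benchmark model
#'
#' Defaults mirror the usual benchmark setup: 5 non-internal nodes,
#' designed mean trajectory length 100, unit rates.
#'
#' @param n_nodes number of nodes.
#' @param n_external number of non-internal nodes (the first
#'   `n_external` nodes; must not exceed `n_nodes`).
#' @param formula_size target mean operand count per formula.
#' @param target_avg_length designed mean number of transitions per
#'   trajectory (`L`).
#' @param seed generator seed; the same spec always yields the same
#'   model.
#' @param rate flip rate `r` shared by all nodes and directions.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes, n_external = 5, formula_size = 10,
                           target_avg_length = 100, seed = 0, rate = 1) {
  stopifnot(
    n_nodes >= 1, n_external >= 0, n_external <= n_nodes,
    formula_size >= 1, target_avg_length > 0, rate > 0
  )
  structure(
    list(
      n_nodes = as.integer(n_nodes), n_external = as.integer(n_external),
      formula_size = as.integer(formula_size),
      target_avg_length = target_avg_length,
      seed = as.numeric(seed), rate = rate
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic benchmark model
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (a `boolean_network`; first
#'   `n_external` nodes non-internal, all initial-state probabilities
#'   0.5) and `config` (a [simulation_config()] with
#'   `max_time = L / (n * rate)`).
#' @export
generate_synthetic_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  rng <- rng_stream(spec$seed, 982451653)
  draw_int <- function(k) {
    min(floor(rng_uniform(rng, 1) * k) + 1, k)
  }

  # per-node padding size: operand count of node i is 1 + 2 * g_ops(i);
  # alternate floor/ceil of (formula_size - 1) / 2 so the mean operand
  # count stays within 1 of formula_size
  half <- (spec$formula_size - 1) / 2
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    g_ops <- if (spec$formula_size < 3) {
      0L
    } else {
      as.integer(if (i %% 2 == 1) floor(half) else ceiling(half))
    }
    self <- f_var(sprintf("N%d", i))
    logic <- f_not(self)
    if (g_ops > 0) {
      g <- random_subformula(n, i, g_ops, draw_int)
      logic <- f_xor(logic, f_and(g, f_not(g)))
    }
    nodes[[i]] <- list(
      name = sprintf("N%d", i), logic = logic,
      rate_up = spec$rate, rate_down = spec$rate,
      is_internal = i > spec$n_external, istate = 0.5
    )
  }
  network <- boolean_network(nodes)
  max_time <- spec$target_avg_length / (n * spec$rate)
  config <- simulation_config(
    max_time = max_time, time_tick = max_time / 10,
    sample_count = 10000, seed = spec$seed, workers = 1
  )
  list(network = network, config = config)
}

# random left-folded sub-formula with n_ops variable operands drawn
# without replacement from nodes other than `self` (the pool refills when
# exhausted); leaves are negated with probability 1/4 and connectives are
# uniform over AND / OR / XOR
random_subformula <- function(n, self, n_ops, draw_int) {
  pool <- setdiff(seq_len(n), self)
  if (length(pool) == 0) pool <- self # single-node degenerate case
  avail <- pool
  leaf <- function() {
    if (length(avail) == 0) avail <<- pool
    j <- draw_int(length(avail))
    v <- f_var(sprintf("N%d", avail[j]))
    avail <<- avail[-j]
    if (draw_int(4) == 1) f_not(v) else v
  }
  g <- leaf()
  if (n_ops > 1) {
    for (k in seq_len(n_ops - 1)) {
      op <- switch(draw_int(3), f_and, f_or, f_xor)
      g <- op(g, leaf())
    }
  }
  g
}

#' Designed mean trajectory length of a synthetic model
#'
#' Closed form of the construction: every state of a generated model has
#' total exit rate `n * rate`, so the number of transitions in
#' `[0, max_time]` is Poisson with mean `n * rate * max_time`, which the
#' generator pins to `target_avg_length`.
#'
#' @param spec a [synthetic_spec()].
#' @return the expected number of transitions per trajectory.
#' @export
expected_trajectory_length <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  max_time <- spec$target_avg_length / (spec$n_nodes * spec$rate)
  spec$n_nodes * spec$rate * max_time
}

# mean operand count over all node formulas ("formula size" metric)
mean_formula_size <- function(network) {
  mean(vapply(network$nodes, function(nd) formula_size(nd$logic),
              integer(1)))
}
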