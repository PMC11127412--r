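# Shared model builders and independent mini-oracles for the tests.
# Everything is generated in code; no fixture files.

# 1-node always-flipping chain: logic = !A
toggle_model <- function(r = 1, p0 = 0.5) {
  boolean_network(list(list(
    name = "A", logic = f_not_(f_var_("A")),
    rate_up = r, rate_down = r, istate = p0
  )))
}

# 1-node absorbing decay: logic = 0, start active
decay_model <- function(r = 1, p0 = 1) {
  boolean_network(list(list(
    name = "A", logic = f_const_(0),
    rate_up = r, rate_down = r, istate = p0
  )))
}

# every node frozen at its own value (all 2^n states fixed points)
frozen_model <- function(n = 2) {
  boolean_network(lapply(seq_len(n), function(i) {
    nm <- paste0("F", i)
    list(name = nm, logic = f_var_(nm), istate = 0.5)
  }))
}

# AST constructors (internal package functions, aliased for brevity)
f_var_ <- function(nm) boolss:::f_var(nm)
f_const_ <- function(v) boolss:::f_const(v)
f_not_ <- function(x) boolss:::f_not(x)
f_and_ <- function(a, b) boolss:::f_and(a, b)
f_or_ <- function(a, b) boolss:::f_or(a, b)
f_xor_ <- function(a, b) boolss:::f_xor(a, b)

# deterministic pseudo-random helpers driven by a package rng stream
make_draw <- function(seed, salt = 424243) {
  rng <- rng_stream(seed, salt)
  function(k) min(floor(rng_uniform(rng, 1) * k) + 1, k)
}

# random formula AST with exactly n_leaves operand leaves over given names
random_formula <- function(names_, n_leaves, draw) {
  if (n_leaves == 1) {
    leaf <- if (draw(10) == 1) {
      f_const_(draw(2) - 1)
    } else {
      f_var_(names_[draw(length(names_))])
    }
    if (draw(4) == 1) f_not_(leaf) else leaf
  } else {
    k1 <- draw(n_leaves - 1)
    op <- switch(draw(3), f_and_, f_or_, f_xor_)
    f <- op(
      random_formula(names_, k1, draw),
      random_formula(names_, n_leaves - k1, draw)
    )
    if (draw(5) == 1) f_not_(f) else f
  }
}

# random n-node network; unit or varied rates, everything non-internal
random_network <- function(n, seed, max_leaves = 5, varied_rates = FALSE,
                           istate = 0.5) {
  draw <- make_draw(seed)
  names_ <- paste0("N", seq_len(n))
  boolean_network(lapply(seq_len(n), function(i) {
    rup <- if (varied_rates) draw(4) / 2 else 1
    rdn <- if (varied_rates) draw(4) / 2 else 1
    list(
      name = names_[i],
      logic = random_formula(names_, draw(max_leaves), draw),
      rate_up = rup, rate_down = rdn, istate = istate
    )
  }))
}

# ---- independent oracles (deliberately different code paths) ----

# arithmetic truth-table evaluator over an explicit bit vector
oracle_eval <- function(f, bits) {
  switch(f$op,
    var = bits[f$index + 1],
    const = f$value,
    not = 1 - oracle_eval(f$args[[1]], bits),
    and = oracle_eval(f$args[[1]], bits) * oracle_eval(f$args[[2]], bits),
    or = max(
      oracle_eval(f$args[[1]], bits),
      oracle_eval(f$args[[2]], bits)
    ),
    xor = (oracle_eval(f$args[[1]], bits) +
             oracle_eval(f$args[[2]], bits)) %% 2
  )
}

# brute-force per-state rate vector from the flip-allowed rule
oracle_rates <- function(network, state) {
  bits <- boolss:::state_to_bits(state, network$n)
  vapply(seq_len(network$n), function(i) {
    nd <- network$nodes[[i]]
    fi <- oracle_eval(nd$logic, bits)
    if (fi == bits[i]) 0 else if (bits[i] == 1) nd$rate_down else nd$rate_up
  }, numeric(1))
}

# structural formula equality ignoring nothing (ASTs are plain lists)
expect_same_network <- function(a, b) {
  expect_identical(a$n, b$n)
  expect_identical(boolss:::node_names(a), boolss:::node_names(b))
  for (i in seq_len(a$n)) {
    expect_identical(a$nodes[[i]]$logic, b$nodes[[i]]$logic)
    expect_identical(a$nodes[[i]]$rate_up, b$nodes[[i]]$rate_up)
    expect_identical(a$nodes[[i]]$rate_down, b$nodes[[i]]$rate_down)
    expect_identical(a$nodes[[i]]$is_internal, b$nodes[[i]]$is_internal)
    expect_identical(a$nodes[[i]]$istate, b$nodes[[i]]$istate)
  }
}
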