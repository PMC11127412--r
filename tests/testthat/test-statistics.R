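# Projection, windowed accumulation, normalization, merging and the two
# statistics backends.

mk_traj <- function(states, times, end_reason = "TIMEOUT") {
  structure(
    list(
      states = states, times = times, end_reason = end_reason,
      fixed_state = if (end_reason == "FIXED_POINT") {
        states[length(states)]
      } else {
        NA_real_
      }
    ),
    class = "trajectory"
  )
}

two_node_net <- function() {
  boolean_network(list(
    list(name = "A", logic = f_not_(f_var_("A"))),
    list(name = "B", logic = f_not_(f_var_("B")))
  ))
}

test_that("projection extracts the non-internal bits", {
  net <- random_network(6, 1)
  mask_all <- projection_mask(net)
  expect_equal(mask_all$width, 6L)
  for (S in c(0, 1, 37, 63)) expect_equal(project_state(S, mask_all), S)

  # external nodes {1, 4} (0-based) of 6: S = 0b010010 -> 0b11
  net2 <- net
  for (i in c(1, 3, 4, 6)) net2$nodes[[i]]$is_internal <- TRUE
  mask <- projection_mask(net2)
  expect_equal(mask$external, c(1L, 4L))
  expect_equal(project_state(strtoi("010010", base = 2), mask), 3)
  expect_equal(project_state(strtoi("010000", base = 2), mask), 2)

  # empty mask: everything collapses to the single <nil> state
  net3 <- net
  for (i in 1:6) net3$nodes[[i]]$is_internal <- TRUE
  mask0 <- projection_mask(net3)
  expect_equal(mask0$width, 0L)
  for (S in c(0, 5, 63)) expect_equal(project_state(S, mask0), 0)
  expect_equal(state_label(0, character(0)), "<nil>")
})

test_that("state labels join active nodes with the separator", {
  nm <- c("P53", "MDM2", "Apoptosis")
  expect_equal(state_label(0, nm), "<nil>")
  expect_equal(state_label(1, nm), "P53")
  expect_equal(state_label(6, nm), "MDM2 -- Apoptosis")
  expect_equal(state_label(7, nm), "P53 -- MDM2 -- Apoptosis")
})

test_that("backend choice switches at the width threshold", {
  net <- random_network(5, 2)
  expect_equal(choose_backend(projection_mask(net)), "histogram")
  mask20 <- structure(
    list(external = 0:19, width = 20L, names = paste0("N", 1:20), n = 20L),
    class = "projection_mask"
  )
  expect_equal(choose_backend(mask20, threshold = 16), "hashmap")
  expect_equal(choose_backend(mask20, threshold = 20), "histogram")
})

test_that("stay durations land in the overlapped windows", {
  net <- two_node_net()
  cfg <- simulation_config(max_time = 1, time_tick = 0.5, sample_count = 1)
  mask <- projection_mask(net)

  # state A (bit0 = 1) on [0, 0.25), then B (bit1 = 1) to the end
  acc <- accumulate_trajectory(
    empty_stats(mask, cfg), mk_traj(c(1, 2), c(0, 0.25))
  )
  expect_equal(acc$windows[[1]][["1"]], 0.25)
  expect_equal(acc$windows[[1]][["2"]], 0.25)
  expect_equal(acc$windows[[2]][["2"]], 0.5)
  expect_equal(acc$final[["2"]], 1)
  expect_equal(length(acc$fixed), 0L)

  # fixed point at t = 0 occupies everything; counted once as final and
  # once as a fixed point
  acc2 <- accumulate_trajectory(
    empty_stats(mask, cfg), mk_traj(3, 0, end_reason = "FIXED_POINT")
  )
  expect_equal(acc2$windows[[1]][["3"]], 0.5)
  expect_equal(acc2$windows[[2]][["3"]], 0.5)
  expect_equal(acc2$final[["3"]], 1)
  expect_equal(acc2$fixed[["3"]], 1)
})

test_that("window weights conserve total trajectory duration", {
  net <- random_network(5, 31, varied_rates = TRUE)
  for (tick in c(0.3, 0.5)) {
    # 0.3 does not divide 2: the last window is truncated
    cfg <- simulation_config(max_time = 2, time_tick = tick,
                             sample_count = 400, seed = 2)
    res <- run_simulation(net, cfg)
    for (w in seq_len(res$n_windows)) {
      len <- boolss:::window_length(w, tick, 2)
      expect_equal(
        sum(res$windows_raw[[w]]), cfg$sample_count * len,
        tolerance = 1e-9
      )
      expect_equal(sum(res$probtraj[w, -1]), 1, tolerance = 1e-9)
    }
    expect_equal(sum(res$final_states$probability), 1)
  }
})

test_that("normalization turns weights into per-window distributions", {
  net <- two_node_net()
  cfg <- simulation_config(max_time = 1, time_tick = 0.5, sample_count = 2)
  mask <- projection_mask(net)
  acc <- empty_stats(mask, cfg)
  acc <- accumulate_trajectory(acc, mk_traj(1, 0))            # A throughout
  acc <- accumulate_trajectory(acc, mk_traj(c(2, 1), c(0, 0.5)))
  norm <- normalize_stats(acc, 2)
  expect_equal(norm$windows[[1]][["1"]], 0.5)
  expect_equal(norm$windows[[1]][["2"]], 0.5)
  expect_equal(norm$windows[[2]][["1"]], 1)
  expect_equal(sum(norm$final), 1)
  for (w in 1:2) expect_equal(sum(norm$windows[[w]]), 1)
})

test_that("merge is a commutative monoid with the empty stats identity", {
  net <- random_network(3, 8)
  cfg <- simulation_config(max_time = 1.5, time_tick = 0.5, sample_count = 1)
  mask <- projection_mask(net)
  cm <- compile_model(net)
  mk_acc <- function(idx) {
    acc <- empty_stats(mask, cfg)
    for (i in idx) {
      rng <- rng_stream(4, i)
      s0 <- sample_initial_state(cm, rng)
      acc <- accumulate_trajectory(acc, simulate_trajectory(cm, s0, cfg, rng))
    }
    acc
  }
  a <- mk_acc(0:4)
  b <- mk_acc(5:11)
  empty <- empty_stats(mask, cfg)
  expect_equal(merge_stats(a, empty), a)
  ab <- merge_stats(a, b)
  ba <- merge_stats(b, a)
  for (w in seq_len(a$W)) {
    expect_equal(
      ab$windows[[w]][sort(names(ab$windows[[w]]))],
      ba$windows[[w]][sort(names(ba$windows[[w]]))]
    )
  }
  # any partition folds to the single-pass accumulation
  whole <- mk_acc(0:11)
  parts <- merge_stats(merge_stats(mk_acc(0:2), mk_acc(3:8)), mk_acc(9:11))
  for (w in seq_len(a$W)) {
    expect_equal(
      parts$windows[[w]][sort(names(parts$windows[[w]]))],
      whole$windows[[w]][sort(names(whole$windows[[w]]))],
      tolerance = 1e-12
    )
  }
  expect_equal(parts$final[sort(names(parts$final))],
               whole$final[sort(names(whole$final))])
  expect_error(
    merge_stats(a, empty_stats(mask, simulation_config(max_time = 2))),
    "incompatible"
  )
})

test_that("hashmap and histogram backends give identical distributions", {
  for (seed in c(3, 12)) {
    net <- random_network(5, seed + 60, varied_rates = TRUE)
    net$nodes[[2]]$is_internal <- TRUE
    cfg <- simulation_config(max_time = 2, time_tick = 0.25,
                             sample_count = 300, seed = seed)
    hist_res <- run_simulation(net, cfg, backend = "histogram")
    hash_res <- run_simulation(net, cfg, backend = "hashmap")
    expect_identical(hist_res$probtraj, hash_res$probtraj)
    expect_identical(hist_res$final_states, hash_res$final_states)
    expect_identical(hist_res$fixed_points, hash_res$fixed_points)
  }
})

test_that("final states match the exact distribution at the horizon", {
  # toggle starting active: P(active at T) = 1/2 + 1/2 exp(-2 r T)
  net <- toggle_model(r = 1, p0 = 1)
  res <- run_simulation(net, max_time = 1, time_tick = 0.1,
                        sample_count = 4e4, seed = 13)
  p_exact <- 0.5 + 0.5 * exp(-2)
  p_hat <- res$final_states$probability[res$final_states$state == "A"]
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(0.25 / 4e4))
})
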