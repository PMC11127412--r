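# Gillespie stepping, trajectory generation, RNG reproducibility and the
# deterministic multi-worker contract.

preset <- function(values) {
  # rng stand-in replaying a fixed queue of variates
  i <- 0
  function(k) {
    out <- values[i + seq_len(k)]
    i <<- i + k
    out
  }
}

test_that("a hand-executed step reproduces the inverse-transform rules", {
  # rates (1, 3), u1 = u2 = 0.5: dt = -ln(.5)/4, cumulative sums 1, 4 and
  # 0.5 * 4 = 2 > 1, so the second node flips
  res <- gillespie_step(c(1, 3), state = 0, t = 2, rng = preset(c(0.5, 0.5)))
  expect_equal(res$time, 2 - log(0.5) / 4)
  expect_equal(res$node, 1L)
  expect_equal(res$state, 2)
  # u2 just below 1/4 selects the first node (strict inequality)
  res2 <- gillespie_step(c(1, 3), 0, 0, preset(c(0.5, 0.2499)))
  expect_equal(res2$node, 0L)
  # zero-rate nodes are never selected even at boundary draws
  res3 <- gillespie_step(c(0, 1), 0, 0, preset(c(0.5, 1e-12)))
  expect_equal(res3$node, 1L)
  # all-zero rates: fixed point regardless of the stream
  expect_null(gillespie_step(c(0, 0), 3, 0, preset(c(0.1, 0.9))))
})

test_that("node selection frequencies follow the rate proportions", {
  rng <- rng_stream(2024, 0)
  n_draw <- 1e5
  picks <- integer(n_draw)
  for (k in seq_len(n_draw)) {
    picks[k] <- gillespie_step(c(1, 3), 0, 0, rng)$node
  }
  p_hat <- mean(picks == 0L)
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / n_draw))
})

test_that("dwell times in a held state are exponential in the total rate", {
  rng <- rng_stream(7, 0)
  total <- 4 # rates (1, 3)
  dwell <- replicate(1e4, gillespie_step(c(1, 3), 0, 0, rng)$time)
  ks <- suppressWarnings(stats::ks.test(dwell, "pexp", rate = total))
  expect_gt(ks$p.value, 0.001)
})

test_that("single-transition decay times have the exponential mean", {
  r <- 2
  net <- decay_model(r = r)
  cm <- compile_model(net)
  cfg <- simulation_config(max_time = 50, sample_count = 1)
  times <- vapply(0:9999, function(i) {
    rng <- rng_stream(11, i)
    s0 <- sample_initial_state(cm, rng)
    tr <- simulate_trajectory(cm, s0, cfg, rng)
    expect_identical(tr$end_reason, "FIXED_POINT")
    tr$times[2]
  }, numeric(1))
  expect_lt(abs(mean(times) - 1 / r), 3 * (1 / r) / 100)
})

test_that("initial states follow the per-node activation probabilities", {
  all_on <- boolean_network(list(
    list(name = "A", logic = f_var_("A"), istate = 1),
    list(name = "B", logic = f_var_("B"), istate = 1)
  ))
  all_off <- boolean_network(list(
    list(name = "A", logic = f_var_("A"), istate = 0),
    list(name = "B", logic = f_var_("B"), istate = 0)
  ))
  rng <- rng_stream(1, 0)
  for (k in 1:20) {
    expect_equal(sample_initial_state(all_on, rng), 3)
    expect_equal(sample_initial_state(all_off, rng), 0)
  }
  biased <- boolean_network(list(
    list(name = "A", logic = f_var_("A"), istate = 0.3)
  ))
  draws <- vapply(
    seq_len(1e5), function(k) sample_initial_state(biased, rng), numeric(1)
  )
  expect_lt(abs(mean(draws) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
})

test_that("frozen networks absorb immediately", {
  net <- frozen_model(3)
  cm <- compile_model(net)
  rng <- rng_stream(5, 1)
  s0 <- sample_initial_state(cm, rng)
  tr <- simulate_trajectory(cm, s0, simulation_config(max_time = 10), rng)
  expect_identical(tr$end_reason, "FIXED_POINT")
  expect_equal(length(tr$states), 1L)
  expect_equal(tr$fixed_state, s0)
  # the absorbing state has zero total exit rate
  expect_equal(sum(transition_rates(net, tr$fixed_state)), 0)
})

test_that("consecutive trajectory states differ in exactly one bit", {
  for (seed in 1:5) {
    net <- random_network(5, seed + 300, varied_rates = TRUE)
    cm <- compile_model(net)
    cfg <- simulation_config(max_time = 5)
    for (i in 0:19) {
      rng <- rng_stream(seed, i)
      s0 <- sample_initial_state(cm, rng)
      tr <- simulate_trajectory(cm, s0, cfg, rng)
      expect_true(all(diff(tr$times) > 0))
      expect_equal(tr$times[1], 0)
      expect_lte(tr$times[length(tr$times)], cfg$max_time)
      if (length(tr$states) > 1) {
        for (j in seq_len(length(tr$states) - 1)) {
          d <- bitwXor(as.integer(tr$states[j]), as.integer(tr$states[j + 1]))
          expect_equal(sum(boolss:::state_to_bits(d, 5)), 1)
        }
      }
      if (tr$end_reason == "FIXED_POINT") {
        expect_equal(sum(transition_rates(net, tr$fixed_state)), 0)
      }
    }
  }
})

test_that("the R reference and C++ engine produce identical trajectories", {
  for (seed in c(1, 9)) {
    net <- random_network(6, seed + 40, varied_rates = TRUE)
    cm <- compile_model(net)
    cfg <- simulation_config(max_time = 8, seed = seed)
    for (i in c(0, 1, 57)) {
      rng <- rng_stream(seed, i)
      s0 <- sample_initial_state(cm, rng)
      tr <- simulate_trajectory(cm, s0, cfg, rng)
      te <- boolss:::.engine_trajectory(
        cm$programs, cm$rate_up, cm$rate_down, cm$istate,
        cfg$max_time, seed, i, 0
      )
      expect_identical(tr$states, te$states)
      expect_identical(tr$times, te$times)
    }
  }
})

test_that("the step cap ends long trajectories with a warning", {
  net <- toggle_model(r = 1)
  cm <- compile_model(net)
  cfg <- simulation_config(max_time = 100, max_steps = 5)
  rng <- rng_stream(3, 0)
  expect_warning(
    tr <- simulate_trajectory(cm, 0, cfg, rng),
    "max_steps"
  )
  expect_identical(tr$end_reason, "STEP_CAP")
  expect_equal(length(tr$states), 6L)
  expect_warning(
    run_simulation(net, max_time = 100, sample_count = 20, seed = 1,
                   max_steps = 5),
    "max_steps"
  )
})

test_that("trajectories split evenly across workers up to the remainder", {
  expect_identical(worker_partition(7, 3), c(3L, 2L, 2L))
  expect_identical(worker_partition(8, 4), c(2L, 2L, 2L, 2L))
  expect_identical(worker_partition(3, 8), c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(sum(worker_partition(10001, 7)), 10001)
})

test_that("results are bit-identical for any worker count", {
  net <- random_network(6, 17, varied_rates = TRUE)
  cfg <- simulation_config(max_time = 3, time_tick = 0.5,
                           sample_count = 501, seed = 5)
  runs <- lapply(c(1, 2, 8), function(w) {
    run_simulation(net, cfg, workers = w)
  })
  for (k in 2:3) {
    expect_identical(runs[[1]]$probtraj, runs[[k]]$probtraj)
    expect_identical(runs[[1]]$windows_raw, runs[[k]]$windows_raw)
    expect_identical(runs[[1]]$final_states, runs[[k]]$final_states)
    expect_identical(runs[[1]]$fixed_points, runs[[k]]$fixed_points)
  }
})

test_that("the batch engine agrees with an R-side trajectory fold", {
  net <- random_network(4, 23, varied_rates = TRUE)
  cfg <- simulation_config(max_time = 2, time_tick = 0.4,
                           sample_count = 60, seed = 9)
  res <- run_simulation(net, cfg)
  cm <- compile_model(net)
  mask <- projection_mask(net)
  acc <- empty_stats(mask, cfg, backend = "hashmap")
  for (i in seq_len(cfg$sample_count) - 1) {
    rng <- rng_stream(cfg$seed, i)
    s0 <- sample_initial_state(cm, rng)
    acc <- accumulate_trajectory(acc, simulate_trajectory(cm, s0, cfg, rng))
  }
  for (w in seq_len(acc$W)) {
    ref <- acc$windows[[w]][order(as.numeric(names(acc$windows[[w]])))]
    expect_equal(res$windows_raw[[w]], ref, tolerance = 1e-12)
  }
  ref_final <- acc$final[order(as.numeric(names(acc$final)))]
  expect_identical(res$final_raw, ref_final)
  if (length(acc$fixed)) {
    ref_fixed <- acc$fixed[order(as.numeric(names(acc$fixed)))]
    expect_identical(res$fixed_raw, ref_fixed)
  }
})
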