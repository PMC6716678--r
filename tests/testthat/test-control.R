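test_that("LFC pointers hold exactly one +1 and respect the chosen module", {
  lfc <- set_pointer(lfc_state(3, chosen = 1), 2)
  expect_equal(lfc$module_pointers, c(-1, 1, -1))
  expect_equal(pointed_module(lfc), 2)
  expect_equal(lfc$layer_pointer, 1)
  # re-choosing is idempotent
  expect_identical(set_pointer(lfc, 2), lfc)
  expect_error(set_pointer(lfc, 4), "module index")
  # random initial choice covers all modules
  set.seed(1)
  picks <- replicate(200, pointed_module(lfc_state(3)))
  expect_setequal(unique(picks), 1:3)
})

test_that("pMFC burst probability is the documented sigmoid", {
  expect_equal(pmfc_burst_probability(1), 0.5)
  expect_equal(pmfc_burst_probability(0), 1 / (1 + exp(10)))
  expect_gt(pmfc_burst_probability(10), 1 - 1e-6)
  set.seed(2)
  draws <- replicate(4000, sample_pmfc_output(1))
  expect_equal(mean(draws), 0.5, tolerance = 0.05)
  expect_true(all(draws %in% c(0, 1)))
})

test_that("shared noise makes same-sign bursts identical and opposite-sign mirrored", {
  lfc <- set_pointer(lfc_state(3, chosen = 1), 1)
  node_module <- c(NA, NA, 1L, 1L, 2L, 3L)   # two layer-pointer nodes + modules
  B <- t(replicate(200, compose_processing_bursts(lfc, 1, node_module,
                                                  U = stats::rnorm(1))))
  expect_equal(B[, 1], B[, 3])    # layer node and pointed module share the burst
  expect_equal(B[, 5], -B[, 3])   # anti-pointed module gets the exact negative
  expect_equal(stats::cor(B[, 1], B[, 2]), 1)
  expect_equal(stats::cor(B[, 3], B[, 6]), -1)
  # silent pMFC -> no bursts at all
  expect_identical(compose_processing_bursts(lfc, 0, node_module, U = 3),
                   rep(0, 6))
})

test_that("feedback-burst window peaks at exactly 200 ms after feedback", {
  t_grid <- seq(2, 500, by = 2)
  p <- feedback_burst_probability(t_grid)
  expect_equal(t_grid[which.max(p)], 200)
  expect_equal(max(p), 1)
  # zero error never bursts
  expect_equal(feedback_burst(0, 200), 0)
})

test_that("Monte-Carlo feedback-burst count matches the analytic window mass", {
  t_grid <- seq(2, 500, by = 2)
  expected <- sum(feedback_burst_probability(t_grid))   # ~31.3 kicks per error
  expect_equal(expected, 25 * sqrt(2 * pi) / 2, tolerance = 1e-6)
  set.seed(3)
  n_rep <- 2000
  counts <- replicate(n_rep, sum(stats::runif(length(t_grid)) <
                                   feedback_burst_probability(t_grid)))
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("pMFC amplitude decays toward its floor without errors and jumps after one", {
  cfg <- run_config("rw-full", beta = 0.2)
  task <- make_one_dim_task(seed = 4, n_trials = 36)
  sim <- run_simulation(task, "rw-full", beta = 0.2, seed = 4,
                        record_traces = TRUE)
  amp <- apply(abs(sim$traces$pmfc), 2, max)
  dmin <- sim$trials$delta_minus
  # error-free stretches: amplitude strictly decreasing (until near the floor)
  quiet <- which(dmin[-length(dmin)] == 0 & amp[-1] > 3 * cfg$rmin_ctrl)
  expect_true(all(amp[quiet + 1] < amp[quiet]))
  # a sizable error pumps the amplitude on the next trial
  err <- which(dmin > 0.3 & seq_along(dmin) < length(dmin))
  if (length(err) > 0) {
    expect_true(any(amp[err + 1] > amp[err]))
  }
})

test_that("bursting drives the pointed module into phase and the rest into anti-phase", {
  task <- make_one_dim_task(seed = 5)
  cfg <- run_config("rw-full", beta = 0)
  streams <- rng_streams(42)
  spec <- network_spec(n_inputs = 3, algorithm = "RW", synchrony = TRUE)
  net <- with_stream(streams, "weights", init_weights(spec))
  states <- list(net = net, pending_dmin = 1,
                 lfc = set_pointer(lfc_state(3, 1), 1),
                 rl = rl_state(3), pmfc = list(E = 1, I = 0))
  st <- run_trial(states, encode_stimulus(task, 1), 1, cfg, streams,
                  record = TRUE)
  E <- st$trace_E[251:500, ]   # after half a second of bursting
  sync <- mean(stats::cor(E[, 1:3], E[, 4:6]))     # input layer vs pointed module
  anti <- mean(stats::cor(E[, 1:3], E[, 7:12]))    # vs anti-pointed modules
  expect_gt(sync, 0.8)
  expect_lt(anti, -0.8)
})
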